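#!/usr/bin/env Rscript
# Stage 2: LD pruning, ROH calling, and F_roh.
#
# SNPs are pruned in 50-SNP windows (step 5) at a variance inflation factor
# threshold of 2; runs of homozygosity require >= 65 consecutive homozygous
# calls with no heterozygote allowed; F_roh divides each sample's summed
# ROH length by the mapped length of the simulated genome (for a real
# array the denominator would be the 2.77e9 bases of SNP-mappable autosome).
#
# Reads scratch/cohort.* (from 01), writes results/roh_segments.tsv and
# results/froh.tsv.

library(eduroh)

G <- read_plink_bed("scratch/cohort")
kept <- vif_prune(G)
cat(sprintf("LD pruning kept %d of %d SNPs\n", length(kept), ncol(G$calls)))
Gp <- subset_snps(G, kept)

segs <- call_rohs(Gp, min_snps = 65)
denom <- mappable_length(Gp$map)
froh <- compute_froh(segs, denominator_bp = denom,
                     sample_ids = rownames(Gp$calls))

utils::write.table(segs, "results/roh_segments.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(froh, "results/froh.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cat(sprintf("%d ROH segments in %d of %d samples\n", nrow(segs),
            length(unique(segs$sample_id)), nrow(Gp$calls)))
cat(sprintf("F_roh: mean %.4f, sd %.4f, %% zero %.1f (denominator %.3g bp)\n",
            mean(froh$froh), sd(froh$froh),
            100 * mean(froh$froh == 0), denom))

# sanity against the generator truth
truth <- utils::read.table("results/truth_hbd.tsv", header = TRUE, sep = "\t")
tlen <- tapply(truth$end - truth$start + 1, truth$sample, sum)
tfrac <- setNames(numeric(nrow(froh)), froh$sample_id)
tfrac[names(tlen)] <- tlen / 150e6
cat(sprintf("rank correlation of F_roh with true HBD fraction: %.3f\n",
            cor(froh$froh, tfrac[froh$sample_id], method = "spearman")))
cat("wrote results/roh_segments.tsv, results/froh.tsv\n")
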