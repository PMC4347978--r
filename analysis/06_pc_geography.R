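#!/usr/bin/env Rscript
# Stage 6: ancestry-geography correlation per parental educational level.
#
# Fits the moderated-correlation model rho_g = rho0 + g * rho1 (bivariate
# normal likelihood, shared means/variances, likelihood-ratio test of
# rho1 = 0) for PC1 vs latitude and PC2 vs longitude, moderated by paternal
# and maternal EA coded 0..3. In the simulated cohort the correlation
# magnitude should decline with parental EA, because more educated parents
# migrated further from their ancestral demes before their children were
# born.
#
# Reads results/covariates.tsv, results/pcs.tsv; writes results/pcgeo.tsv.

library(eduroh)

fam <- utils::read.table("results/covariates.tsv", header = TRUE, sep = "\t")
pcs <- utils::read.table("results/pcs.tsv", header = TRUE, sep = "\t")
key <- paste0("fam", fam$family_id)
fam <- cbind(fam, pcs[match(key, pcs$sample_id), c("pc1", "pc2", "pc3")])

rows <- list()
for (s in list(c("pc1", "o_lat", "father_ea"),
               c("pc1", "o_lat", "mother_ea"),
               c("pc2", "o_lon", "father_ea"),
               c("pc2", "o_lon", "mother_ea"))) {
  pc <- fam[[s[1]]] / sd(fam[[s[1]]])
  fit <- moderated_correlation_fit(pc, fam[[s[2]]], fam[[s[3]]] - 1)
  per_group <- vapply(0:3, function(g) {
    sel <- fam[[s[3]]] - 1 == g
    cor(pc[sel], fam[[s[2]]][sel])
  }, numeric(1))
  rows[[paste(s, collapse = "_")]] <- data.frame(
    pc = s[1], coordinate = s[2], moderator = s[3],
    rho0 = fit$rho0, rho1 = fit$rho1, se_rho1 = fit$se_rho1,
    lrt_stat = fit$lrt_stat, p = fit$p, n = fit$n)
  cat(sprintf(
    "%s vs %s by %s: sample rho by group %s; rho1 = %.3f +/- %.3f (LRT p = %.2g)\n",
    s[1], s[2], s[3], paste(sprintf("%.2f", per_group), collapse = " / "),
    fit$rho1, fit$se_rho1, fit$p))
}
utils::write.table(do.call(rbind, rows), "results/pcgeo.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/pcgeo.tsv\n")
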