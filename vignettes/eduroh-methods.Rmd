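---
title: "Methods: educational assortment, migration, and genomic homozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: educational assortment, migration, and genomic homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

In populations where ancestry correlates strongly with geography, mate
choice and migration shape the genome of the next generation. More educated
people migrate further from their birthplace, and spouses assort strongly on
educational attainment (EA). Both behaviours together mean that highly
educated couples tend to come from more distant — hence more genetically
dissimilar — origins, so their children carry fewer runs of homozygosity
(ROHs). A naive association study would see "education is associated with
lower F\_roh" and might read a causal, inbreeding-depression story into what
is really a demographic artefact.

`eduroh` implements the full analysis chain needed to study this phenomenon:
an ROH caller and the F\_roh statistic, birthplace-distance statistics,
assortment statistics, permutation inference for regression R² changes,
Sobel mediation tests, ancestry PCA, and a moderated-correlation model for
the decay of the ancestry–geography correlation with parental education.
Because the motivating cohort data are not public, the package is driven by
a synthetic-population generator whose statistical structure matches the
study conditions, so that every stage is testable end to end.

# The synthetic cohort generator

## Educational attainment

EA is ordinal with four levels (primary, secondary, higher secondary,
tertiary). Marginals default to the observed father/mother margins of a
2,058-couple spouse cross-tabulation and to the genotyped generation's own
margins (`ea_marginals_default()`).

Assortment is generated through a Gaussian copula: father and mother latent
traits are bivariate normal, thresholded at the quantiles of their
marginals. The latent correlation is calibrated by 1-D root finding so that
the *discretized* Spearman correlation (midranks for ties, computed exactly
from the bivariate-normal cell probabilities) equals the target, 0.66 by
default. The offspring's latent trait loads equally on both parents, with
the loading calibrated the same way to a parent–offspring Spearman
correlation of 0.40. The calibration is deterministic (numerical integration
of the conditional normal CDF), so no Monte-Carlo tuning loop is involved.
At n = 5,000 the realized Spearman correlations sit within ±0.02 of their
targets.

## Geography and migration

Birthplaces live on a regular deme grid (default 10 × 10 demes at 15 km
spacing, a ~135 km square standing in for a small, densely sampled country).
The generator is *offspring-centric*: each offspring is born in a uniformly
chosen deme, and each parent's birthplace is displaced from it by an
exponential radius with mean equal to that parent's EA-specific migration
scale (defaults 19.2 / 16.3 / 28.7 / 49.8 km for EA 1–4, the observed
paternal migration means), with uniform bearing. Two consequences were the
reason for this design:

* the expected parent–offspring birthplace distance per parental EA level
  equals the corresponding migration parameter *exactly*, which makes the
  generator's contract testable without slack; and
* the father–mother birthplace distance is automatically increasing in both
  parents' EA — the upstream cause of the homozygosity gradient.

An alternative (father uniform, mother displaced from the father, offspring
displaced from the midpoint) produces qualitatively the same structure but
convolves two displacement kernels into every parent–offspring distance, so
no generator parameter maps cleanly onto a testable mean. Parental
coordinates stay continuous (no snap to the grid): snapping to a 15-km
lattice would add noise of the order of the smallest migration means.
Offspring birthplaces do sit on demes, because the genotype model needs a
deme for every *genotyped* individual. Parents displaced beyond the grid are
clamped to a declared bounding box (grid plus a 250 km margin).

## Genotypes, kinship, and HBD tracts

Each SNP gets a baseline logit frequency (uniform 0.1–0.9 on the probability
scale) plus per-axis logit gradients drawn as N(0, c²) per degree, with
c = 0.8 for latitude and 0.4 for longitude by default. Using *random
per-SNP gradients* with axis-specific variances — rather than one shared
gradient — gives the allele-frequency field rank-2 spatial structure, so PC1
aligns with the north–south axis and PC2 with the east–west axis, mirroring
the two distinct ancestry gradients of the motivating population. Deme
frequencies are then drawn from a finite haplotype pool (binomial with
2 × `pool_size` draws) to add drift noise.

Parental kinship follows a one-parameter isolation-by-distance kernel,
φ = φ₀·exp(−d/λ), with d the parental birthplace distance. The defaults are
φ₀ = 0.0625 (first-cousin kinship for parents born in the same place — an
upper anchor chosen so that desk-scale genomes still carry callable ROH) and
λ = 50 km (roughly a quarter of the simulated country span). These are
acknowledged free knobs: the motivating study never quantifies the spatial
kinship decay, so the package treats them as simulation parameters, not
estimates.

Offspring autozygosity is laid down directly as a two-state Markov process
along each chromosome: homozygous-by-descent (HBD) tracts with stationary
fraction φ/2 and mean tract length 0.1 Morgan (10 Mb at the default
1 cM/Mb), alternating with non-HBD stretches. Simulating HBD directly —
instead of a pedigree or coalescent — gives exact control over E[F\_roh],
which is the quantity all downstream statistics consume; the generator's
truth segments make that expectation testable (the mean true-HBD fraction at
φ₀ = 0.1, d = 0 is 0.05 within sampling error).

Given the tract states, the two alleles outside HBD are drawn independently
at the *father's* and the *mother's* origin-deme frequencies, so offspring
ancestry reflects parental origins rather than the offspring's own
birthplace — this is precisely the mechanism by which education-dependent
migration weakens the offspring-level correlation between ancestry PCs and
birthplace. Inside HBD tracts a single allele is drawn at the mean parental
frequency and doubled.

The default genome is 5 chromosomes × 2,000 SNPs over 30 Mb each (15 kb
spacing, the density of a pruned array). At this density a 65-SNP run spans
about 1 Mb and a 10 Mb HBD tract contains ~650 SNPs, so the ROH caller
recovers truth tracts essentially perfectly (rank correlation of F\_roh with
the true HBD fraction ≈ 0.97). Religion and city size are independent
Bernoulli covariates by default (`religion_ea_shift` adds an optional
EA-religion dependence).

What the generator does *not* emulate: linkage disequilibrium outside HBD
tracts (draws are independent given the deme), X chromosomes, genotyping
error, secular EA trends across birth cohorts, and realistic minor-allele
frequency spectra. Passing tests therefore demonstrate the correctness of
the *statistics* under a known truth, not the realism of any particular
parameter value for a real population.

# The ROH caller

LD pruning follows the classic sliding-window variance-inflation-factor
procedure (window 50 SNPs, step 5, VIF threshold 2): within each window the
VIF of each remaining SNP is 1/(1−R²) from regressing its standardized
genotype on the other remaining SNPs, read off the diagonal of the inverse
correlation matrix. The max-VIF SNP is removed until all VIFs are below
threshold; ties break toward removing the lower-MAF SNP. A ridge of 1e-10 on
the correlation diagonal keeps perfectly collinear windows finite and the
removal order deterministic.

An ROH is a maximal run of ≥65 consecutive homozygous calls with no
heterozygote allowed. Missing calls break a run by default — the
conservative reading, since the motivating definition only states the
heterozygote rule — and `missing_breaks = FALSE` tolerates them inside a
run. Runs never span chromosomes. Segment length uses the
`end_bp − start_bp` convention of the standard tooling (not +1).
F\_roh divides each sample's summed segment length by the total mappable
length: 2.77 × 10⁹ bases for a real autosomal array, or
`mappable_length(snp_map)` (per-chromosome last − first position) for
simulated genomes — using the real-array constant on a 150 Mb toy genome
would only rescale every downstream coefficient.

# Inference machinery

**Permutation test for the R² change.** The observed statistic is
R²(covariates + EA) − R²(covariates) for F\_roh. The null distribution
permutes F\_roh across samples (keeping the design intact) and recomputes
the change; the default empirical p is (exceedances + 1)/(n\_perm + 1),
which cannot return an exact zero — the plain rank/n\_perm convention (which
can) is available via `convention = "rank"`. Internally both models are
reduced to thin orthonormal bases once, so each permutation costs two small
matrix products and 100,000 permutations at n = 2,000 take seconds. Type-I
error at α = 0.05 is calibrated to [0.03, 0.07] over 1,000 null replicates.

**Mediation.** The Sobel test uses the classic second-order standard error
√(β²SE\_α² + α²SE\_β²) on two OLS equations (mediator on exposure +
covariates; outcome on exposure + mediator + covariates). For this
just-identified path model, maximum-likelihood covariance fitting and the
two-equation OLS estimates coincide; the package asserts the exact OLS path
identity τ = τ' + αβ to 1e-8 on every run as a structural self-check. The
full-mediation test is the t-test of τ' = 0. Missing data are handled by
listwise deletion per analysis, which is why every reported analysis carries
its own n.

**Moderated correlation.** The trend of the PC–geography correlation across
EA groups g = 0..3 is fit by maximizing the bivariate-normal log-likelihood
with group correlation ρ\_g = ρ₀ + g·ρ₁ and *shared* means and variances
across groups. Sharing the moments isolates the correlation trend and keeps
the likelihood-ratio test of ρ₁ = 0 at one degree of freedom; a
`free_moments = TRUE` variant frees them per group (with two groups that
variant is saturated in ρ and reproduces the per-group sample correlations,
which serves as an oracle check). Correlations are optimized on the natural
scale with a |ρ\_g| < 0.999 barrier rather than Fisher-z, because the linear
trend is specified on the ρ scale. The full fit starts both from sample
moments and from the null solution and is never allowed below the null, so
the LRT statistic is non-negative by construction; when the trend improves
the log-likelihood by less than 5e-7 the fit snaps to the null exactly
(identical groups thus give lrt\_stat = 0, not 1e-9). Standard errors come
from the numerical Hessian at the optimum; fits with any |ρ\_g| > 0.995 are
flagged as boundary hits.

**PCA.** Ancestry PCs use the standard genotype standardization — center by
2p̂, scale by √(2p̂(1−p̂)), mean-impute missing calls, drop monomorphic
SNPs — and an exact eigendecomposition of the sample-by-sample covariance
(no approximation is needed at desk scale). Component signs are arbitrary;
all geography checks compare |correlations| or fix signs explicitly.

# Numerical and degenerate-input choices

* `great_circle_km` uses the spherical law of cosines with radius 6371.0 km
  and clamps the arccos argument to [−1, 1]; an independent haversine
  implementation agrees to <0.5 % beyond 1 km.
* `ols` rejects rank-deficient designs naming the collinear columns, and
  rejects zero-variance outcomes; the pipeline catches the latter (a
  global-null cohort has F\_roh ≡ 0) and reports p = NA with a log entry
  rather than a fabricated p-value.
* Empirical p-values, copula calibration, and every simulation consume
  explicit integer seeds; the pipeline derives per-stage seeds from one root
  seed so a configuration reproduces its report bundle byte for byte (each
  output TSV carries the configuration hash).
* The permutation test warns below 100 permutations and rejects 0; the
  Spearman helpers signal constant inputs instead of returning NaN.

# Problem sizes

The shipped analyses and tests run at desk scale, chosen to finish in
minutes while keeping every effect detectable: cohorts of 2,000 families
(matching the ~2,000-subject motivating cohort) on a 10 × 10 deme grid,
genomes of 5 × 2,000 SNPs, 10,000 permutations in the analysis scripts
(100,000 remains the package default for single runs), 100-replicate
recovery experiments, and 1,000-replicate calibration of the permutation
test at n = 500 / 500 permutations.

# Known limitations

* The kinship kernel and cline strengths are stipulations, not estimates;
  only signs, orderings, and calibration properties — never real-data effect
  magnitudes — are meaningful outputs of the simulated analyses.
* The ROH caller implements exactly the ≥65-homozygote rule: no
  heterozygote-tolerant windows, density or gap filters, or length classes.
* Real-data mode is format support (PLINK text/binary plus a covariate TSV);
  it has not been exercised against a genuine cohort.
* The moderated-correlation model assumes bivariate normality within groups;
  PC scores and coordinates that are strongly non-normal would call for a
  rank-based alternative that the package does not provide.
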