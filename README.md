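# eduroh — educational assortment, migration, and genomic homozygosity

`eduroh` is an R package for studying how educational attainment (EA)
shapes genome-wide homozygosity through two behaviours: more educated
people migrate further from their birthplace, and spouses assort strongly
on education. Where ancestry correlates with geography, highly educated
couples therefore tend to come from more distant, genetically more
dissimilar origins — and their children carry fewer runs of homozygosity
(ROHs). The package implements the complete analysis chain needed to
detect, quantify, and correctly attribute this demographic signal, driven
by a synthetic two-generation cohort generator so that every stage is
testable without access to cohort data.

## What is in the package

* **Synthetic cohort generator** — ordinal EA (4 levels) with spousal
  Spearman assortment via a calibrated Gaussian copula (default ρ = 0.66,
  parent–offspring ρ = 0.40); EA-dependent parental migration on a deme
  grid (default means 19.2/16.3/28.7/49.8 km for EA 1–4); parental kinship
  decaying with birthplace distance, φ = φ₀·exp(−d/λ); offspring
  homozygous-by-descent tracts as a two-state Markov process with
  stationary fraction φ/2; spatial allele-frequency clines giving distinct
  north–south/east–west ancestry axes. PLINK text/binary output.
* **ROH caller** — sliding-window variance-inflation-factor LD pruning
  (window 50, step 5, VIF 2), the ≥65-consecutive-homozygote run
  definition with no heterozygote allowed, and
  F_roh = Σ ROH length / mappable autosomal length
  (2.77 × 10⁹ bases on a real array).
* **Geography** — spherical-law-of-cosines great-circle distances between
  birthplaces (radius 6371 km).
* **Assortment statistics** — contingency χ², Spearman ρ with midranks
  (vector or crosstab input), one-way migration ANOVA, consecutive-level
  t-tests.
* **Regression machinery** — OLS with standardized betas, permutation
  tests of the R² change of a nested regression (default 100,000
  permutations), Sobel mediation tests with the exact OLS path identity
  τ = τ' + αβ asserted on every run.
* **Ancestry PCA and the moderated correlation model** — standardized
  genotype PCA, and the trend model ρ_g = ρ₀ + g·ρ₁ for the PC–geography
  correlation across parental-EA groups, fit by bivariate-normal maximum
  likelihood with a df = 1 likelihood-ratio test of ρ₁ = 0.
* **Pipeline** — `pipeline_config()` / `run_pipeline()` run everything end
  to end with one root seed and produce report tables shaped like a
  migration table, a spouse crosstab, F_roh group means, and the
  regression/permutation summary, plus mediation and PC-geography reports.

## Worked example

Reproduce the published spouse-EA cross-tabulation statistics from the
printed counts of 2,058 Dutch couples, then simulate a cohort and test
whether parental education predicts offspring homozygosity:

```r
library(eduroh)

ct <- contingency_chi2(spouse_ea_crosstab())
sprintf("chi2(%d) = %.2f, rho = %.3f, same-level couples = %.1f%%",
        ct$df, ct$chi2, ct$spearman_rho, 100 * ct$diagonal_share)
#> "chi2(9) = 1496.89, rho = 0.664, same-level couples = 58.5%"

b <- run_pipeline(pipeline_config(mode = "simulate", seed = 60, n_perm = 1000))
subset(b$table4_like, ea_of == "paternal")
#>      ea_of beta_std_ea         p_ea   r2_change empirical_p    n
#> 2 paternal  -0.0783135 0.0004630785 0.006119561 0.000999001 2000
b$mediation[1, c("ea_of", "sobel_p", "tau_prime_p")]
#>      ea_of      sobel_p tau_prime_p
#> 1 paternal 5.821649e-13    0.735722
```

Read: in the simulated 2,000-family cohort, paternal education has a
negative standardized effect on offspring F_roh (β = −0.078), the R²
gain from adding it to the ancestry-PC/religion/city regression is 0.006
with permutation p ≈ 0.001 — and the Sobel test attributes the whole
effect to parental birthplace distance (indirect path p ≈ 6e-13, direct
path τ' p = 0.74): full mediation, exactly the demographic mechanism the
generator encodes.

The numbered scripts under `analysis/` run the same chain stepwise
(simulate → prune/ROH/F_roh → migration & assortment → regressions →
mediation → PC-geography trend), print what they find, and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_roh_froh.R
# ... through analysis/06_pc_geography.R
```

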