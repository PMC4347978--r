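# End-to-end orchestration: simulate (or load) a cohort, prune, call ROHs,
# compute F_roh, birthplace distances, assortment statistics, regression /
# permutation / mediation analyses, and the PC-geography trend model;
# collect everything in a report bundle shaped like the study's tables.

#' Build a pipeline configuration
#'
#' A flat list of parameters with defaults matching the package's study
#' conditions. `seed` is mandatory in simulate mode; every stage derives its
#' own seed from it (`seed + fixed offset`), so a config reproduces its
#' report bundle exactly.
#'
#' @param mode `"simulate"` or `"real"`.
#' @param seed Root seed (integer).
#' @param n_families Families to simulate.
#' @param assortment_rho Spousal EA Spearman target.
#' @param migration_km_by_ea Mean parent-offspring migration km per EA level.
#' @param phi0,lambda_km Kinship kernel: kinship at distance 0, decay km.
#' @param cline_strength Per-axis SD of per-SNP logit gradients (lat, lon).
#' @param n_chr,snps_per_chr,chr_length_bp Simulated genome dimensions.
#' @param pool_size Deme haplotype-pool size.
#' @param religion_prob Probability of being religious.
#' @param min_snps ROH minimum run length in SNPs.
#' @param n_perm Permutations for the R-squared change tests.
#' @param n_pcs Ancestry PCs to compute and include as covariates.
#' @param vif_window,vif_step,vif_threshold LD-pruning parameters.
#' @param genotype_prefix,covariate_path Input paths (real mode).
#' @param deme_nx,deme_ny,deme_spacing_km Deme grid dimensions.
#' @param prune Run LD pruning before ROH calling.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "real"),
                            seed = NULL,
                            n_families = 2000,
                            assortment_rho = 0.66,
                            migration_km_by_ea = c(19.2, 16.3, 28.7, 49.8),
                            phi0 = 0.0625,
                            lambda_km = 50,
                            cline_strength = c(0.8, 0.4),
                            n_chr = 5, snps_per_chr = 2000,
                            chr_length_bp = 30e6,
                            pool_size = 100,
                            religion_prob = 0.5,
                            min_snps = 65,
                            n_perm = 1000,
                            n_pcs = 3,
                            vif_window = 50, vif_step = 5, vif_threshold = 2,
                            genotype_prefix = NULL, covariate_path = NULL,
                            deme_nx = 10, deme_ny = 10, deme_spacing_km = 15,
                            prune = TRUE) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(seed))
    stop("seed is mandatory in simulate mode", call. = FALSE)
  if (mode == "real") {
    if (is.null(genotype_prefix) || is.null(covariate_path))
      stop("real mode needs genotype_prefix and covariate_path", call. = FALSE)
    for (f in c(paste0(genotype_prefix, ".bed"), covariate_path))
      if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Global-null pipeline configuration
#'
#' The default config with every generative effect switched off: no kinship
#' (`phi0 = 0`), no spatial allele-frequency structure (`cline = 0`), flat
#' migration means across EA levels, and no spousal assortment. Every
#' headline test should then be non-significant (or degenerate: with
#' `phi0 = 0` the simulated F_roh is identically zero and the regression
#' stages report `p = NA`, logged as "no outcome variation").
#'
#' @param seed Root seed.
#' @param ... Overrides passed to [pipeline_config()].
#' @export
null_config <- function(seed, ...) {
  pipeline_config(mode = "simulate", seed = seed,
                  assortment_rho = 0,
                  migration_km_by_ea = rep(26, 4),
                  phi0 = 0, cline_strength = c(0, 0), ...)
}

.cfg_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[order(names(unclass(cfg)))], f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or PLINK + covariate loading),
#' VIF LD pruning, ROH calling, F_roh, birthplace distances, migration
#' ANOVA and consecutive-level t-tests (table-1 shape), spouse-EA crosstab
#' (table-2 shape), mean F_roh per EA group (table-3 shape), regressions of
#' F_roh on own/paternal/maternal EA with covariates and permutation
#' R-squared change tests (table-4 shape), Sobel mediation tests of
#' parental EA through parental birthplace distance, and the moderated
#' PC-geography correlation fits. Sample counts and dropped-SNP counts per
#' stage are logged.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every table is written as
#'   TSV (with the config hash in a header comment) plus a plain-text log.
#' @return A `report_bundle` list: `table1_like`, `table2_like`,
#'   `table3_like`, `table4_like`, `mediation`, `pcgeo`, `froh`, `families`,
#'   `log`, `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  say("config hash: %s", .cfg_hash(cfg))

  # --- stage: cohort ----------------------------------------------------
  if (cfg$mode == "simulate") {
    dm <- build_deme_map(cfg$deme_nx, cfg$deme_ny, cfg$deme_spacing_km)
    fam <- simulate_families(
      cfg$n_families, assortment_rho = cfg$assortment_rho,
      migration_km_by_ea = cfg$migration_km_by_ea, deme_map = dm,
      religion_prob = cfg$religion_prob, seed = cfg$seed
    )
    snp_map <- build_snp_map(cfg$n_chr, cfg$snps_per_chr, cfg$chr_length_bp)
    sim <- simulate_genotypes(
      fam, snp_map, kinship_kernel = c(cfg$phi0, cfg$lambda_km),
      cline_strength = cfg$cline_strength, pool_size = cfg$pool_size,
      seed = cfg$seed + 1000L, deme_map = dm
    )
    G <- sim$genotypes
    truth <- sim$truth
    say("simulated %d families, %d SNPs (seed %d)",
        nrow(fam), ncol(G$calls), cfg$seed)
  } else {
    G <- read_plink_bed(cfg$genotype_prefix)
    fam <- utils::read.table(cfg$covariate_path, header = TRUE, sep = "\t")
    truth <- NULL
    say("loaded %d samples, %d SNPs from %s",
        nrow(G$calls), ncol(G$calls), cfg$genotype_prefix)
  }

  # --- stage: prune -> roh -> froh --------------------------------------
  if (isTRUE(cfg$prune)) {
    kept <- suppressMessages(
      vif_prune(G, cfg$vif_window, cfg$vif_step, cfg$vif_threshold))
    say("LD pruning kept %d of %d SNPs", length(kept), ncol(G$calls))
    Gp <- subset_snps(G, kept)
  } else {
    Gp <- G
    say("LD pruning skipped")
  }
  segs <- call_rohs(Gp, min_snps = cfg$min_snps)
  denom <- mappable_length(Gp$map)
  froh <- compute_froh(segs, denominator_bp = denom,
                       sample_ids = rownames(Gp$calls))
  say("%d ROH segments in %d of %d samples; denominator %.3g bp",
      nrow(segs), length(unique(segs$sample_id)), nrow(Gp$calls), denom)

  fam <- add_birthplace_distances(fam)
  fam$froh <- froh$froh[match(paste0("fam", fam$family_id), froh$sample_id)]
  if (cfg$mode == "real")
    fam$froh <- froh$froh[match(as.character(fam$family_id), froh$sample_id)]

  # --- stage: migration ANOVA (table 1 shape) ---------------------------
  t1 <- list()
  specs <- list(
    c("dist_fo_km", "father_ea", "father-offspring distance by paternal EA"),
    c("dist_mo_km", "mother_ea", "mother-offspring distance by maternal EA"),
    c("dist_fm_km", "father_ea", "father-mother distance by paternal EA"),
    c("dist_fm_km", "mother_ea", "father-mother distance by maternal EA")
  )
  for (s in specs) {
    an <- anova_by_level(fam[[s[1]]], fam[[s[2]]])
    tt <- consecutive_level_ttests(fam[[s[1]]], fam[[s[2]]])
    g <- an$groups
    g$analysis <- s[3]
    g$anova_F <- an$F; g$anova_p <- an$p
    g$t_vs_prev <- c(NA, tt$t); g$p_vs_prev <- c(NA, tt$p)
    t1[[s[3]]] <- g
    say("ANOVA %s: F = %.2f, p = %.3g (n = %d)", s[3], an$F, an$p,
        sum(g$n))
  }
  table1_like <- do.call(rbind, t1)
  rownames(table1_like) <- NULL

  # --- stage: assortment (table 2 shape) --------------------------------
  obs <- table(factor(fam$father_ea, 1:4), factor(fam$mother_ea, 1:4))
  ct <- contingency_chi2(unclass(obs))
  sp <- spearman_test(fam$father_ea, fam$mother_ea)
  table2_like <- list(observed = ct$observed, expected = ct$expected,
                      chi2 = ct$chi2, df = ct$df, p = ct$p,
                      spearman_rho = sp$rho, spearman_p = sp$p,
                      diagonal_share = ct$diagonal_share, n = ct$n)
  say("spouse-EA crosstab: chi2(%d) = %.2f, rho = %.3f, diag = %.1f%% (n = %d)",
      ct$df, ct$chi2, sp$rho, 100 * ct$diagonal_share, ct$n)

  # --- stage: F_roh by EA group (table 3 shape) -------------------------
  t3 <- lapply(c(offspring = "offspring_ea", paternal = "father_ea",
                 maternal = "mother_ea"), function(cl) {
    data.frame(level = 1:4,
               mean_froh = as.numeric(tapply(fam$froh, factor(fam[[cl]], 1:4),
                                             mean)),
               sd_froh = as.numeric(tapply(fam$froh, factor(fam[[cl]], 1:4),
                                           stats::sd)),
               n = as.integer(table(factor(fam[[cl]], 1:4))))
  })
  table3_like <- do.call(rbind, Map(function(d, nm) {
    d$ea_of <- nm; d
  }, t3, names(t3)))
  rownames(table3_like) <- NULL

  # --- stage: regressions + permutation tests (table 4 shape) -----------
  pca <- suppressMessages(standardized_pca(Gp, k = cfg$n_pcs))
  pcs <- as.data.frame(pca$scores)
  names(pcs) <- paste0("pc", seq_len(ncol(pcs)))
  reg_dat <- cbind(fam, pcs[match(paste0("fam", fam$family_id),
                                  rownames(pca$scores)), , drop = FALSE])
  base_cols <- c(paste0("pc", seq_len(cfg$n_pcs)), "religion", "city")

  degenerate <- stats::sd(reg_dat$froh, na.rm = TRUE) == 0
  if (degenerate)
    say("F_roh has no variation: regression and mediation stages report NA")

  t4 <- list(); med <- list()
  ea_specs <- c(offspring = "offspring_ea", paternal = "father_ea",
                maternal = "mother_ea")
  for (nm in names(ea_specs)) {
    cl <- ea_specs[[nm]]
    if (degenerate) {
      t4[[nm]] <- data.frame(ea_of = nm, beta_std_ea = NA_real_,
                             p_ea = NA_real_, r2_change = NA_real_,
                             empirical_p = NA_real_, n = nrow(reg_dat))
      next
    }
    X_base <- reg_dat[, base_cols]
    fit <- ols(reg_dat$froh, cbind(reg_dat[cl], X_base))
    pt <- r2_change_perm_test(reg_dat$froh, X_base, reg_dat[[cl]],
                              n_perm = cfg$n_perm,
                              seed = cfg$seed + 2000L + match(nm, names(ea_specs)))
    t4[[nm]] <- data.frame(ea_of = nm,
                           beta_std_ea = unname(fit$beta_std[cl]),
                           p_ea = unname(fit$p[cl]),
                           r2_change = pt$r2_change,
                           empirical_p = pt$empirical_p, n = fit$n)
    say("F_roh ~ %s EA: std beta = %.4f (p = %.3g), dR2 = %.4f (perm p = %.3g)",
        nm, t4[[nm]]$beta_std_ea, t4[[nm]]$p_ea, pt$r2_change, pt$empirical_p)
  }
  table4_like <- do.call(rbind, t4)
  rownames(table4_like) <- NULL

  # --- stage: mediation -------------------------------------------------
  for (nm in c("paternal", "maternal")) {
    cl <- ea_specs[[nm]]
    if (degenerate) {
      med[[nm]] <- data.frame(ea_of = nm, alpha = NA_real_, beta = NA_real_,
                              sobel_z = NA_real_, sobel_p = NA_real_,
                              tau_prime = NA_real_, tau_prime_p = NA_real_,
                              n = nrow(reg_dat))
      next
    }
    st <- sobel_test(reg_dat[[cl]], reg_dat$dist_fm_km, reg_dat$froh,
                     covariates = reg_dat[, base_cols])
    med[[nm]] <- data.frame(ea_of = nm, alpha = st$alpha, beta = st$beta,
                            sobel_z = st$sobel_z, sobel_p = st$sobel_p,
                            tau_prime = st$tau_prime,
                            tau_prime_p = st$tau_prime_p, n = st$n)
    say("mediation %s EA -> distance -> F_roh: sobel p = %.3g, tau' p = %.3g",
        nm, st$sobel_p, st$tau_prime_p)
  }
  mediation <- do.call(rbind, med)
  rownames(mediation) <- NULL

  # --- stage: PC-geography trend ----------------------------------------
  pg <- list()
  pg_specs <- list(c("pc1", "o_lat", "father_ea"),
                   c("pc1", "o_lat", "mother_ea"),
                   c("pc2", "o_lon", "father_ea"),
                   c("pc2", "o_lon", "mother_ea"))
  for (s in pg_specs) {
    fitted <- tryCatch(
      moderated_correlation_fit(reg_dat[[s[1]]], reg_dat[[s[2]]],
                                reg_dat[[s[3]]] - 1),
      error = function(e) NULL)
    r_all <- tryCatch(corr_pc_geo(reg_dat[[s[1]]], reg_dat[[s[2]]]),
                      error = function(e) NA_real_)
    pg[[paste(s, collapse = "_")]] <- data.frame(
      pc = s[1], coordinate = s[2], moderator = s[3],
      corr_overall = r_all,
      rho0 = if (is.null(fitted)) NA_real_ else fitted$rho0,
      rho1 = if (is.null(fitted)) NA_real_ else fitted$rho1,
      lrt_stat = if (is.null(fitted)) NA_real_ else fitted$lrt_stat,
      p = if (is.null(fitted)) NA_real_ else fitted$p,
      n = if (is.null(fitted)) NA_integer_ else fitted$n)
    if (!is.null(fitted))
      say("PC-geography trend %s ~ %s by %s: rho1 = %.3f (LRT p = %.3g)",
          s[1], s[2], s[3], fitted$rho1, fitted$p)
  }
  pcgeo <- do.call(rbind, pg)
  rownames(pcgeo) <- NULL

  bundle <- structure(list(
    table1_like = table1_like, table2_like = table2_like,
    table3_like = table3_like, table4_like = table4_like,
    mediation = mediation, pcgeo = pcgeo,
    froh = froh, families = fam, truth = truth,
    log = log, config_hash = .cfg_hash(cfg)
  ), class = "report_bundle")

  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle to TSV files
#'
#' Each table is written with a `# config: <hash>` header comment so that
#' re-runs of the same configuration are byte-identical.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# config: ", bundle$config_hash), con)
    utils::write.table(format(df, digits = 10), con, quote = FALSE,
                       sep = "\t", row.names = FALSE)
    close(con)
  }
  wt(bundle$table1_like, "table1_like")
  t2 <- bundle$table2_like
  t2df <- data.frame(statistic = c("chi2", "df", "p", "spearman_rho",
                                   "spearman_p", "diagonal_share", "n"),
                     value = c(t2$chi2, t2$df, t2$p, t2$spearman_rho,
                               t2$spearman_p, t2$diagonal_share, t2$n))
  wt(t2df, "table2_like")
  wt(bundle$table3_like, "table3_like")
  wt(bundle$table4_like, "table4_like")
  wt(bundle$mediation, "mediation")
  wt(bundle$pcgeo, "pcgeo")
  wt(bundle$froh, "froh")
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}
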