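# Spouse-EA contingency analysis, migration-distance ANOVA, and
# consecutive-level t-tests.

#' Published spouse educational-attainment cross-tabulation
#'
#' Observed counts of 2,058 Dutch spouse pairs by the father's (rows) and
#' mother's (columns) educational attainment on the four-level scale
#' (primary, secondary, higher secondary, tertiary). Used as a validation
#' input: the package's contingency statistics reproduce the published
#' chi-square, Spearman rank correlation, expected counts, and the share of
#' couples sharing a level.
#'
#' @return 4x4 integer matrix with dimnames.
#' @export
spouse_ea_crosstab <- function() {
  m <- matrix(c(273,  79,  11,   8,
                110, 528,  70,  24,
                 38, 190, 151,  31,
                 13, 120, 161, 251),
              nrow = 4, byrow = TRUE)
  lv <- c("primary", "secondary", "higher_secondary", "tertiary")
  dimnames(m) <- list(father = lv, mother = lv)
  m
}

#' Chi-square contingency analysis of a crosstab
#'
#' Pearson chi-square without continuity correction, expected counts under
#' independence, and for square tables the diagonal share (fraction of pairs
#' in the same category) and the Spearman rank correlation treating row and
#' column indices as ordinal levels. The statistic and expected counts are
#' exact; the p-value is the asymptotic chi-square tail, so judge it against
#' the returned expected counts when cells are sparse.
#'
#' @param observed Matrix of non-negative counts, at least 2x2, with
#'   positive row and column margins.
#' @return List (`crosstab_result`): `observed`, `expected`, `chi2`, `df`,
#'   `p`, `n`, `spearman_rho` and `diagonal_share` (square tables only,
#'   otherwise `NA`).
#' @export
contingency_chi2 <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2 || ncol(observed) < 2)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(observed < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("zero row/column margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  square <- nrow(observed) == ncol(observed)
  structure(list(
    observed = observed,
    expected = ct$expected,
    chi2 = unname(ct$statistic),
    df = unname(ct$parameter),
    p = ct$p.value,
    n = sum(observed),
    spearman_rho = if (square) spearman_midrank(table = observed) else NA_real_,
    diagonal_share = if (square) sum(diag(observed)) / sum(observed)
                     else NA_real_
  ), class = "crosstab_result")
}

#' Spearman rank correlation with midranks for ties
#'
#' Pearson correlation of midranks (average ranks within ties), either on
#' paired vectors or on a contingency table of counts (equivalent to
#' expanding the table to its pair list). The p-value uses the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Paired ordinal/numeric vectors (ignored if `table` given).
#' @param table Optional matrix of counts; rows score as row index, columns
#'   as column index.
#' @return For vectors/tables, the correlation (numeric). Use
#'   [spearman_test()] for the p-value.
#' @export
spearman_midrank <- function(x = NULL, y = NULL, table = NULL) {
  if (!is.null(table)) {
    P <- as.matrix(table) / sum(table)
    return(spearman_from_probs(P))
  }
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant vector: Spearman rho undefined", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Spearman correlation with t-approximation p-value
#'
#' @inheritParams spearman_midrank
#' @return List with `rho`, `n`, `statistic` (t), `p`.
#' @export
spearman_test <- function(x = NULL, y = NULL, table = NULL) {
  if (!is.null(table)) {
    rho <- spearman_midrank(table = table)
    n <- sum(table)
  } else {
    ok <- stats::complete.cases(x, y)
    rho <- spearman_midrank(x[ok], y[ok])
    n <- sum(ok)
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, n = n, statistic = tstat,
       p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' One-way ANOVA of distances by ordinal level
#'
#' Standard one-way decomposition of birthplace distance by EA level, with
#' the per-level summary (mean, SD, n) mirroring a migration-distance table.
#' Levels with fewer than 2 observations are excluded with a warning.
#'
#' @param values Numeric outcome (e.g. km distances).
#' @param levels Ordinal group labels (e.g. EA 1-4).
#' @return List (`anova_result`): `F`, `df1`, `df2`, `p`, and `groups`
#'   (data frame `level`, `mean`, `sd`, `n`).
#' @export
anova_by_level <- function(values, levels) {
  ok <- stats::complete.cases(values, levels)
  values <- values[ok]; levels <- levels[ok]
  cnt <- table(levels)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("excluding level(s) with n < 2: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(levels %in% small)
    values <- values[keep]; levels <- levels[keep]
  }
  if (length(unique(levels)) < 2)
    stop("need at least 2 non-empty groups", call. = FALSE)
  fit <- stats::lm(values ~ factor(levels))
  an <- stats::anova(fit)
  groups <- data.frame(
    level = sort(unique(levels)),
    mean = as.numeric(tapply(values, levels, mean)),
    sd = as.numeric(tapply(values, levels, stats::sd)),
    n = as.integer(table(levels))
  )
  structure(list(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                 p = an$`Pr(>F)`[1], groups = groups),
            class = "anova_result")
}

#' t-tests between consecutive ordinal levels
#'
#' Two-sample t-tests comparing the outcome between each pair of consecutive
#' levels (1 vs 2, 2 vs 3, 3 vs 4). Pooled-variance by default (the classic
#' default of the point-and-click statistics packages these analyses are
#' usually run in); Welch available with `var_equal = FALSE`.
#'
#' @inheritParams anova_by_level
#' @param var_equal Pooled-variance t-test if `TRUE` (default), else Welch.
#' @return Data frame: `level_a`, `level_b`, `t`, `df`, `p` (t is for
#'   level_b minus level_a).
#' @export
consecutive_level_ttests <- function(values, levels, var_equal = TRUE) {
  ok <- stats::complete.cases(values, levels)
  values <- values[ok]; levels <- levels[ok]
  lv <- sort(unique(levels))
  out <- list()
  for (k in seq_len(length(lv) - 1)) {
    a <- values[levels == lv[k]]
    b <- values[levels == lv[k + 1]]
    if (length(a) < 2 || length(b) < 2) {
      warning("skipping pair (", lv[k], ",", lv[k + 1], "): too few values",
              call. = FALSE)
      next
    }
    tt <- stats::t.test(b, a, var.equal = var_equal)
    out[[length(out) + 1]] <- data.frame(
      level_a = lv[k], level_b = lv[k + 1],
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
    )
  }
  do.call(rbind, out)
}
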