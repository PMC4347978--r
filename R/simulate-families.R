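# Two-generation family simulator: ordinal educational attainment (EA) with
# spousal assortment and education-dependent parental migration on a deme
# grid.

#' Default EA level marginals
#'
#' Marginal frequencies of the four EA levels (1 primary, 2 secondary,
#' 3 higher secondary, 4 tertiary) in a Dutch two-generation cohort:
#' father and mother margins from the 2,058-couple spouse cross-tabulation,
#' offspring margins from the genotyped generation.
#'
#' @param who `"father"`, `"mother"` or `"offspring"`.
#' @return Probability 4-vector.
#' @export
ea_marginals_default <- function(who = c("father", "mother", "offspring")) {
  who <- match.arg(who)
  switch(who,
    father    = c(371, 732, 410, 545) / 2058,
    mother    = c(434, 917, 393, 314) / 2058,
    offspring = c(74, 368, 659, 988) / 2089
  )
}

#' Simulate a two-generation cohort of families
#'
#' EA is generated through a Gaussian copula: father EA is a thresholded
#' standard normal with marginals `ea_marginals`; the mother's latent trait
#' correlates with the father's at the level needed so that the discretized
#' spousal Spearman rho equals `assortment_rho`; the offspring's latent trait
#' loads equally on both parents, calibrated so the parent-offspring
#' Spearman rho equals `parent_offspring_rho`.
#'
#' Geography is offspring-centric: each offspring is born in a uniformly
#' chosen deme, and each parent's birthplace is displaced from the
#' offspring's by an exponential radius with mean equal to that parent's
#' EA-specific migration scale (`migration_km_by_ea`), uniform bearing.
#' Hence the expected parent-offspring birthplace distance per parental EA
#' level equals the corresponding `migration_km_by_ea` entry, and the
#' father-mother distance grows with both parents' EA. Parental coordinates
#' are continuous (not snapped to demes) and must fall within the deme map's
#' declared bounding box (grid plus margin).
#'
#' Religion and city size are independent Bernoulli covariates by default;
#' `religion_ea_shift` adds an optional dependence of religion on father EA
#' on the logit scale.
#'
#' @param n_families Number of families.
#' @param ea_marginals Father EA marginals (4 probabilities summing to 1).
#' @param assortment_rho Target spousal Spearman rho on EA.
#' @param migration_km_by_ea Mean parent-offspring birthplace distance (km)
#'   for EA levels 1-4. Defaults to the paternal migration means of the
#'   study population.
#' @param deme_map Grid from [build_deme_map()].
#' @param religion_prob Baseline probability of being religious.
#' @param seed Integer seed; the simulation is fully reproducible given it.
#' @param mother_marginals,offspring_marginals EA marginals for mothers and
#'   offspring.
#' @param parent_offspring_rho Target parent-offspring Spearman rho on EA.
#' @param city_prob Probability of living in a large city.
#' @param religion_ea_shift Logit shift of religion probability per father
#'   EA level above 1 (default 0: independent).
#' @return A `data.frame` with columns `family_id`, `father_ea`, `mother_ea`,
#'   `offspring_ea`, `f_lat`, `f_lon`, `m_lat`, `m_lon`, `o_lat`, `o_lon`,
#'   `o_deme`, `religion`, `city`, `father_birth_year`, `mother_birth_year`,
#'   `offspring_birth_year`.
#' @export
simulate_families <- function(n_families,
                              ea_marginals = ea_marginals_default("father"),
                              assortment_rho = 0.66,
                              migration_km_by_ea = c(19.2, 16.3, 28.7, 49.8),
                              deme_map = build_deme_map(10, 10, 15),
                              religion_prob = 0.5,
                              seed = 1L,
                              mother_marginals = ea_marginals_default("mother"),
                              offspring_marginals = ea_marginals_default("offspring"),
                              parent_offspring_rho = 0.40,
                              city_prob = 0.5,
                              religion_ea_shift = 0) {
  stopifnot(n_families >= 1)
  if (abs(sum(ea_marginals) - 1) > 1e-8 || any(ea_marginals < 0))
    stop("ea_marginals must be non-negative and sum to 1", call. = FALSE)
  if (any(migration_km_by_ea < 0))
    stop("migration_km_by_ea must be non-negative", call. = FALSE)
  if (abs(assortment_rho) >= 1)
    stop("unreachable assortment target: |rho| must be < 1", call. = FALSE)

  set.seed(seed)

  # --- EA via Gaussian copula ------------------------------------------
  r_spouse <- copula_latent_rho(assortment_rho, ea_marginals, mother_marginals)
  r_po <- copula_latent_rho(parent_offspring_rho, ea_marginals,
                            offspring_marginals)
  load_c <- r_po / (1 + r_spouse)       # corr(Z_o, Z_f) = c * (1 + r_spouse)
  resid_var <- 1 - 2 * load_c^2 * (1 + r_spouse)
  if (resid_var < 0)
    stop("parent-offspring target incompatible with assortment target",
         call. = FALSE)

  zf <- stats::rnorm(n_families)
  zm <- r_spouse * zf + sqrt(1 - r_spouse^2) * stats::rnorm(n_families)
  zo <- load_c * (zf + zm) + sqrt(resid_var) * stats::rnorm(n_families)

  cut_levels <- function(z, marg) {
    thr <- stats::qnorm(cumsum(marg)[-length(marg)])
    findInterval(z, thr) + 1L
  }
  father_ea <- cut_levels(zf, ea_marginals)
  mother_ea <- cut_levels(zm, mother_marginals)
  offspring_ea <- cut_levels(zo, offspring_marginals)

  # --- geography --------------------------------------------------------
  o_deme <- sample(deme_map$deme_id, n_families, replace = TRUE)
  o_lat <- deme_map$lat[o_deme]
  o_lon <- deme_map$lon[o_deme]

  displace <- function(lat, lon, mean_km) {
    r <- stats::rexp(length(lat), rate = ifelse(mean_km > 0, 1 / mean_km, Inf))
    r[mean_km == 0] <- 0
    theta <- stats::runif(length(lat), 0, 2 * pi)
    deg_per_km <- 360 / (2 * pi * EARTH_RADIUS_KM)
    list(lat = lat + r * cos(theta) * deg_per_km,
         lon = lon + r * sin(theta) * deg_per_km / cos(lat * pi / 180))
  }
  f_bp <- displace(o_lat, o_lon, migration_km_by_ea[father_ea])
  m_bp <- displace(o_lat, o_lon, migration_km_by_ea[mother_ea])

  bbox <- attr(deme_map, "bbox")
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  f_bp$lat <- clamp(f_bp$lat, bbox["lat_min"], bbox["lat_max"])
  f_bp$lon <- clamp(f_bp$lon, bbox["lon_min"], bbox["lon_max"])
  m_bp$lat <- clamp(m_bp$lat, bbox["lat_min"], bbox["lat_max"])
  m_bp$lon <- clamp(m_bp$lon, bbox["lon_min"], bbox["lon_max"])

  # --- other covariates -------------------------------------------------
  p_rel <- stats::plogis(stats::qlogis(religion_prob) +
                           religion_ea_shift * (father_ea - 1))
  religion <- stats::rbinom(n_families, 1, p_rel)
  city <- stats::rbinom(n_families, 1, city_prob)
  offspring_birth_year <- round(stats::rnorm(n_families, 1970, 8))
  father_birth_year <- offspring_birth_year - round(stats::rnorm(n_families, 30, 4))
  mother_birth_year <- offspring_birth_year - round(stats::rnorm(n_families, 28, 4))

  out <- data.frame(
    family_id = seq_len(n_families),
    father_ea = father_ea, mother_ea = mother_ea, offspring_ea = offspring_ea,
    f_lat = f_bp$lat, f_lon = f_bp$lon,
    m_lat = m_bp$lat, m_lon = m_bp$lon,
    o_lat = o_lat, o_lon = o_lon, o_deme = o_deme,
    religion = religion, city = city,
    father_birth_year = father_birth_year,
    mother_birth_year = mother_birth_year,
    offspring_birth_year = offspring_birth_year
  )
  attr(out, "latent_rho_spouse") <- r_spouse
  attr(out, "latent_rho_parent_offspring") <- r_po
  out
}

#' Validate a family table against its deme map
#'
#' Checks the structural invariants of the covariate table: EA levels in
#' 1..4, offspring coordinates inside the deme grid, parental coordinates
#' inside the declared bounding box (grid plus margin), no missing values.
#'
#' @param families Family table.
#' @param deme_map The deme grid the table was simulated on.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_family_table <- function(families, deme_map) {
  ea_cols <- c("father_ea", "mother_ea", "offspring_ea")
  for (cl in ea_cols)
    if (!all(families[[cl]] %in% 1:4))
      stop(sprintf("%s outside 1..4", cl), call. = FALSE)
  if (anyNA(families)) stop("missing values in family table", call. = FALSE)
  g <- attr(deme_map, "grid_bbox"); b <- attr(deme_map, "bbox")
  eps <- 1e-9
  if (any(families$o_lat < g["lat_min"] - eps | families$o_lat > g["lat_max"] + eps |
          families$o_lon < g["lon_min"] - eps | families$o_lon > g["lon_max"] + eps))
    stop("offspring birthplace outside deme grid", call. = FALSE)
  par_lat <- c(families$f_lat, families$m_lat)
  par_lon <- c(families$f_lon, families$m_lon)
  if (any(par_lat < b["lat_min"] - eps | par_lat > b["lat_max"] + eps |
          par_lon < b["lon_min"] - eps | par_lon > b["lon_max"] + eps))
    stop("parental birthplace outside declared bounding box", call. = FALSE)
  invisible(TRUE)
}
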