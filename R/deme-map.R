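# Regular deme grid standing in for national birthplace geography.

#' Build a regular grid of demes
#'
#' Lays out `n_x * n_y` demes on a regular grid with a fixed great-circle
#' spacing between east-west neighbours and between north-south neighbours.
#' Latitude steps are `spacing_km / 111.194...` degrees (one degree of
#' latitude on a 6371-km sphere); longitude steps are widened by
#' `1 / cos(latitude)` so that east-west neighbour distances stay close to
#' `spacing_km` across the grid.
#'
#' @param n_x,n_y Grid dimensions (columns run west-east, rows south-north).
#' @param spacing_km Neighbour spacing in kilometers.
#' @param origin Numeric `(lat, lon)` of the south-west deme.
#' @param margin_km Margin added around the grid when declaring the bounding
#'   box used for coordinate validation; parents displaced off the grid must
#'   stay inside this box. Default 250 km.
#' @return A `deme_map`: data frame with `deme_id`, `lat`, `lon`, `ix`, `iy`
#'   plus attributes `spacing_km` and `bbox` (lat/lon limits incl. margin).
#' @export
build_deme_map <- function(n_x, n_y, spacing_km, origin = c(52.0, 5.0),
                           margin_km = 250) {
  if (length(n_x) != 1 || length(n_y) != 1 || n_x < 1 || n_y < 1 ||
      n_x != round(n_x) || n_y != round(n_y))
    stop("n_x and n_y must be positive integers", call. = FALSE)
  if (!is.numeric(spacing_km) || spacing_km <= 0)
    stop("spacing_km must be positive", call. = FALSE)
  check_coords(origin[1], origin[2])

  deg_per_km_lat <- 360 / (2 * pi * EARTH_RADIUS_KM)
  lat0 <- origin[1]
  mid_lat <- lat0 + (n_y - 1) * spacing_km * deg_per_km_lat / 2
  dlat <- spacing_km * deg_per_km_lat

  grid <- expand.grid(ix = seq_len(n_x), iy = seq_len(n_y))
  row_lat <- lat0 + (grid$iy - 1) * dlat
  # per-row longitude step keeps east-west neighbour distances at
  # spacing_km on every row (rows are slightly sheared, not a lon-lattice)
  dlon_row <- spacing_km * deg_per_km_lat / cos(row_lat * pi / 180)
  demes <- data.frame(
    deme_id = seq_len(nrow(grid)),
    lat = row_lat,
    lon = origin[2] + (grid$ix - 1) * dlon_row,
    ix = grid$ix, iy = grid$iy
  )
  margin_lat <- margin_km * deg_per_km_lat
  margin_lon <- margin_km * deg_per_km_lat / cos(mid_lat * pi / 180)
  attr(demes, "spacing_km") <- spacing_km
  attr(demes, "bbox") <- c(
    lat_min = min(demes$lat) - margin_lat, lat_max = max(demes$lat) + margin_lat,
    lon_min = min(demes$lon) - margin_lon, lon_max = max(demes$lon) + margin_lon
  )
  attr(demes, "grid_bbox") <- c(
    lat_min = min(demes$lat), lat_max = max(demes$lat),
    lon_min = min(demes$lon), lon_max = max(demes$lon)
  )
  class(demes) <- c("deme_map", "data.frame")
  demes
}

#' Index of the deme nearest to each coordinate
#'
#' @param deme_map A [build_deme_map()] grid.
#' @param lat,lon Coordinate vectors.
#' @return Integer vector of `deme_id`s.
#' @export
nearest_deme <- function(deme_map, lat, lon) {
  # equirectangular metric is exact enough for nearest-neighbour on a
  # grid a few degrees across
  mid_lat <- mean(range(deme_map$lat))
  w <- cos(mid_lat * pi / 180)^2
  vapply(seq_along(lat), function(i) {
    d2 <- (deme_map$lat - lat[i])^2 + w * (deme_map$lon - lon[i])^2
    deme_map$deme_id[which.min(d2)]
  }, integer(1))
}
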