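# Great-circle distances between birthplaces.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance between two points
#'
#' Spherical law of cosines distance on a sphere of radius 6371.0 km, the
#' classic formula used by simple geodata scripts for distances between
#' town coordinates. The arccos argument is clamped to \[-1, 1\] so that
#' identical and antipodal points do not produce NaN from rounding.
#'
#' Inputs are recycled, so vectors of coordinates give a vector of
#' distances.
#'
#' @param lat1,lon1 Latitude/longitude of the first point, decimal degrees.
#' @param lat2,lon2 Latitude/longitude of the second point, decimal degrees.
#' @return Distance(s) in kilometers.
#' @examples
#' great_circle_km(52.37, 4.90, 51.92, 4.48) # Amsterdam - Rotterdam, ~58 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  phi1 <- lat1 * pi / 180
  phi2 <- lat2 * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  x <- sin(phi1) * sin(phi2) + cos(phi1) * cos(phi2) * cos(dlam)
  EARTH_RADIUS_KM * acos(pmin(1, pmax(-1, x)))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("coordinates must be finite", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude out of range [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop("longitude out of range [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Add birthplace-distance columns to a family table
#'
#' Computes the three pairwise great-circle distances used throughout the
#' analyses: father-mother (the parental birthplace distance), father-offspring
#' and mother-offspring (parental migration distances relative to the
#' offspring's birthplace).
#'
#' @param families A family table as returned by [simulate_families()] (needs
#'   columns `f_lat, f_lon, m_lat, m_lon, o_lat, o_lon`).
#' @return The table with columns `dist_fm_km`, `dist_fo_km`, `dist_mo_km`
#'   appended.
#' @export
add_birthplace_distances <- function(families) {
  families$dist_fm_km <- great_circle_km(families$f_lat, families$f_lon,
                                         families$m_lat, families$m_lon)
  families$dist_fo_km <- great_circle_km(families$f_lat, families$f_lon,
                                         families$o_lat, families$o_lon)
  families$dist_mo_km <- great_circle_km(families$m_lat, families$m_lon,
                                         families$o_lat, families$o_lon)
  families
}
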