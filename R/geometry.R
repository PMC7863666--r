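#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of radius 6371 km. Inputs are
#' WGS84 decimal degrees and are recycled to a common length, so the function
#' works both for scalar pairs and for aligned coordinate vectors.
#'
#' @param lat1,lon1 Latitude/longitude of the first point(s), decimal degrees.
#' @param lat2,lon2 Latitude/longitude of the second point(s), decimal degrees.
#' @return Numeric vector of distances in km. Zero iff the two points coincide.
#' @examples
#' haversine_km(45, -89, 46, -89) # one degree of latitude, ~111.19 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6371000) / 1000
}

#' Initial great-circle bearing
#'
#' Bearing from an origin to a destination, degrees clockwise from north in
#' \[0, 360). Coincident points have no defined bearing and raise an error.
#'
#' @inheritParams haversine_km
#' @return Numeric vector of bearings in degrees, in \[0, 360).
#' @export
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  if (any(p1[, 1] == p2[, 1] & p1[, 2] == p2[, 2])) {
    stop("bearing is undefined for coincident points", call. = FALSE)
  }
  geosphere::bearing(p1, p2) %% 360
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite numbers", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(lon < -180 | lon > 180)) {
    stop("longitude out of range [-180, 180]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pairwise great-circle distance matrix for a lake table
#'
#' @param lakes A lake table (see [read_lake_table()]).
#' @return Symmetric matrix of distances in km, dimnames = lake ids.
#' @export
lake_distance_matrix <- function(lakes) {
  n <- nrow(lakes)
  d <- matrix(0, n, n, dimnames = list(lakes$lake_id, lakes$lake_id))
  if (n < 2) return(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  v <- haversine_km(lakes$lat[idx[, 1]], lakes$lon[idx[, 1]],
                    lakes$lat[idx[, 2]], lakes$lon[idx[, 2]])
  d[idx] <- v
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# Local tangent-plane conversion used by the landscape generator: planar km
# offsets about a reference origin mapped to lat/lon. Adequate for study-scale
# extents (tens of km), where the error against haversine is < 1%.
km_to_latlon <- function(x_km, y_km, origin_lat = 45.7, origin_lon = -89.5) {
  km_per_deg_lat <- pi * 6371 / 180
  lat <- origin_lat + y_km / km_per_deg_lat
  lon <- origin_lon + x_km / (km_per_deg_lat * cos(origin_lat * pi / 180))
  data.frame(lat = lat, lon = lon)
}
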