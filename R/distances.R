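#' Great-circle distance between points (haversine)
#'
#' All ground distances in windowscape are great-circle distances on a sphere
#' of radius 6371 km (WGS84 lon/lat in decimal degrees, no projection).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees; vectors are
#'   recycled elementwise.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 90)  # quarter meridian, ~10007.5 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(is.numeric(lon1), is.numeric(lat1), is.numeric(lon2), is.numeric(lat2))
  check_lonlat(c(lon1, lon2), c(lat1, lat2))
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * r * asin(sqrt(a))
}

check_lonlat <- function(lon, lat) {
  ok <- is.na(lon) | is.na(lat) |
    (lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90)
  if (!all(ok)) {
    stop("invalid coordinates: lon must lie in [-180, 180], lat in [-90, 90]")
  }
  invisible(TRUE)
}

#' Pairwise great-circle distance matrix
#'
#' @param lon,lat Coordinate vectors (decimal degrees).
#' @param labels Optional point labels (defaults to seq_along).
#' @return A symmetric `n x n` matrix of distances in km with zero diagonal.
#' @export
geographic_distance <- function(lon, lat, labels = NULL) {
  n <- length(lon)
  if (n < 2) stop("need at least 2 locations")
  if (length(lat) != n) stop("lon and lat must have equal length")
  if (anyNA(lon) || anyNA(lat)) stop("invalid coordinates: NA not allowed")
  check_lonlat(lon, lat)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  to_rad <- pi / 180
  phi <- lat * to_rad
  lam <- lon * to_rad
  # haversine via outer sums; numerically identical to the scalar form
  sdlat <- sin(outer(phi, phi, "-") / 2)^2
  sdlon <- sin(outer(lam, lam, "-") / 2)^2
  a <- sdlat + outer(cos(phi), cos(phi)) * sdlon
  a <- pmin(pmax(a, 0), 1)   # first arg keeps the dim attribute
  d <- 2 * 6371 * asin(sqrt(a))
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  d
}
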