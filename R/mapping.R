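#' Inverse-distance-weighted interpolation onto a raster grid
#'
#' Each output cell takes the weighted mean of the `k` nearest finite-valued
#' points within `radius_km`, with weights d^(-power); a cell whose center
#' coincides with a data point (distance < 1e-9 km) gets that point's value
#' exactly. Cells with no usable point become NoData. Output values are a
#' convex combination of inputs, hence bounded by their range.
#'
#' @param lon,lat,values Data points (NA values are dropped).
#' @param template A `land_raster` supplying the output grid (its values are
#'   ignored except that NoData cells stay NoData).
#' @param power IDW exponent (default 2).
#' @param k Number of nearest neighbors to use (default 12).
#' @param radius_km Search radius (default Inf).
#' @return A `land_raster` on the template grid.
#' @export
idw_interpolate <- function(lon, lat, values, template, power = 2, k = 12,
                            radius_km = Inf) {
  stopifnot(inherits(template, "land_raster"), power > 0, k >= 1)
  ok <- is.finite(values)
  if (!any(ok)) {
    return(land_raster(matrix(NA_real_, nrow(template$values), ncol(template$values)),
                       template$xll, template$yll, template$cellsize))
  }
  lon <- lon[ok]; lat <- lat[ok]; values <- values[ok]
  cc <- raster_cell_centers(template)
  out <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  mask <- is.finite(template$values) | is.na(template$values) # interpolate everywhere
  for (i in seq_len(nrow(cc))) {
    d <- haversine_km(cc$lon[i], cc$lat[i], lon, lat)
    hit <- which(d < 1e-9)
    if (length(hit) > 0) { out[cc$cell[i]] <- values[hit[1]]; next }
    use <- which(d <= radius_km)
    if (length(use) == 0) next
    use <- use[order(d[use])][seq_len(min(k, length(use)))]
    w <- d[use]^(-power)
    out[cc$cell[i]] <- sum(w * values[use]) / sum(w)
  }
  land_raster(out, template$xll, template$yll, template$cellsize)
}
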