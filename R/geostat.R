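# Empirical semivariogram and exponential model fit, used to read off the
# spatial scales of genetic structure from PCA axis-1 scores.

#' Empirical semivariogram
#'
#' For each distance bin \[k*w, (k+1)*w) the semivariance is half the mean
#' squared difference of the variable over all point pairs whose great-circle
#' separation falls in the bin. Empty bins are reported with `N = 0` and
#' `gamma = NA`.
#'
#' @param values Numeric vector, one value per location.
#' @param lon,lat Location coordinates (decimal degrees).
#' @param lag_width_km Bin width in km (default 50).
#' @param max_dist_km Upper distance limit; defaults to the maximum pairwise
#'   distance (so every pair is binned).
#' @return Data frame of class `variogram` with columns `h` (bin center, km),
#'   `gamma`, `n_pairs`; attributes `lag_width_km`, `max_dist_km`.
#' @export
empirical_variogram <- function(values, lon, lat, lag_width_km = 50,
                                max_dist_km = NULL) {
  n <- length(values)
  stopifnot(n >= 2, length(lon) == n, length(lat) == n, lag_width_km > 0)
  d <- geographic_distance(lon, lat)
  dv <- d[lower.tri(d)]
  sq <- outer(values, values, "-")[lower.tri(d)]^2
  if (is.null(max_dist_km)) max_dist_km <- max(dv)
  keep <- dv <= max_dist_km
  if (!any(keep)) warning("all pairs beyond max_dist_km; variogram is empty")
  n_bins <- max(1L, ceiling(max_dist_km / lag_width_km))
  bin <- pmin(floor(dv[keep] / lag_width_km), n_bins - 1L) + 1L
  # pairs exactly at a bin's upper edge beyond the last bin are clamped into it
  bin[dv[keep] >= n_bins * lag_width_km] <- n_bins
  cnt <- tabulate(bin, nbins = n_bins)
  ssq <- vapply(seq_len(n_bins), function(k) sum(sq[keep][bin == k]), 0)
  gamma <- ifelse(cnt > 0, ssq / (2 * cnt), NA_real_)
  out <- data.frame(h = (seq_len(n_bins) - 0.5) * lag_width_km,
                    gamma = gamma, n_pairs = cnt)
  attr(out, "lag_width_km") <- lag_width_km
  attr(out, "max_dist_km") <- max_dist_km
  class(out) <- c("variogram", "data.frame")
  out
}

#' Fit an exponential variogram model
#'
#' Weighted least squares (weights = pair counts) fit of
#' gamma(h) = nugget + sill * (1 - exp(-h / range)); all three parameters are
#' constrained non-negative.
#'
#' @param vgm A `variogram` from [empirical_variogram()] with >= 4 non-empty
#'   bins.
#' @return Named numeric vector `c(nugget, sill, range)` (km for range).
#' @export
fit_exponential <- function(vgm) {
  ok <- vgm$n_pairs > 0 & is.finite(vgm$gamma)
  if (sum(ok) < 4) stop("need at least 4 non-empty bins to fit")
  df <- vgm[ok, ]
  g_lo <- min(df$gamma); g_hi <- max(df$gamma)
  start <- list(nugget = g_lo, sill = max(g_hi - g_lo, 1e-8),
                range = max(stats::median(df$h), 1e-6))
  # warnOnly: nls flags exact (zero-residual) fits as "singular convergence";
  # we judge the fit by its achieved weighted residuals instead
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(gamma ~ nugget + sill * (1 - exp(-h / range)),
                 data = df, weights = df$n_pairs, start = start,
                 algorithm = "port",
                 lower = c(nugget = 0, sill = 0, range = 1e-9),
                 control = stats::nls.control(maxiter = 500, warnOnly = TRUE))
    ),
    error = function(e) {
      stop("exponential variogram fit did not converge: ", conditionMessage(e),
           sprintf(" [bins=%d, gamma range %.3g..%.3g]", nrow(df), g_lo, g_hi))
    }
  )
  wrss <- sum(df$n_pairs * stats::resid(fit)^2)
  wtss <- sum(df$n_pairs * (df$gamma - stats::weighted.mean(df$gamma, df$n_pairs))^2)
  if (!fit$convInfo$isConv && wtss > 0 && wrss > wtss) {
    stop(sprintf("exponential variogram fit did not converge (weighted RSS %.3g > TSS %.3g, bins=%d)",
                 wrss, wtss, nrow(df)))
  }
  stats::coef(fit)[c("nugget", "sill", "range")]
}
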