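# Multi-scale, multi-site sliding windows: generation, per-window analysis,
# aggregation by scale, per-individual support surfaces and environmental
# heterogeneity comparisons.

#' Generate circular study-area windows
#'
#' One candidate window per (center location, diameter); an individual is a
#' member when its great-circle distance to the center is at most
#' diameter / 2. Candidates containing fewer than `min_demes` distinct demes
#' are dropped (logged in the `dropped` attribute).
#'
#' @param locations Data frame with `location_id`, `lon`, `lat` (window
#'   centers, typically the sampling locations).
#' @param diameters Numeric vector of diameters (km).
#' @param individuals Data frame with `individual_id`, `deme_id`, `lon`, `lat`.
#' @param min_demes Minimum distinct demes per retained window (default 3).
#' @return List of `window` objects (fields `window_id`, `location_id`,
#'   `center_lon`, `center_lat`, `diameter_km`, `members`, `n_demes`);
#'   attributes `n_candidates` and `dropped`.
#' @export
generate_windows <- function(locations, diameters, individuals, min_demes = 3) {
  stopifnot(nrow(locations) >= 1, length(diameters) >= 1)
  need <- c("individual_id", "deme_id", "lon", "lat")
  stopifnot(all(c("location_id", "lon", "lat") %in% names(locations)),
            all(need %in% names(individuals)))
  windows <- list()
  dropped <- list()
  for (i in seq_len(nrow(locations))) {
    d_ind <- haversine_km(locations$lon[i], locations$lat[i],
                          individuals$lon, individuals$lat)
    for (diam in diameters) {
      members <- individuals$individual_id[d_ind <= diam / 2]
      demes <- unique(individuals$deme_id[d_ind <= diam / 2])
      w <- list(window_id = sprintf("%s_d%04d", locations$location_id[i], as.integer(diam)),
                location_id = as.character(locations$location_id[i]),
                center_lon = locations$lon[i], center_lat = locations$lat[i],
                diameter_km = diam, members = members,
                n_demes = length(demes))
      class(w) <- "window"
      if (length(demes) >= min_demes) {
        windows[[length(windows) + 1]] <- w
      } else {
        dropped[[length(dropped) + 1]] <-
          data.frame(window_id = w$window_id, n_demes = w$n_demes,
                     reason = sprintf("fewer than %d demes", min_demes))
      }
    }
  }
  if (length(windows) == 0) warning("no window satisfies the min_demes constraint")
  attr(windows, "n_candidates") <- nrow(locations) * length(diameters)
  attr(windows, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  windows
}

# deterministic per-window seed derived from the global seed (< 2^31)
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647L)
}

#' Analyze one window
#'
#' Subsets the global matrices to the window's members (matrices are never
#' recomputed per window) and runs, per scenario, the partial Mantel tests
#' G ~ IBR | IBD and G ~ IBD | IBR plus the support criterion; also the
#' simple Mantel test G ~ IBD, and optionally a commonality analysis.
#'
#' @param window A `window`.
#' @param G Genetic distance matrix covering all members.
#' @param IBD Geographic distance matrix.
#' @param IBR Named list of resistance distance matrices (one per scenario).
#' @param config A `run_config`.
#' @param seed RNG seed for this window (default derived from `config$seed`).
#' @param run_commonality Also run [commonality()] on all scenarios?
#' @return List of class `window_result`: `window`, `testable`, `ibd`
#'   (mantel_result), `scenarios` (per scenario: the two partial tests and
#'   the `support_decision`), `n`, optionally `commonality`.
#' @export
run_window <- function(window, G, IBD, IBR, config, seed = NULL,
                       run_commonality = FALSE) {
  stopifnot(inherits(window, "window"), inherits(config, "run_config"))
  ids <- window$members
  if (length(ids) < 4) {
    return(untestable_result(window, "fewer than 4 members"))
  }
  g <- subset_pairwise(G, ids)
  ibd <- subset_pairwise(IBD, ids)
  if (is.null(seed)) seed <- config$seed
  if (stats::sd(lower_tri(g)) == 0 || stats::sd(lower_tri(ibd)) == 0) {
    return(untestable_result(window, "zero-variance distance matrix"))
  }
  ibd_res <- mantel_test(g, ibd, n_perm = config$n_permutations,
                         seed = derive_seed(seed, 0))
  scen <- list()
  for (k in seq_along(config$scenarios)) {
    s <- config$scenarios[k]
    if (!s %in% names(IBR)) stop("IBR matrix missing for scenario ", s)
    x <- subset_pairwise(IBR[[s]], ids)
    if (stats::sd(lower_tri(x)) == 0 || any(!is.finite(lower_tri(x)))) {
      scen[[s]] <- list(testable = FALSE)
      next
    }
    ibr_ibd <- partial_mantel(g, x, ibd, n_perm = config$n_permutations,
                              seed = derive_seed(seed, 2 * k - 1))
    ibd_ibr <- partial_mantel(g, ibd, x, n_perm = config$n_permutations,
                              seed = derive_seed(seed, 2 * k))
    scen[[s]] <- list(testable = TRUE,
                      ibr_given_ibd = ibr_ibd, ibd_given_ibr = ibd_ibr,
                      support = support_criterion(ibr_ibd$p, ibd_ibr$p,
                                                  config$alpha, hypothesis = s))
  }
  res <- list(window = window, testable = TRUE, ibd = ibd_res,
              scenarios = scen, n = length(ids))
  if (run_commonality) {
    preds <- lapply(config$scenarios, function(s) subset_pairwise(IBR[[s]], ids))
    names(preds) <- config$scenarios
    res$commonality <- tryCatch(suppressWarnings(commonality(g, preds)),
                                error = function(e) NULL)
  }
  class(res) <- "window_result"
  res
}

untestable_result <- function(window, reason) {
  structure(list(window = window, testable = FALSE, reason = reason,
                 ibd = NULL, scenarios = list(), n = length(window$members)),
            class = "window_result")
}

#' Analyze a list of windows
#'
#' Runs [run_window()] over all windows with deterministic per-window seeds
#' derived from `config$seed`.
#'
#' @inheritParams run_window
#' @param windows List of `window` objects from [generate_windows()].
#' @return List of `window_result`.
#' @export
run_windows <- function(windows, G, IBD, IBR, config, run_commonality = FALSE) {
  lapply(seq_along(windows), function(i) {
    run_window(windows[[i]], G, IBD, IBR, config,
               seed = derive_seed(config$seed, i),
               run_commonality = run_commonality)
  })
}

#' Summarize window results by scale
#'
#' Per diameter and hypothesis: the percentage of testable windows with a
#' supported IBR hypothesis and the mean partial Mantel r (IBR | IBD) over
#' the supported windows only; for IBD, the percentage of testable windows
#' with a significant simple Mantel test and the mean r among those.
#'
#' @param results List of `window_result`.
#' @param alpha Significance level for the IBD rows (default 0.05).
#' @return Data frame with columns `diameter_km`, `hypothesis`, `n_windows`
#'   (testable), `n_supported`, `pct_supported`, `mean_r`.
#' @export
summarize_by_scale <- function(results, alpha = 0.05) {
  testable <- Filter(function(r) isTRUE(r$testable), results)
  if (length(testable) == 0) stop("no testable window")
  diams <- sort(unique(vapply(testable, function(r) r$window$diameter_km, 0)))
  hyps <- unique(unlist(lapply(testable, function(r) names(r$scenarios))))
  rows <- list()
  for (d in diams) {
    at_d <- Filter(function(r) r$window$diameter_km == d, testable)
    for (h in hyps) {
      sc <- lapply(at_d, function(r) r$scenarios[[h]])
      sc <- Filter(function(s) !is.null(s) && isTRUE(s$testable), sc)
      supp <- Filter(function(s) s$support$supported, sc)
      rows[[length(rows) + 1]] <- data.frame(
        diameter_km = d, hypothesis = h,
        n_windows = length(sc), n_supported = length(supp),
        pct_supported = if (length(sc)) 100 * length(supp) / length(sc) else NA_real_,
        mean_r = if (length(supp)) {
          mean(vapply(supp, function(s) s$ibr_given_ibd$r, 0))
        } else NA_real_
      )
    }
    sig <- Filter(function(r) r$ibd$p < alpha, at_d)
    rows[[length(rows) + 1]] <- data.frame(
      diameter_km = d, hypothesis = "IBD",
      n_windows = length(at_d), n_supported = length(sig),
      pct_supported = 100 * length(sig) / length(at_d),
      mean_r = if (length(sig)) mean(vapply(sig, function(r) r$ibd$r, 0)) else NA_real_
    )
  }
  do.call(rbind, rows)
}

#' Per-individual support surface with overlap correction
#'
#' For each individual and hypothesis, the number of supported windows
#' containing the individual divided by the number of testable windows
#' containing it (the correction for overlapping windows: individuals
#' covered by many windows are normalized by their exposure). Restricted to
#' windows whose diameter lies in `scale_band`.
#'
#' @param results List of `window_result`.
#' @param individuals Data frame with `individual_id` (and coordinates, which
#'   are carried through for mapping).
#' @param scale_band Length-2 numeric, inclusive diameter band (default
#'   c(220, 600)).
#' @return Data frame: `individual_id`, `lon`, `lat`, one column per
#'   hypothesis with the corrected support value in \[0, 1\] (NA when the
#'   individual occurs in no testable window of the band).
#' @export
support_surface <- function(results, individuals, scale_band = c(220, 600)) {
  stopifnot(length(scale_band) == 2, scale_band[1] <= scale_band[2])
  in_band <- Filter(function(r) {
    isTRUE(r$testable) &&
      r$window$diameter_km >= scale_band[1] &&
      r$window$diameter_km <= scale_band[2]
  }, results)
  hyps <- unique(unlist(lapply(in_band, function(r) names(r$scenarios))))
  ids <- individuals$individual_id
  out <- individuals[, intersect(c("individual_id", "lon", "lat"), names(individuals)),
                     drop = FALSE]
  for (h in hyps) {
    n_test <- n_supp <- stats::setNames(numeric(length(ids)), ids)
    for (r in in_band) {
      s <- r$scenarios[[h]]
      if (is.null(s) || !isTRUE(s$testable)) next
      m <- intersect(r$window$members, ids)
      n_test[m] <- n_test[m] + 1
      if (s$support$supported) n_supp[m] <- n_supp[m] + 1
    }
    out[[h]] <- ifelse(n_test > 0, n_supp / n_test, NA_real_)
  }
  out
}

#' Environmental heterogeneity of supported vs non-supported windows
#'
#' The SD (population form) of the conductance raster's valid cells inside
#' each window circle, averaged per scale over windows with and without
#' support for each hypothesis.
#'
#' @param results List of `window_result`.
#' @param rasters Named list of conductance `land_raster`s, one per
#'   hypothesis appearing in the results.
#' @return Data frame: `diameter_km`, `hypothesis`, `mean_sd_supported`,
#'   `mean_sd_unsupported`, `n_supported`, `n_unsupported`.
#' @export
env_heterogeneity <- function(results, rasters) {
  testable <- Filter(function(r) isTRUE(r$testable), results)
  if (length(testable) == 0) stop("no testable window")
  hyps <- intersect(unique(unlist(lapply(testable, function(r) names(r$scenarios)))),
                    names(rasters))
  sds <- new.env()
  window_sd <- function(r, h) {
    key <- paste(r$window$window_id, h)
    if (!is.null(sds[[key]])) return(sds[[key]])
    v <- raster_window_sd(rasters[[h]], r$window$center_lon, r$window$center_lat,
                          r$window$diameter_km / 2)$sd
    sds[[key]] <- v
    v
  }
  diams <- sort(unique(vapply(testable, function(r) r$window$diameter_km, 0)))
  rows <- list()
  for (d in diams) {
    at_d <- Filter(function(r) r$window$diameter_km == d, testable)
    for (h in hyps) {
      ok <- Filter(function(r) isTRUE(r$scenarios[[h]]$testable), at_d)
      supp <- vapply(ok, function(r) r$scenarios[[h]]$support$supported, TRUE)
      sd_all <- vapply(ok, window_sd, 0, h = h)
      rows[[length(rows) + 1]] <- data.frame(
        diameter_km = d, hypothesis = h,
        mean_sd_supported = if (any(supp)) mean(sd_all[supp], na.rm = TRUE) else NA_real_,
        mean_sd_unsupported = if (any(!supp)) mean(sd_all[!supp], na.rm = TRUE) else NA_real_,
        n_supported = sum(supp), n_unsupported = sum(!supp)
      )
    }
  }
  do.call(rbind, rows)
}
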