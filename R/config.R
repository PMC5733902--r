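#' Run configuration
#'
#' Bundles the tunable parameters of a sliding-window analysis. Defaults
#' follow the reference design: circular study areas of 220-1,000 km diameter
#' in 20-km steps centered on every sampling location, 999 permutations,
#' alpha = 0.05, at least 3 demes per window, 8-neighbor lattice
#' connectivity, IDW power 2, 50-km variogram lags.
#'
#' @param scenarios Character vector of IBR scenarios to test.
#' @param diameter_min,diameter_max,diameter_step Window diameters (km).
#' @param n_permutations Mantel permutations (>= 99).
#' @param alpha Significance level in (0, 1).
#' @param min_demes Minimum demes per window.
#' @param seed Global RNG seed (per-window seeds are derived from it).
#' @param connectivity Lattice connectivity, 4 or 8.
#' @param idw_power IDW exponent.
#' @param variogram_lag_km Variogram bin width (km).
#' @return List of class `run_config`.
#' @export
run_config <- function(scenarios = c("T", "E", "Pr", "Pc"),
                       diameter_min = 220, diameter_max = 1000,
                       diameter_step = 20,
                       n_permutations = 999, alpha = 0.05, min_demes = 3,
                       seed = 42, connectivity = 8, idw_power = 2,
                       variogram_lag_km = 50) {
  stopifnot(diameter_min <= diameter_max, diameter_step > 0,
            alpha > 0, alpha < 1, n_permutations >= 99,
            connectivity %in% c(4, 8), idw_power > 0, min_demes >= 1)
  unknown <- setdiff(scenarios, names(scenario_directions))
  if (length(unknown) > 0) stop("unknown scenarios: ", paste(unknown, collapse = ", "))
  structure(
    list(scenarios = scenarios, diameter_min = diameter_min,
         diameter_max = diameter_max, diameter_step = diameter_step,
         n_permutations = n_permutations, alpha = alpha,
         min_demes = min_demes, seed = seed, connectivity = connectivity,
         idw_power = idw_power, variogram_lag_km = variogram_lag_km),
    class = "run_config"
  )
}

#' Window diameter sequence of a configuration
#' @param config A `run_config`.
#' @return Numeric vector of diameters in km.
#' @export
config_diameters <- function(config) {
  seq(config$diameter_min, config$diameter_max, by = config$diameter_step)
}

#' Read a run configuration from YAML
#'
#' Unknown keys raise an error; missing keys take the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
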