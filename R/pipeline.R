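#' Full sliding-window landscape genetic analysis
#'
#' Chains the standard stages: filter genotypes, 0/1/2 encoding, Bray-Curtis
#' genetic distances (G), great-circle geographic distances (IBD), per-
#' scenario conductance surfaces and commute-time resistance distances (IBR,
#' normalized to \[0, 1\]), sliding-window generation, per-window partial
#' Mantel tests with the support criterion, and the per-scale summary.
#'
#' @param gt A `genotype_table` with coordinates.
#' @param rasters Named list of `land_raster`s with roles `temperature`,
#'   `elevation`, `pine` (only the roles needed by `config$scenarios` are
#'   required).
#' @param config A `run_config`.
#' @param locations Optional data frame of window centers (`location_id`,
#'   `lon`, `lat`); defaults to the distinct deme locations.
#' @param diameters Optional diameter vector; defaults to
#'   [config_diameters()].
#' @param max_missing_loci Individual filter threshold (default 2).
#' @param run_commonality Run commonality analysis per window?
#' @return List: `G`, `IBD`, `IBR` (named list), `conductance` (named list),
#'   `windows`, `results`, `scale_summary`, `genotypes` (the filtered table).
#' @export
run_landscape_analysis <- function(gt, rasters, config = run_config(),
                                   locations = NULL, diameters = NULL,
                                   max_missing_loci = 2,
                                   run_commonality = FALSE) {
  stopifnot(inherits(gt, "genotype_table"), inherits(config, "run_config"))
  gt <- suppressMessages(filter_individuals(gt, max_missing_loci))
  am <- encode_alleles(gt)
  G <- bray_curtis(am)
  IBD <- geographic_distance(gt$meta$lon, gt$meta$lat, gt$meta$individual_id)

  cond <- list(); IBR <- list()
  for (s in config$scenarios) {
    role <- scenario_raster_role[[s]]
    if (!role %in% names(rasters)) stop("missing raster for role: ", role)
    cond[[s]] <- scenario_conductance(rasters[[role]], s)
    graph <- build_graph(cond[[s]], config$connectivity)
    IBR[[s]] <- normalize_matrix(
      commute_distance(graph, gt$meta$lon, gt$meta$lat, gt$meta$individual_id)
    )
  }

  if (is.null(locations)) {
    locations <- unique(gt$meta[, c("deme_id", "lon", "lat")])
    names(locations)[1] <- "location_id"
  }
  if (is.null(diameters)) diameters <- config_diameters(config)
  windows <- generate_windows(locations, diameters, gt$meta, config$min_demes)
  results <- run_windows(windows, G, IBD, IBR, config,
                         run_commonality = run_commonality)
  list(G = G, IBD = IBD, IBR = IBR, conductance = cond,
       windows = windows, results = results,
       scale_summary = summarize_by_scale(results, config$alpha),
       genotypes = gt)
}
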