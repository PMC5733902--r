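# Synthetic landscapes and microsatellite genotypes with known ground truth.
# A forward-time Wright-Fisher stepping-stone simulator whose migration decays
# with commute distance over a chosen conductance surface; stepwise (+/-1
# repeat) microsatellite mutation.

#' Simulation configuration
#'
#' Defaults describe a CI-sized fixture: 20 demes of 10 diploid individuals
#' on a 25 x 25 raster (~0.32 degree, i.e. roughly 30 km cells spanning an
#' Iberia-sized rectangle), 10 loci, stepwise mutation at 1e-3, 200
#' non-overlapping generations, and migration proportional to
#' exp(-commute / theta) at total emigration rate 0.25.
#'
#' @param n_demes,deme_size,n_loci Deme count, diploid individuals per deme,
#'   locus count.
#' @param grid_nrow,grid_ncol,cellsize,xll,yll Landscape raster geometry
#'   (degrees).
#' @param mutation_rate Stepwise mutation probability per copy per
#'   generation, in (0, 0.01].
#' @param generations Forward generations.
#' @param migration_rate Total per-generation emigration probability of a
#'   gene copy.
#' @param theta_quantile Commute-distance quantile that sets the migration
#'   decay scale theta (default 0.25: migration halves over roughly the
#'   lower-quartile commute distance).
#' @param scenario Scenario driving migration (`"T"`, `"E"`, `"Pr"`, `"Pc"`)
#'   or `"none"` for uniform (island-model) migration.
#' @param barrier Add a low-conductance vertical barrier strip to the
#'   temperature raster (the strong positive-control landscape)?
#' @param raster_cor Target correlation between the shared landscape trend
#'   and each raster in \[0, 1) (0 = independent rasters).
#' @param smoothness Gaussian smoothing radius of the random fields, cells.
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_demes = 20, deme_size = 10, n_loci = 10,
                       grid_nrow = 25, grid_ncol = 25, cellsize = 0.32,
                       xll = -9.5, yll = 36,
                       mutation_rate = 1e-3, generations = 200,
                       migration_rate = 0.25, theta_quantile = 0.25,
                       scenario = "T", barrier = TRUE,
                       raster_cor = 0, smoothness = 3, seed = 1) {
  stopifnot(n_demes > 1, deme_size > 0, n_loci > 0,
            mutation_rate > 0, mutation_rate <= 0.01,
            generations > 0, migration_rate > 0, migration_rate < 1,
            raster_cor >= 0, raster_cor < 1)
  if (!scenario %in% c(names(scenario_directions), "none")) {
    stop("scenario must be one of T, E, Pr, Pc or 'none'")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Gaussian-smoothed white-noise field, standardized.
smooth_field <- function(nr, nc, radius) {
  pad <- ceiling(3 * radius)
  z <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)), nr + 2 * pad)
  kx <- stats::dnorm(seq(-pad, pad), sd = radius)
  kx <- kx / sum(kx)
  z <- apply(z, 2, function(col) stats::filter(col, kx, circular = TRUE))
  z <- t(apply(z, 1, function(row) stats::filter(row, kx, circular = TRUE)))
  z <- z[pad + seq_len(nr), pad + seq_len(nc)]
  (z - mean(z)) / stats::sd(z)
}

#' Simulate environmental rasters
#'
#' Three smooth random fields (temperature, elevation, pine density) with a
#' controllable common component (`raster_cor`); temperature additionally
#' carries a latitudinal trend and, optionally, a cold vertical barrier strip
#' through the middle of the map.
#'
#' @param cfg A `sim_config`.
#' @return Named list of `land_raster`s: `temperature`, `elevation`, `pine`.
#' @export
simulate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nr <- cfg$grid_nrow; nc <- cfg$grid_ncol
  shared <- smooth_field(nr, nc, cfg$smoothness)
  mix <- function(own) {
    sqrt(cfg$raster_cor) * shared + sqrt(1 - cfg$raster_cor) * own
  }
  lat_trend <- matrix(rep(seq(-1, 1, length.out = nr), nc), nr)  # warm south
  temp <- 0.7 * mix(smooth_field(nr, nc, cfg$smoothness)) + 0.7 * lat_trend
  elev <- mix(smooth_field(nr, nc, cfg$smoothness))
  pine <- mix(smooth_field(nr, nc, cfg$smoothness))
  if (cfg$barrier) {
    cols <- floor(nc / 2) + (-1:1)
    temp[, cols] <- min(temp) - 6   # cold strip: near-zero T conductance
  }
  lapply(
    list(temperature = temp, elevation = elev, pine = pine),
    function(m) land_raster(m, cfg$xll, cfg$yll, cfg$cellsize)
  )
}

# scenario -> source raster role
scenario_raster_role <- c(T = "temperature", E = "elevation",
                          Pr = "pine", Pc = "pine")

# Place demes on distinct cells, spread by rejection of close pairs.
place_demes <- function(cfg, graph) {
  nodes <- graph$nodes
  min_sep <- 1.5 * cfg$cellsize * 111  # km, keeps demes on distinct cells
  picked <- integer(0)
  cand <- sample(nrow(nodes))
  for (i in cand) {
    if (length(picked) == cfg$n_demes) break
    if (length(picked) == 0 ||
        all(haversine_km(nodes$lon[i], nodes$lat[i],
                         nodes$lon[picked], nodes$lat[picked]) >= min_sep)) {
      picked <- c(picked, i)
    }
  }
  if (length(picked) < cfg$n_demes) {
    picked <- c(picked, setdiff(cand, picked)[seq_len(cfg$n_demes - length(picked))])
  }
  nodes[picked, ]
}

#' Simulate microsatellite genotypes over a conductance surface
#'
#' Forward-time Wright-Fisher demes: each new gene copy picks a source deme
#' (itself with probability 1 - m; otherwise deme j with probability
#' proportional to exp(-commute(i, j) / theta)), copies a uniformly chosen
#' parent allele and mutates by +/- 1 repeat with the stepwise rate. With
#' `cfg$scenario == "none"` migration is uniform across demes (island model).
#'
#' @param cfg A `sim_config`.
#' @param conductance Conductance `land_raster` driving migration (ignored
#'   for `scenario = "none"`, where only deme placement uses it).
#' @return List: `genotypes` (a `genotype_table`), `demes` (data frame with
#'   `location_id`, `lon`, `lat`), `commute` (deme-level commute matrix),
#'   `migration` (row-stochastic migration matrix).
#' @export
simulate_genotypes <- function(cfg, conductance) {
  stopifnot(inherits(cfg, "sim_config"), inherits(conductance, "land_raster"))
  graph <- build_graph(conductance, connectivity = 8)
  set.seed(cfg$seed + 1L)
  demes <- place_demes(cfg, graph)
  K <- cfg$n_demes
  Cm <- commute_distance(graph, demes$lon, demes$lat,
                         labels = sprintf("d%02d", seq_len(K)))
  if (any(!is.finite(Cm))) stop("disconnected demes: commute distance is infinite")

  if (cfg$scenario == "none") {
    W <- matrix(1, K, K)
  } else {
    off <- Cm[row(Cm) != col(Cm)]
    theta <- stats::quantile(off, cfg$theta_quantile)
    if (theta <= 0) theta <- mean(off)
    W <- exp(-Cm / theta)
  }
  diag(W) <- 0
  M <- cfg$migration_rate * W / rowSums(W)
  diag(M) <- 1 - cfg$migration_rate

  copies <- 2L * cfg$deme_size
  # pools[[locus]] is a K x copies integer matrix of repeat numbers
  pools <- replicate(cfg$n_loci,
                     matrix(20L + sample(-2:2, K * copies, replace = TRUE), K),
                     simplify = FALSE)
  deme_idx <- rep(seq_len(K), each = copies)
  n_copies_tot <- K * copies
  for (gen in seq_len(cfg$generations)) {
    src <- unlist(lapply(seq_len(K), function(i) {
      sample.int(K, copies, replace = TRUE, prob = M[i, ])
    }))
    which_parent <- sample.int(copies, n_copies_tot, replace = TRUE)
    for (l in seq_len(cfg$n_loci)) {
      new_alleles <- pools[[l]][cbind(src, which_parent)]
      mut <- stats::runif(n_copies_tot) < cfg$mutation_rate
      if (any(mut)) {
        new_alleles[mut] <- new_alleles[mut] +
          sample(c(-1L, 1L), sum(mut), replace = TRUE)
      }
      # new_alleles runs deme-by-deme (deme_idx order), so fill by row
      pools[[l]] <- matrix(new_alleles, K, copies, byrow = TRUE)
    }
  }

  # pair consecutive copies into diploid individuals
  loci <- sprintf("loc%02d", seq_len(cfg$n_loci))
  n_ind <- K * cfg$deme_size
  a1 <- a2 <- matrix(NA_integer_, n_ind, cfg$n_loci, dimnames = list(NULL, loci))
  for (l in seq_len(cfg$n_loci)) {
    m <- pools[[l]]
    a1[, l] <- as.vector(t(m[, seq(1, copies, by = 2), drop = FALSE]))
    a2[, l] <- as.vector(t(m[, seq(2, copies, by = 2), drop = FALSE]))
  }
  deme_of_ind <- rep(seq_len(K), each = cfg$deme_size)
  meta <- data.frame(
    individual_id = sprintf("d%02d_i%02d", deme_of_ind,
                            stats::ave(deme_of_ind, deme_of_ind, FUN = seq_along)),
    deme_id = sprintf("d%02d", deme_of_ind),
    lon = demes$lon[deme_of_ind], lat = demes$lat[deme_of_ind],
    stringsAsFactors = FALSE
  )
  list(genotypes = genotype_table(meta, a1, a2),
       demes = data.frame(location_id = sprintf("d%02d", seq_len(K)),
                          lon = demes$lon, lat = demes$lat,
                          stringsAsFactors = FALSE),
       commute = Cm, migration = M)
}

#' Simulate a complete synthetic dataset
#'
#' Landscape rasters plus genotypes whose gene flow follows the configured
#' scenario's conductance surface (or uniform migration for `"none"`).
#'
#' @param cfg A `sim_config`.
#' @return List: `rasters`, `conductance` (the driving surface; for
#'   `"none"` the temperature surface, used only to place demes),
#'   `genotypes`, `demes`, `commute`, `migration`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  rasters <- simulate_landscape(cfg)
  drive_scen <- if (cfg$scenario == "none") "T" else cfg$scenario
  cond <- scenario_conductance(rasters[[scenario_raster_role[[drive_scen]]]],
                               drive_scen)
  sim <- simulate_genotypes(cfg, cond)
  c(list(rasters = rasters, conductance = cond, cfg = cfg), sim)
}
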