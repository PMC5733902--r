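# Fixtures are built in code; nothing is read from disk except the printed
# commonality table shipped in inst/extdata.

# Genotype table from per-locus call strings ("120/124", "" = missing).
make_gt <- function(calls, deme_id = NULL, lon = NULL, lat = NULL, ids = NULL) {
  n <- length(calls[[1]])
  loci <- names(calls)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci), dimnames = list(NULL, loci))
  for (j in seq_along(loci)) {
    parts <- strsplit(calls[[j]], "/", fixed = TRUE)
    for (i in seq_len(n)) {
      if (length(parts[[i]]) == 2) {
        a1[i, j] <- as.integer(parts[[i]][1])
        a2[i, j] <- as.integer(parts[[i]][2])
      }
    }
  }
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(n))
  if (is.null(deme_id)) deme_id <- rep("d1", n)
  if (is.null(lon)) lon <- seq(0, 1, length.out = n)
  if (is.null(lat)) lat <- rep(40, n)
  genotype_table(
    data.frame(individual_id = ids, deme_id = deme_id, lon = lon, lat = lat,
               stringsAsFactors = FALSE),
    a1, a2
  )
}

# Random labeled distance-like matrix (euclidean distances of random points).
rand_pairwise <- function(n, seed, labels = sprintf("i%02d", seq_len(n)),
                          dims = 3) {
  set.seed(seed)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(n * dims), n)))
  dimnames(m) <- list(labels, labels)
  m
}

# Symmetric zero-diagonal matrix with a prescribed lower triangle.
mat_from_lt <- function(v, n, labels = sprintf("i%02d", seq_len(n))) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  dimnames(m) <- list(labels, labels)
  m
}

# Hand-built conductance graph (documented structure), for non-lattice
# topologies such as the triangle.
make_graph <- function(edges, n_nodes, lon = seq_len(n_nodes) - 1,
                       lat = rep(0, n_nodes)) {
  comp <- rep(1L, n_nodes)
  structure(
    list(nodes = data.frame(cell = seq_len(n_nodes), row = 1,
                            col = seq_len(n_nodes), lon = lon, lat = lat,
                            node = seq_len(n_nodes), component = comp),
         edges = edges, volume = 2 * sum(edges$w),
         n_rows = 1, n_cols = n_nodes, xll = 0, yll = 0, cellsize = 0.5),
    class = "conductance_graph"
  )
}

# Independent commute-time oracle: expected round-trip steps of the Markov
# chain with transition probabilities w_ij / sum_k w_ik, via hitting-time
# linear solves (no Laplacian, no pseudo-inverse).
commute_oracle <- function(edges, n_nodes) {
  W <- matrix(0, n_nodes, n_nodes)
  for (k in seq_len(nrow(edges))) {
    W[edges$i[k], edges$j[k]] <- W[edges$i[k], edges$j[k]] + edges$w[k]
    W[edges$j[k], edges$i[k]] <- W[edges$j[k], edges$i[k]] + edges$w[k]
  }
  P <- W / rowSums(W)
  hit <- function(target) {
    idx <- setdiff(seq_len(n_nodes), target)
    h <- solve(diag(length(idx)) - P[idx, idx, drop = FALSE],
               rep(1, length(idx)))
    full <- numeric(n_nodes); full[idx] <- h
    full
  }
  H <- vapply(seq_len(n_nodes), hit, numeric(n_nodes)) # H[i, j] = E[hit j from i]
  H + t(H)
}

# Monte-Carlo commute times by literal random walks.
commute_mc <- function(edges, n_nodes, from, to, n_walks, seed) {
  W <- matrix(0, n_nodes, n_nodes)
  for (k in seq_len(nrow(edges))) {
    W[edges$i[k], edges$j[k]] <- W[edges$i[k], edges$j[k]] + edges$w[k]
    W[edges$j[k], edges$i[k]] <- W[edges$j[k], edges$i[k]] + edges$w[k]
  }
  set.seed(seed)
  one <- function() {
    steps <- 0L; pos <- from; seen_to <- FALSE
    repeat {
      pos <- sample.int(n_nodes, 1, prob = W[pos, ])
      steps <- steps + 1L
      if (pos == to) seen_to <- TRUE
      if (seen_to && pos == from) return(steps)
    }
  }
  replicate(n_walks, one())
}

# Direct Mantel r between two matrices, used by the enumeration oracle.
mantel_r_direct <- function(x, y) stats::cor(x[lower.tri(x)], y[lower.tri(y)])

# All n! permutations of 1..n as rows.
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Brute-force semivariogram (double loop over pairs), the binning oracle.
variogram_oracle <- function(values, lon, lat, lag, max_dist) {
  n_bins <- max(1L, ceiling(max_dist / lag))
  cnt <- integer(n_bins); ssq <- numeric(n_bins)
  n <- length(values)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- haversine_km(lon[i], lat[i], lon[j], lat[j])
      if (d > max_dist) next
      b <- min(floor(d / lag), n_bins - 1) + 1
      cnt[b] <- cnt[b] + 1L
      ssq[b] <- ssq[b] + (values[i] - values[j])^2
    }
  }
  list(gamma = ifelse(cnt > 0, ssq / (2 * cnt), NA_real_), n_pairs = cnt)
}

# A minimal viable analysis fixture: 3 demes, 12 individuals, matrices built
# from coordinates and random genetic noise.
mini_fixture <- function(seed = 42) {
  set.seed(seed)
  demes <- data.frame(location_id = c("A", "B", "C"),
                      lon = c(-5, -4.4, -4.7), lat = c(40, 40.2, 40.6))
  idx <- rep(1:3, each = 4)
  ids <- sprintf("%s%d", demes$location_id[idx], rep(1:4, times = 3))
  ind <- data.frame(individual_id = ids, deme_id = demes$location_id[idx],
                    lon = demes$lon[idx] + runif(12, -0.01, 0.01),
                    lat = demes$lat[idx] + runif(12, -0.01, 0.01),
                    stringsAsFactors = FALSE)
  IBD <- geographic_distance(ind$lon, ind$lat, ind$individual_id)
  G <- rand_pairwise(12, seed + 1, labels = ids)
  IBR <- lapply(c(T = 1, E = 2, Pr = 3, Pc = 4),
                function(k) rand_pairwise(12, seed + 1 + k, labels = ids))
  list(demes = demes, individuals = ind, G = G, IBD = IBD, IBR = IBR)
}
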