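# Scenario conductance surfaces, the raster lattice graph, and commute-time
# resistance distances (random-walk / circuit-theory distances) via the
# weighted graph Laplacian.

scenario_directions <- c(T = "high_high", E = "high_low",
                         Pr = "high_low", Pc = "high_high")

#' Scenario conductance surface from an environmental raster
#'
#' The raster is min-max rescaled to \[eps, 1\] (eps = 1e-3, keeping every
#' cell traversable), then oriented by hypothesis: for T (warm = easy
#' movement) and Pc (pines as corridors) conductance increases with the
#' raster value; for E (elevation as resistance) and Pr (pines as resistance)
#' conductance is the complementary transform (1 + eps) - rescaled value, so
#' high raster values mean low conductance. Pr and Pc thus sum to a constant
#' cell-wise.
#'
#' @param r A `land_raster` with at least 2 distinct finite values.
#' @param scenario One of `"T"`, `"E"`, `"Pr"`, `"Pc"`.
#' @param eps Floor of the rescaled surface (default 1e-3).
#' @return A `land_raster` of strictly positive conductances (NA preserved).
#' @export
scenario_conductance <- function(r, scenario, eps = 1e-3) {
  stopifnot(inherits(r, "land_raster"))
  scenario <- match.arg(scenario, names(scenario_directions))
  v <- r$values
  fin <- v[is.finite(v)]
  if (length(unique(fin)) < 2) stop("constant raster: no environmental contrast")
  sc <- eps + (1 - eps) * (v - min(fin)) / (max(fin) - min(fin))
  cond <- if (scenario_directions[[scenario]] == "high_high") sc else (1 + eps) - sc
  out <- land_raster(cond, r$xll, r$yll, r$cellsize, units = "conductance")
  attr(out, "scenario") <- scenario
  out
}

#' Build the lattice conductance graph of a raster
#'
#' Nodes are valid (finite) cells; undirected edges join 4- or 8-neighbors.
#' An edge weight is the mean of the two cells' conductances; diagonal edges
#' are additionally divided by sqrt(2) to account for the longer step.
#'
#' @param cond Conductance `land_raster` (strictly positive where finite).
#' @param connectivity 4 or 8 (default 8).
#' @return Object of class `conductance_graph`: `nodes` (data frame of cells
#'   with coordinates and component label), `edges` (node index pairs +
#'   weight), `volume` (2 * total edge weight) and the source raster geometry.
#' @export
build_graph <- function(cond, connectivity = 8) {
  stopifnot(inherits(cond, "land_raster"), connectivity %in% c(4, 8))
  v <- cond$values
  if (any(v[is.finite(v)] <= 0)) stop("conductance must be strictly positive")
  nr <- nrow(v); nc <- ncol(v)
  valid <- which(is.finite(v))
  if (length(valid) == 0) stop("raster has no valid cells")
  node_of_cell <- rep(NA_integer_, nr * nc)
  node_of_cell[valid] <- seq_along(valid)

  offsets <- list(c(1L, 0L), c(0L, 1L))                 # down, right
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  rw <- ((valid - 1L) %% nr) + 1L
  cl <- ((valid - 1L) %/% nr) + 1L
  ei <- ej <- integer(0); ew <- numeric(0)
  for (off in offsets) {
    r2 <- rw + off[1]; c2 <- cl + off[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    tgt <- (c2[ok] - 1L) * nr + r2[ok]
    src <- valid[ok]
    good <- !is.na(node_of_cell[tgt])
    src <- src[good]; tgt <- tgt[good]
    w <- (v[src] + v[tgt]) / 2
    if (any(off != 0) && all(abs(off) == 1)) w <- w / sqrt(2)
    ei <- c(ei, node_of_cell[src]); ej <- c(ej, node_of_cell[tgt]); ew <- c(ew, w)
  }

  cc <- raster_cell_centers(land_raster(v, cond$xll, cond$yll, cond$cellsize))
  nodes <- cc[valid, c("cell", "row", "col", "lon", "lat")]
  nodes$node <- seq_along(valid)

  # connected components by label propagation over the edge list
  comp <- seq_along(valid)
  repeat {
    new_comp <- comp
    m1 <- pmin(comp[ei], comp[ej])
    new_comp[ei] <- pmin(new_comp[ei], m1)
    new_comp[ej] <- pmin(new_comp[ej], m1)
    # path-compress
    while (any(new_comp != new_comp[new_comp])) new_comp <- new_comp[new_comp]
    if (identical(new_comp, comp)) break
    comp <- new_comp
  }
  nodes$component <- match(comp, unique(comp))

  structure(
    list(nodes = nodes,
         edges = data.frame(i = ei, j = ej, w = ew),
         volume = 2 * sum(ew),
         n_rows = nr, n_cols = nc,
         xll = cond$xll, yll = cond$yll, cellsize = cond$cellsize),
    class = "conductance_graph"
  )
}

#' @export
print.conductance_graph <- function(x, ...) {
  cat(sprintf("conductance_graph: %d nodes, %d edges, %d component(s), volume %.4g\n",
              nrow(x$nodes), nrow(x$edges), max(x$nodes$component), x$volume))
  invisible(x)
}

# Map lon/lat points to graph nodes, snapping to the nearest valid cell
# within `tol_cells` cell diagonals.
snap_to_nodes <- function(graph, lon, lat, tol_cells = 1) {
  vapply(seq_along(lon), function(k) {
    d <- haversine_km(lon[k], lat[k], graph$nodes$lon, graph$nodes$lat)
    i <- which.min(d)
    diag_km <- haversine_km(0, 0, graph$cellsize, graph$cellsize)
    if (d[i] > tol_cells * diag_km) {
      stop(sprintf("point (%g, %g) is %.1f km from the nearest valid cell (tolerance %.1f km)",
                   lon[k], lat[k], d[i], tol_cells * diag_km))
    }
    graph$nodes$node[i]
  }, integer(1))
}

#' Commute-time resistance distances between locations
#'
#' Commute time C(i, j) = vol(G) * (L+_ii + L+_jj - 2 L+_ij), the expected
#' round-trip steps of the random walk whose transition probabilities follow
#' edge conductances; equivalently effective resistance times graph volume.
#' Computed exactly per connected component by a grounded sparse Laplacian
#' solve. Pairs spanning components get `Inf`.
#'
#' @param graph A `conductance_graph`.
#' @param lon,lat Point coordinates; each point is snapped to the nearest
#'   valid cell (within one cell diagonal, else error).
#' @param labels Point labels (default `seq_along(lon)`).
#' @return Symmetric pairwise matrix of commute distances (class attribute
#'   `scenario` copied from the graph when present).
#' @export
commute_distance <- function(graph, lon, lat, labels = NULL) {
  stopifnot(inherits(graph, "conductance_graph"))
  if (is.null(labels)) labels <- as.character(seq_along(lon))
  nodes_pt <- snap_to_nodes(graph, lon, lat)
  uniq <- sort(unique(nodes_pt))
  n_nodes <- nrow(graph$nodes)

  # sparse weighted Laplacian
  e <- graph$edges
  L <- Matrix::sparseMatrix(
    i = c(e$i, e$j, e$i, e$j),
    j = c(e$j, e$i, e$i, e$j),
    x = c(-e$w, -e$w, e$w, e$w),
    dims = c(n_nodes, n_nodes)
  )

  comp <- graph$nodes$component
  R <- matrix(Inf, length(uniq), length(uniq))  # effective resistances
  diag(R) <- 0
  for (cmp in unique(comp[uniq])) {
    members <- which(comp == cmp)
    tgt <- which(uniq %in% members)
    if (length(tgt) < 2 && length(members) >= 1) next
    ground <- members[1]
    keep <- setdiff(members, ground)
    pos <- match(uniq[tgt], keep)   # NA for the ground node itself
    if (length(keep) == 0) next
    Lr <- L[keep, keep, drop = FALSE]
    ok <- !is.na(pos)
    rhs <- Matrix::sparseMatrix(
      i = pos[ok], j = which(ok),
      x = 1, dims = c(length(keep), length(tgt))
    )
    S <- as.matrix(Matrix::solve(Lr, rhs))   # grounded inverse columns
    # grounded inverse entries between targets (0 on the ground row/column)
    G <- matrix(0, length(tgt), length(tgt))
    G[ok, ok] <- S[pos[ok], ok, drop = FALSE]
    dg <- diag(G)
    R[tgt, tgt] <- outer(dg, dg, "+") - 2 * G
  }
  C <- graph$volume * R
  diag(C) <- 0
  out <- C[match(nodes_pt, uniq), match(nodes_pt, uniq), drop = FALSE]
  diag(out) <- 0
  dimnames(out) <- list(labels, labels)
  out
}
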