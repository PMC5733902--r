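# Mantel and partial Mantel permutation tests, the IBR support criterion,
# and commonality analysis of multiple regression on distance matrices.
#
# Permutation convention: rows and columns of one matrix are permuted jointly
# (for the partial test, the response G), the test is one-tailed for positive
# association, and the p-value uses the add-one estimator
# (1 + #{r_perm >= r_obs}) / (1 + n_perm), so p is never 0.

# Shared checks + lower-triangle pair index for a set of matrices.
mantel_prep <- function(...) {
  mats <- list(...)
  labs <- rownames(mats[[1]])
  n <- nrow(mats[[1]])
  if (n < 4) stop("need at least 4 individuals for a Mantel test")
  for (m in mats) {
    validate_pairwise(m)
    if (!identical(rownames(m), labs)) stop("matrices must share labels (same order)")
  }
  ij <- which(lower.tri(mats[[1]]), arr.ind = TRUE)
  list(n = n, ij = ij)
}

# Random permutations as an n_perm x n integer matrix (or validate a given one).
perm_matrix <- function(n, n_perm, perms, seed) {
  if (!is.null(perms)) {
    perms <- as.matrix(perms)
    if (ncol(perms) != n) stop("permutation matrix must have n columns")
    return(perms)
  }
  if (!is.null(seed)) set.seed(seed)
  t(replicate(n_perm, sample.int(n)))
}

new_mantel_result <- function(r, p, n_perm, partialled, seed) {
  structure(list(r = r, p = p, n_perm = n_perm, partialled = partialled,
                 seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel%s: r = %.4f, p = %.4g (%d permutations, one-tailed)\n",
              if (is.na(x$partialled)) "" else paste0(" | ", x$partialled),
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Simple Mantel permutation test
#'
#' Pearson correlation of the lower-triangle vectors of two pairwise
#' matrices; significance by jointly permuting rows and columns of `y`.
#' One-tailed for positive association.
#'
#' @param x,y Pairwise matrices with identical labels (n >= 4).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed for reproducibility.
#' @param perms Optional explicit permutation matrix (rows = permutations of
#'   `1:n`), e.g. the full enumeration for exact tests; overrides `n_perm`.
#' @return A `mantel_result` with elements `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(x, y, n_perm = 999, seed = NULL, perms = NULL) {
  pr <- mantel_prep(x, y)
  xv <- x[pr$ij]; yv <- y[pr$ij]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero-variance distance matrix")
  }
  r_obs <- stats::cor(xv, yv)
  P <- perm_matrix(pr$n, n_perm, perms, seed)
  n_perm <- nrow(P)
  # under a joint row/column permutation the off-diagonal multiset of y is
  # unchanged, so mean and sd of yv are permutation-invariant
  m <- length(xv)
  xc <- xv - mean(xv)
  denom <- sqrt(sum(xc^2)) * stats::sd(yv) * sqrt(m - 1)
  i1 <- pr$ij[, 1]; i2 <- pr$ij[, 2]
  r_perm <- vapply(seq_len(n_perm), function(k) {
    p <- P[k, ]
    sum(xc * y[cbind(p[i1], p[i2])]) / denom
  }, numeric(1))
  p_val <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  new_mantel_result(r_obs, p_val, n_perm, NA_character_, seed)
}

# residuals of v on z (with intercept); a constant z yields centered v,
# which makes the partial test collapse to the simple test
resid_on <- function(v, z, zc = z - mean(z), szz = sum(zc^2)) {
  vc <- v - mean(v)
  if (szz == 0) return(vc)
  vc - (sum(vc * zc) / szz) * zc
}

#' Partial Mantel permutation test
#'
#' Correlation of (G residualized on Z) with (X residualized on Z); the
#' response G's rows/columns are permuted jointly and the residuals are
#' recomputed within each permutation. One-tailed for positive association.
#'
#' @param g Response pairwise matrix (genetic distances).
#' @param x Predictor pairwise matrix under test.
#' @param z Pairwise matrix to partial out.
#' @param n_perm,seed,perms As in [mantel_test()].
#' @return A `mantel_result` with `partialled` set to `"Z"`.
#' @export
partial_mantel <- function(g, x, z, n_perm = 999, seed = NULL, perms = NULL) {
  pr <- mantel_prep(g, x, z)
  gv <- g[pr$ij]; xv <- x[pr$ij]; zv <- z[pr$ij]
  if (stats::sd(gv) == 0 || stats::sd(xv) == 0) stop("zero-variance distance matrix")
  if (stats::sd(zv) > 0 && abs(stats::cor(xv, zv)) > 1 - 1e-10) {
    stop("degenerate design: x is affinely identical to z")
  }
  zc <- zv - mean(zv); szz <- sum(zc^2)
  rx <- resid_on(xv, zv, zc, szz)
  rg <- resid_on(gv, zv, zc, szz)
  sx <- sqrt(sum(rx^2))
  r_obs <- sum(rg * rx) / (sqrt(sum(rg^2)) * sx)
  P <- perm_matrix(pr$n, n_perm, perms, seed)
  n_perm <- nrow(P)
  i1 <- pr$ij[, 1]; i2 <- pr$ij[, 2]
  r_perm <- vapply(seq_len(n_perm), function(k) {
    p <- P[k, ]
    rgp <- resid_on(g[cbind(p[i1], p[i2])], zv, zc, szz)
    sum(rgp * rx) / (sqrt(sum(rgp^2)) * sx)
  }, numeric(1))
  p_val <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  new_mantel_result(r_obs, p_val, n_perm, "Z", seed)
}

#' IBR support criterion
#'
#' An isolation-by-resistance hypothesis is supported when IBR is
#' significantly correlated with G after partialling out IBD (p < alpha) AND
#' IBD is non-significant with IBR partialled out (p >= alpha).
#'
#' @param p_ibr_given_ibd p-value of the partial Mantel test G ~ IBR | IBD.
#' @param p_ibd_given_ibr p-value of the partial Mantel test G ~ IBD | IBR.
#' @param alpha Significance level (default 0.05).
#' @param hypothesis Optional hypothesis name carried through.
#' @return List of class `support_decision` with both p-values, `alpha`,
#'   `hypothesis` and logical `supported`.
#' @export
support_criterion <- function(p_ibr_given_ibd, p_ibd_given_ibr, alpha = 0.05,
                              hypothesis = NA_character_) {
  stopifnot(p_ibr_given_ibd > 0, p_ibr_given_ibd <= 1,
            p_ibd_given_ibr > 0, p_ibd_given_ibr <= 1,
            alpha > 0, alpha < 1)
  structure(
    list(hypothesis = hypothesis,
         p_ibr_given_ibd = p_ibr_given_ibd,
         p_ibd_given_ibr = p_ibd_given_ibr,
         alpha = alpha,
         supported = (p_ibr_given_ibd < alpha) && (p_ibd_given_ibr >= alpha)),
    class = "support_decision"
  )
}

# subsets of 1..p grouped by order, within order in lexicographic index order
subset_list <- function(p) {
  out <- list()
  for (s in seq_len(p)) {
    cmb <- utils::combn(p, s)
    for (k in seq_len(ncol(cmb))) out[[length(out) + 1]] <- cmb[, k]
  }
  out
}

#' Commonality analysis of distance-matrix regression
#'
#' The response's lower-triangle vector is regressed (OLS) on every non-empty
#' subset of the predictors' vectors; the 2^p - 1 commonality coefficients
#' are the unique solution of the linear system R2(A) = sum of C_S over all
#' subsets S intersecting A, so they always sum exactly to the full-model R2.
#'
#' @param g Response pairwise matrix.
#' @param predictors Named list of 1..6 pairwise matrices (same labels as `g`).
#' @return Data frame of class `commonality_result` with columns `subset`
#'   (comma-joined predictor names), `order`, `coef` and `pct_total`;
#'   attributes `r2_full` and `collinear` (logical VIF > 10 flag).
#' @export
commonality <- function(g, predictors) {
  p <- length(predictors)
  if (p < 1 || p > 6) stop("need between 1 and 6 predictors")
  if (is.null(names(predictors)) || any(!nzchar(names(predictors)))) {
    stop("predictors must be named")
  }
  pr <- do.call(mantel_prep, c(list(g), predictors))
  y <- g[pr$ij]
  X <- vapply(predictors, function(m) m[pr$ij], numeric(nrow(pr$ij)))
  subs <- subset_list(p)
  r2 <- vapply(subs, function(s) ols_r2(y, X[, s, drop = FALSE]), numeric(1))
  # M[a, s] = 1 if subset s intersects subset a
  M <- matrix(0, length(subs), length(subs))
  for (a in seq_along(subs)) {
    for (s in seq_along(subs)) {
      M[a, s] <- as.numeric(any(subs[[s]] %in% subs[[a]]))
    }
  }
  coefs <- solve(M, r2)
  r2_full <- r2[[length(r2)]]
  labels <- vapply(subs, function(s) paste(names(predictors)[s], collapse = ","), "")
  out <- data.frame(subset = labels,
                    order = lengths(subs),
                    coef = coefs,
                    pct_total = if (r2_full > 0) 100 * coefs / r2_full else NA_real_,
                    stringsAsFactors = FALSE)
  collinear <- FALSE
  if (p >= 2) {
    vifs <- tryCatch(vif_matrices(predictors), error = function(e) NA)
    collinear <- any(is.infinite(vifs)) || any(vifs > 10, na.rm = TRUE)
    if (isTRUE(collinear)) warning("collinear predictors (VIF > 10); coefficients reported anyway")
  }
  attr(out, "r2_full") <- r2_full
  attr(out, "collinear") <- collinear
  class(out) <- c("commonality_result", "data.frame")
  out
}
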