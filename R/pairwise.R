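# Pairwise individual-by-individual matrices are plain base matrices with
# dimnames; these helpers centralise validation, I/O and subsetting.

#' Validate a pairwise distance matrix
#'
#' Checks squareness, symmetry (within tolerance), a zero diagonal and
#' matching row/column labels.
#'
#' @param m Matrix to check.
#' @param tol Symmetry tolerance.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_pairwise <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("pairwise matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("pairwise matrix must carry identical row and column labels")
  }
  fin <- is.finite(m) & is.finite(t(m))
  if (any(abs(m[fin] - t(m)[fin]) > tol)) stop("pairwise matrix is asymmetric")
  if (any(is.infinite(m) != is.infinite(t(m)))) stop("pairwise matrix is asymmetric")
  if (any(abs(diag(m)) > tol)) stop("pairwise matrix diagonal must be zero")
  invisible(m)
}

#' Lower-triangle vector of a pairwise matrix
#'
#' @param m Square matrix.
#' @return Numeric vector of the strictly-lower-triangular entries, column-major.
#' @export
lower_tri <- function(m) m[lower.tri(m)]

#' Subset a pairwise matrix by labels
#'
#' @param m Pairwise matrix with labels.
#' @param ids Labels to retain (order preserved as given).
#' @return The sub-matrix.
#' @export
subset_pairwise <- function(m, ids) {
  miss <- setdiff(ids, rownames(m))
  if (length(miss) > 0) {
    stop("labels absent from matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  m[ids, ids, drop = FALSE]
}

#' Write / read a labeled square matrix as TSV
#'
#' The on-disk format is a square tab-separated table with row and column
#' labels; write-then-read is the identity.
#'
#' @param m Pairwise matrix (validated before writing).
#' @param path File path.
#' @return `read_pairwise_matrix` returns the matrix; `write_pairwise_matrix`
#'   returns `path` invisibly.
#' @export
write_pairwise_matrix <- function(m, path) {
  validate_pairwise(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairwise_matrix
#' @export
read_pairwise_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  validate_pairwise(m)
  m
}

#' Rescale a pairwise matrix to [0, 1]
#'
#' Off-diagonal finite values are mapped linearly so the minimum becomes 0 and
#' the maximum 1; infinities (disconnected pairs) are preserved; the diagonal
#' stays zero. Matrices already spanning [0, 1] are returned unchanged.
#'
#' @param m Pairwise matrix.
#' @return Rescaled matrix of the same shape and labels.
#' @export
normalize_matrix <- function(m) {
  validate_pairwise(m)
  off <- m[row(m) != col(m)]
  v <- off[is.finite(off)]
  if (length(unique(v)) < 2) stop("cannot normalize: off-diagonal values are constant")
  lo <- min(v); hi <- max(v)
  if (lo == 0 && hi == 1) return(m)
  out <- (m - lo) / (hi - lo)
  out[is.infinite(m)] <- Inf
  diag(out) <- 0
  out
}

#' Variance inflation factors among pairwise matrices
#'
#' Each matrix's lower-triangle vector is regressed (OLS) on the others';
#' VIF = 1 / (1 - R^2). Values above 10 conventionally flag collinearity.
#'
#' @param mats Named list of >= 2 pairwise matrices with identical labels.
#' @return Named numeric vector of VIFs (`Inf` for perfectly collinear input).
#' @export
vif_matrices <- function(mats) {
  if (length(mats) < 2) stop("need at least 2 matrices")
  labs <- rownames(mats[[1]])
  for (m in mats) {
    validate_pairwise(m)
    if (!identical(rownames(m), labs)) stop("matrices must share labels")
  }
  vecs <- vapply(mats, lower_tri, numeric(length(lower_tri(mats[[1]]))))
  vapply(seq_along(mats), function(k) {
    r2 <- ols_r2(vecs[, k], vecs[, -k, drop = FALSE])
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(names(mats))
}

# R^2 of an OLS fit of y on columns of X (with intercept)
ols_r2 <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response has zero variance")
  1 - sum(fit$residuals^2) / tss
}
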