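# Genotype filtering, 0/1/2 allele coding, Bray-Curtis individual genetic
# distances, PCA, and per-deme summary statistics.

#' Remove individuals with too many missing loci
#'
#' Individuals *exceeding* `max_missing_loci` missing loci are removed (an
#' individual with exactly `max_missing_loci` missing loci is retained).
#'
#' @param gt A `genotype_table`.
#' @param max_missing_loci Maximum tolerated number of missing loci (default 2).
#' @return Filtered `genotype_table`; the number removed is attached as
#'   attribute `n_removed` and reported via `message()`.
#' @export
filter_individuals <- function(gt, max_missing_loci = 2) {
  stopifnot(inherits(gt, "genotype_table"), max_missing_loci >= 0)
  miss <- missing_loci_per_individual(gt)
  keep <- miss <= max_missing_loci
  if (!any(keep)) warning("all individuals removed by missing-loci filter")
  out <- genotype_table(gt$meta[keep, , drop = FALSE],
                        gt$a1[keep, , drop = FALSE],
                        gt$a2[keep, , drop = FALSE])
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("filter_individuals: removed %d of %d individuals (> %d missing loci)",
                    n_removed, length(keep), max_missing_loci))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Drop named loci from a genotype table
#'
#' @param gt A `genotype_table`.
#' @param loci Character vector of locus names to remove (may be empty).
#' @return `genotype_table` without those loci.
#' @export
drop_loci <- function(gt, loci) {
  stopifnot(inherits(gt, "genotype_table"))
  if (length(loci) == 0) return(gt)
  unknown <- setdiff(loci, colnames(gt$a1))
  if (length(unknown) > 0) stop("unknown loci: ", paste(unknown, collapse = ", "))
  keep <- setdiff(colnames(gt$a1), loci)
  if (length(keep) == 0) stop("cannot drop all loci")
  genotype_table(gt$meta, gt$a1[, keep, drop = FALSE], gt$a2[, keep, drop = FALSE])
}

#' Encode genotypes as a 0/1/2 allele matrix
#'
#' One column per distinct allele observed in the dataset (grouped by locus,
#' alleles in increasing order): 0 when absent, 1 when present once
#' (heterozygote), 2 for homozygotes. A missing locus masks all of that
#' locus's columns for that individual (`NA`).
#'
#' @param gt A `genotype_table`.
#' @return Matrix of class `allele_matrix` (individuals x alleles) with
#'   attributes `locus` (per-column locus name) and `allele` (per-column
#'   allele identifier); column names are `"locus.allele"`.
#' @export
encode_alleles <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  loci <- colnames(gt$a1)
  cols <- list()
  for (l in loci) {
    alleles <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0) next
    block <- matrix(0, n_individuals(gt), length(alleles),
                    dimnames = list(gt$meta$individual_id,
                                    paste(l, alleles, sep = ".")))
    for (k in seq_along(alleles)) {
      block[, k] <- (gt$a1[, l] == alleles[k]) + (gt$a2[, l] == alleles[k])
    }
    block[is.na(gt$a1[, l]), ] <- NA
    cols[[l]] <- list(block = block, alleles = alleles)
  }
  am <- do.call(cbind, lapply(cols, `[[`, "block"))
  locus_of <- rep(names(cols), vapply(cols, function(x) length(x$alleles), 0L))
  allele_of <- unlist(lapply(cols, `[[`, "alleles"), use.names = FALSE)
  structure(am, locus = locus_of, allele = allele_of,
            class = c("allele_matrix", "matrix", "array"))
}

#' Bray-Curtis dissimilarity between individuals
#'
#' For 0/1/2 coded individuals x and y, d = 1 - 2 * sum(min(x, y)) /
#' (sum(x) + sum(y)), computed over the loci non-missing in *both* members of
#' each pair (pairwise deletion). With the 0/1/2 coding each shared locus
#' contributes 2 to both totals, so d = sum|x - y| / (4 * shared loci).
#'
#' @param am An `allele_matrix` from [encode_alleles()].
#' @param on_empty What to do for a pair sharing no typed locus: `"error"`
#'   (default) or `"na"`.
#' @return Symmetric pairwise matrix of dissimilarities in \[0, 1\].
#' @export
bray_curtis <- function(am, on_empty = c("error", "na")) {
  on_empty <- match.arg(on_empty)
  if (nrow(am) < 2) stop("need at least 2 individuals")
  locus_of <- attr(am, "locus")
  n <- nrow(am)
  num <- matrix(0, n, n)
  shared <- matrix(0L, n, n)
  for (l in unique(locus_of)) {
    sub <- am[, locus_of == l, drop = FALSE]
    typed <- !is.na(sub[, 1])
    if (sum(typed) < 2) next
    sub0 <- sub[typed, , drop = FALSE]
    dl <- as.matrix(stats::dist(sub0, method = "manhattan"))
    num[typed, typed] <- num[typed, typed] + dl
    shared[typed, typed] <- shared[typed, typed] + 1L
  }
  if (any(shared[lower.tri(shared)] == 0)) {
    if (on_empty == "error") stop("pair(s) share no typed locus")
  }
  d <- num / (4 * shared)   # NaN where shared == 0
  d[shared == 0] <- NA
  diag(d) <- 0
  dimnames(d) <- list(rownames(am), rownames(am))
  d
}

#' PCA of the allele matrix
#'
#' Masked (missing-locus) entries are imputed by the column mean; columns are
#' centered but not scaled before the eigendecomposition, following the usual
#' PCA-on-allele-frequencies convention.
#'
#' @param am An `allele_matrix`.
#' @param n_axes Number of axes to return (truncated to the rank, with a
#'   warning, if larger).
#' @return List with `scores` (individuals x axes), `eigenvalues` (all
#'   positive eigenvalues, non-increasing) and `percent_inertia`.
#' @export
pca_scores <- function(am, n_axes = 2) {
  x <- unclass(am)
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  ev <- sv$d^2 / (nrow(x) - 1)
  pos <- ev > max(ev) * 1e-12
  ev <- ev[pos]
  if (n_axes > length(ev)) {
    warning(sprintf("n_axes truncated from %d to rank %d", n_axes, length(ev)))
    n_axes <- length(ev)
  }
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(scores) <- rownames(am)
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  list(scores = scores, eigenvalues = ev,
       percent_inertia = 100 * ev / sum(ev))
}

# Weir-Cockerham variance components for one allele at one locus across demes.
# n: sample sizes (individuals typed), p: allele frequencies, h: observed
# heterozygote frequencies (for this allele). Returns c(a, b, c).
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Per-locus allele frequency / heterozygosity tabulation for one deme subset.
locus_tab <- function(a1, a2, alleles) {
  typed <- !is.na(a1)
  n <- sum(typed)
  if (n == 0) return(NULL)
  cnt <- vapply(alleles, function(al) sum(a1[typed] == al) + sum(a2[typed] == al), 0)
  het <- vapply(alleles, function(al) {
    sum((a1[typed] == al | a2[typed] == al) & a1[typed] != a2[typed])
  }, 0)
  list(n = n, p = cnt / (2 * n), h = het / n)
}

#' Weir-Cockerham Fst between two demes
#'
#' Multilocus theta: variance components a, b, c are summed over all alleles
#' of all loci and theta = sum(a) / sum(a + b + c).
#'
#' @param gt A `genotype_table`.
#' @param deme_a,deme_b Deme ids (each with >= 2 individuals).
#' @return Theta (NA if every locus is monomorphic across the pair).
#' @export
fst_wc <- function(gt, deme_a, deme_b) {
  stopifnot(inherits(gt, "genotype_table"))
  ia <- gt$meta$deme_id == deme_a
  ib <- gt$meta$deme_id == deme_b
  if (sum(ia) < 2 || sum(ib) < 2) stop("both demes need n >= 2")
  num <- den <- 0
  for (l in colnames(gt$a1)) {
    av <- c(gt$a1[ia | ib, l], gt$a2[ia | ib, l])
    alleles <- sort(unique(av[!is.na(av)]))
    if (length(alleles) < 2) next
    ta <- locus_tab(gt$a1[ia, l], gt$a2[ia, l], alleles)
    tb <- locus_tab(gt$a1[ib, l], gt$a2[ib, l], alleles)
    if (is.null(ta) || is.null(tb) || ta$n < 2 || tb$n < 2) next
    for (k in seq_along(alleles)) {
      comp <- wc_components(c(ta$n, tb$n), c(ta$p[k], tb$p[k]), c(ta$h[k], tb$h[k]))
      num <- num + comp["a"]
      den <- den + sum(comp)
    }
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

#' Weir-Cockerham Fis of a group
#'
#' Multilocus small-f over the individuals of one deme (or any id subset):
#' f = 1 - sum(c) / sum(b + c) with the single-sample variance components
#' b = n/(n-1) * (p(1-p) - h(2n-1)/(4n)) and c = h/2, summed over alleles and
#' loci.
#'
#' @param gt A `genotype_table`.
#' @param group A deme id, or a character vector of individual ids.
#' @return f (NA if no polymorphic locus).
#' @export
fis <- function(gt, group) {
  stopifnot(inherits(gt, "genotype_table"))
  if (length(group) == 1 && group %in% gt$meta$deme_id) {
    idx <- gt$meta$deme_id == group
  } else {
    idx <- gt$meta$individual_id %in% group
  }
  if (sum(idx) < 2) stop("group needs n >= 2")
  sb <- sc <- 0
  for (l in colnames(gt$a1)) {
    a1 <- gt$a1[idx, l]; a2 <- gt$a2[idx, l]
    av <- c(a1, a2)
    alleles <- sort(unique(av[!is.na(av)]))
    if (length(alleles) < 2) next
    tl <- locus_tab(a1, a2, alleles)
    if (is.null(tl) || tl$n < 2) next
    n <- tl$n
    b <- (n / (n - 1)) * (tl$p * (1 - tl$p) - tl$h * (2 * n - 1) / (4 * n))
    sb <- sb + sum(b)
    sc <- sc + sum(tl$h / 2)
  }
  if (sb + sc == 0) return(NA_real_)
  1 - sc / (sb + sc)
}

#' Rarefied allelic richness of a deme
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, per locus sum over alleles of 1 - choose(N - Na, g) / choose(N, g),
#' averaged over loci with at least `g` typed copies (loci with fewer are
#' skipped with a warning).
#'
#' @param gt A `genotype_table`.
#' @param deme Deme id.
#' @param g Standardized number of gene copies, `1 <= g <= 2 * n_deme`.
#' @return Mean rarefied richness across usable loci.
#' @export
rarefied_richness <- function(gt, deme, g) {
  stopifnot(inherits(gt, "genotype_table"))
  idx <- gt$meta$deme_id == deme
  if (!any(idx)) stop("unknown deme: ", deme)
  if (g < 1 || g > 2 * sum(idx)) stop("g must lie in [1, 2 * n_deme]")
  vals <- c()
  for (l in colnames(gt$a1)) {
    av <- c(gt$a1[idx, l], gt$a2[idx, l])
    av <- av[!is.na(av)]
    N <- length(av)
    if (N < g) {
      warning(sprintf("locus %s skipped: %d typed copies < g = %d", l, N, g))
      next
    }
    Na <- table(av)
    vals <- c(vals, sum(1 - choose(N - Na, g) / choose(N, g)))
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Per-deme summary statistics
#'
#' @param gt A `genotype_table`.
#' @param g Rarefaction size in gene copies; default is twice the smallest
#'   deme size among demes with n >= 2.
#' @return Data frame with `deme_id`, `n`, `A` (mean alleles per locus),
#'   `AR` (rarefied richness) and `Fis` (NA for demes with n < 2).
#' @export
deme_summary <- function(gt, g = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  demes <- sort(unique(gt$meta$deme_id))
  sizes <- table(gt$meta$deme_id)
  if (is.null(g)) {
    usable <- sizes[sizes >= 2]
    if (length(usable) == 0) stop("no deme with n >= 2")
    g <- 2 * min(usable)
  }
  rows <- lapply(demes, function(d) {
    idx <- gt$meta$deme_id == d
    A <- mean(vapply(colnames(gt$a1), function(l) {
      av <- c(gt$a1[idx, l], gt$a2[idx, l])
      length(unique(av[!is.na(av)]))
    }, 0))
    if (sum(idx) >= 2) {
      AR <- suppressWarnings(rarefied_richness(gt, d, g))
      f <- fis(gt, d)
    } else {
      AR <- NA_real_; f <- NA_real_
    }
    data.frame(deme_id = d, n = sum(idx), A = A, AR = AR, Fis = f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "g") <- g
  out
}
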