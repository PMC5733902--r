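# Diploid microsatellite genotype tables. Calls are stored as two integer
# matrices (allele 1, allele 2; fragment sizes) with NA marking a missing
# locus; metadata rides in a parallel data frame.

#' Construct a genotype table
#'
#' @param meta Data frame with columns `individual_id`, `deme_id`, `lon`,
#'   `lat` and optionally `year`, `cluster_label`.
#' @param a1,a2 Integer matrices (individuals x loci) of allele identifiers
#'   (e.g. fragment sizes); `NA` in both marks a missing locus call. Column
#'   names are locus names.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(meta, a1, a2) {
  stopifnot(is.data.frame(meta), is.matrix(a1), is.matrix(a2))
  need <- c("individual_id", "deme_id", "lon", "lat")
  if (!all(need %in% names(meta))) {
    stop("meta must contain columns: ", paste(need, collapse = ", "))
  }
  meta$individual_id <- as.character(meta$individual_id)
  meta$deme_id <- as.character(meta$deme_id)
  if (anyDuplicated(meta$individual_id)) stop("duplicate individual_id")
  check_lonlat(meta$lon, meta$lat)
  if (!identical(dim(a1), dim(a2))) stop("a1 and a2 must have equal dimensions")
  if (nrow(a1) != nrow(meta)) stop("allele matrices and meta disagree on n")
  if (is.null(colnames(a1))) stop("allele matrices need locus column names")
  if (any(xor(is.na(a1), is.na(a2)))) {
    stop("a call must have exactly 2 alleles or be entirely missing")
  }
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  colnames(a2) <- colnames(a1)
  rownames(a1) <- rownames(a2) <- meta$individual_id
  structure(list(meta = meta, a1 = a1, a2 = a2), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d demes, %d loci, %d missing calls\n",
              nrow(x$meta), length(unique(x$meta$deme_id)), ncol(x$a1),
              sum(is.na(x$a1))))
  invisible(x)
}

#' Number of loci / individuals
#' @param gt A `genotype_table`.
#' @return Integer count.
#' @export
n_loci <- function(gt) ncol(gt$a1)

#' @rdname n_loci
#' @export
n_individuals <- function(gt) nrow(gt$meta)

#' Missing-locus count per individual
#' @param gt A `genotype_table`.
#' @return Named integer vector.
#' @export
missing_loci_per_individual <- function(gt) rowSums(is.na(gt$a1))

#' Read genotypes from CSV or GenePop
#'
#' CSV dialect: columns `individual_id`, `deme_id`, `lon`, `lat`, optional
#' `year` and `cluster_label`, then one column per locus holding `"120/124"`
#' style calls; an empty cell (or `NA`) is a missing call. GenePop dialect
#' (2- or 3-digit alleles): title line, locus names (one per line or
#' comma-separated), `Pop` separators; `deme_id` is assigned per block
#' (`pop1`, `pop2`, ...) and coordinates are absent (`NA`).
#'
#' @param path File path.
#' @param format `"csv"` or `"genepop"`.
#' @return A `genotype_table`.
#' @export
read_genotypes <- function(path, format = c("csv", "genepop")) {
  format <- match.arg(format)
  switch(format,
    csv = read_genotypes_csv(path),
    genepop = read_genotypes_genepop(path)
  )
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("individual_id", "deme_id", "lon", "lat")
  if (!all(need %in% names(df))) {
    stop("genotype CSV must contain columns: ", paste(need, collapse = ", "))
  }
  opt <- intersect(c("year", "cluster_label"), names(df))
  loci <- setdiff(names(df), c(need, opt))
  if (length(loci) == 0) stop("no locus columns found")
  n <- nrow(df)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci), dimnames = list(NULL, loci))
  for (j in seq_along(loci)) {
    cell <- trimws(df[[loci[j]]])
    blank <- is.na(cell) | cell == "" | cell == "NA"
    parts <- strsplit(cell[!blank], "/", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad) > 0) {
      row_no <- which(!blank)[bad[1]] + 1L  # +1 for the header line
      stop(sprintf("parse error at line %d, locus %s: a call needs exactly 2 alleles",
                   row_no, loci[j]))
    }
    al <- suppressWarnings(vapply(parts, function(p) as.integer(p), integer(2)))
    if (anyNA(al)) {
      stop(sprintf("parse error in locus %s: non-integer allele identifier", loci[j]))
    }
    a1[!blank, j] <- al[1, ]
    a2[!blank, j] <- al[2, ]
  }
  meta <- data.frame(individual_id = df$individual_id, deme_id = df$deme_id,
                     lon = as.numeric(df$lon), lat = as.numeric(df$lat),
                     stringsAsFactors = FALSE)
  if ("year" %in% opt) meta$year <- as.integer(df$year)
  if ("cluster_label" %in% opt) meta$cluster_label <- df$cluster_label
  genotype_table(meta, a1, a2)
}

read_genotypes_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a GenePop file: ", path)
  body <- lines[-1]  # drop title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("GenePop file has no 'Pop' separator")
  locus_lines <- body[seq_len(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  sample_lines <- body[-seq_len(first_pop - 1)]
  pop_id <- cumsum(grepl("^\\s*pop\\s*$", sample_lines, ignore.case = TRUE))
  keep <- !grepl("^\\s*pop\\s*$", sample_lines, ignore.case = TRUE)
  sample_lines <- sample_lines[keep]; pop_id <- pop_id[keep]
  n <- length(sample_lines)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci), dimnames = list(NULL, loci))
  ids <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(sample_lines[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed GenePop sample line: ", sample_lines[i])
    ids[i] <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    calls <- calls[nzchar(calls)]
    if (length(calls) != length(loci)) {
      stop(sprintf("parse error at sample '%s': %d calls for %d loci",
                   ids[i], length(calls), length(loci)))
    }
    w <- nchar(calls)
    if (!all(w %in% c(4L, 6L))) {
      stop(sprintf("parse error at sample '%s': alleles must be 2- or 3-digit", ids[i]))
    }
    half <- w / 2
    x1 <- as.integer(substr(calls, 1, half))
    x2 <- as.integer(substr(calls, half + 1, w))
    miss <- x1 == 0L & x2 == 0L   # GenePop missing convention
    a1[i, !miss] <- x1[!miss]
    a2[i, !miss] <- x2[!miss]
  }
  meta <- data.frame(individual_id = ids,
                     deme_id = paste0("pop", pop_id),
                     lon = NA_real_, lat = NA_real_, stringsAsFactors = FALSE)
  genotype_table(meta, a1, a2)
}

#' Write genotypes as CSV
#'
#' Inverse of [read_genotypes()] with `format = "csv"`; missing calls become
#' empty cells.
#'
#' @param gt A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  calls <- matrix("", n_individuals(gt), n_loci(gt),
                  dimnames = list(NULL, colnames(gt$a1)))
  ok <- !is.na(gt$a1)
  calls[ok] <- paste0(gt$a1[ok], "/", gt$a2[ok])
  out <- cbind(gt$meta, as.data.frame(calls, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a genotype table by individuals
#'
#' @param gt A `genotype_table`.
#' @param ids Individual ids to retain (order preserved).
#' @return A `genotype_table`.
#' @export
subset_individuals <- function(gt, ids) {
  keep <- match(ids, gt$meta$individual_id)
  if (anyNA(keep)) stop("unknown individual ids")
  genotype_table(gt$meta[keep, , drop = FALSE],
                 gt$a1[keep, , drop = FALSE], gt$a2[keep, , drop = FALSE])
}
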