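# Minimal single-band raster container (ESRI ASCII grid semantics).
# values is a numeric matrix whose FIRST row is the NORTHERNMOST row, matching
# the on-disk ASCII grid order; NoData cells are NA in memory and never enter
# arithmetic.

#' Construct a raster
#'
#' @param values Numeric matrix; row 1 is the top (northernmost) row. `NA`
#'   marks NoData.
#' @param xll,yll Coordinates of the lower-left corner (degrees).
#' @param cellsize Cell size in degrees; must be > 0.
#' @param units Free-text units label.
#' @return An object of class `land_raster`.
#' @export
land_raster <- function(values, xll, yll, cellsize, units = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1 || !is.finite(cellsize) ||
      cellsize <= 0) {
    stop("cellsize must be a single positive number")
  }
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         units = units),
    class = "land_raster"
  )
}

#' @export
print.land_raster <- function(x, ...) {
  cat(sprintf("land_raster: %d x %d cells, cellsize %g deg, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  cat(sprintf("  valid cells: %d / %d", sum(is.finite(x$values)),
              length(x$values)))
  if (nzchar(x$units)) cat("  units:", x$units)
  cat("\n")
  invisible(x)
}

#' @export
dim.land_raster <- function(x) dim(x$values)

#' Cell-center coordinates of a raster
#'
#' @param r A `land_raster`.
#' @return Data frame with columns `cell` (linear index into `r$values`),
#'   `row`, `col`, `lon`, `lat`.
#' @export
raster_cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  idx <- seq_len(nr * nc)
  rw <- ((idx - 1) %% nr) + 1      # column-major like R matrices
  cl <- ((idx - 1) %/% nr) + 1
  data.frame(
    cell = idx, row = rw, col = cl,
    lon = r$xll + (cl - 0.5) * r$cellsize,
    lat = r$yll + (nr - rw + 0.5) * r$cellsize
  )
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`) followed by whitespace-separated
#' cell values, north row first. GeoTIFF is not supported in this build; a
#' `.tif`/`.tiff` path raises an error.
#'
#' @param path File path (`.asc` / `.txt`).
#' @return A `land_raster` with NoData as `NA`.
#' @export
read_ascii_raster <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("GeoTIFF is not supported; supply an ESRI ASCII grid (.asc)")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("not an ESRI ASCII grid: ", path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header incomplete; need: ", paste(need, collapse = ", "))
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d cell values, found %d", nr * nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  land_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' Round-trips exactly with [read_ascii_raster()]: values are printed with
#' full double precision (`%.17g`), NoData as `-9999`.
#'
#' @param r A `land_raster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(r, path) {
  stopifnot(inherits(r, "land_raster"))
  m <- r$values
  nodata <- -9999
  if (any(is.finite(m) & m == nodata)) stop("value collides with NoData sentinel -9999")
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.17g", r$xll),
    sprintf("yllcorner %.17g", r$yll),
    sprintf("cellsize %.17g", r$cellsize),
    sprintf("nodata_value %d", nodata)
  )
  rows <- apply(m, 1, function(v) paste(sprintf("%.17g", v), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Standard deviation of raster values inside a circular window
#'
#' Population SD (divisor n) over valid cells whose centers fall within
#' `radius_km` of the center, by great-circle distance.
#'
#' @param r A `land_raster`.
#' @param center_lon,center_lat Circle center (degrees).
#' @param radius_km Circle radius (km).
#' @return List with `sd`, `mean` and `n_cells` (NA sd if no valid cell).
#' @export
raster_window_sd <- function(r, center_lon, center_lat, radius_km) {
  cc <- raster_cell_centers(r)
  d <- haversine_km(center_lon, center_lat, cc$lon, cc$lat)
  v <- r$values[cc$cell[d <= radius_km]]
  v <- v[is.finite(v)]
  if (length(v) == 0) return(list(sd = NA_real_, mean = NA_real_, n_cells = 0L))
  list(sd = sqrt(mean((v - mean(v))^2)), mean = mean(v), n_cells = length(v))
}
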