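#' Read and write ESRI ASCII grids
#'
#' Minimal reader/writer for the ESRI ASCII raster exchange format used for
#' mapping-unit grids and density surfaces. The in-memory representation is a
#' numeric matrix whose row 1 is the northernmost raster row, together with
#' the geographic position of the top-left corner of cell (1, 1).
#'
#' Only square cells (`cellsize`) are supported, which is what the soil
#' database stand-in uses (0.0083 decimal degrees, about 1 km at mid
#' latitudes).
#'
#' @param file path to an `.asc` file.
#' @param grid numeric matrix (row 1 = north).
#' @param origin_lon,origin_lat top-left corner of the top-left cell, decimal
#'   degrees WGS84.
#' @param resolution cell size in decimal degrees.
#' @param nodata value written for `NA` cells (default -9999).
#' @return `read_ascii_grid()` returns a list with elements `grid`,
#'   `origin_lon`, `origin_lat`, `resolution`, `nodata`;
#'   `write_ascii_grid()` returns `file` invisibly.
#' @export
read_ascii_grid <- function(file) {
  lines <- readLines(file, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && !grepl("^[-0-9.]", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (is.null(nr) || is.null(nc))
    stop("not an ESRI ASCII grid: missing nrows/ncols header", call. = FALSE)
  vals <- scan(file, skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body does not match nrows*ncols", call. = FALSE)
  nodata <- hdr$nodata_value %||% -9999
  vals[vals == nodata] <- NA_real_
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  res <- hdr$cellsize
  # header stores the lower-left corner; convert to top-left origin
  if (!is.null(hdr$xllcenter)) {
    xll <- hdr$xllcenter - res / 2
    yll <- hdr$yllcenter - res / 2
  } else {
    xll <- hdr$xllcorner
    yll <- hdr$yllcorner
  }
  list(grid = grid, origin_lon = xll, origin_lat = yll + nr * res,
       resolution = res, nodata = nodata)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, origin_lon, origin_lat, resolution, file,
                             nodata = -9999) {
  stopifnot(is.matrix(grid))
  nr <- nrow(grid); nc <- ncol(grid)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", origin_lon),
    sprintf("yllcorner %.10g", origin_lat - nr * resolution),
    sprintf("cellsize %.10g", resolution),
    sprintf("NODATA_value %g", nodata)
  ), con)
  body <- grid
  body[is.na(body)] <- nodata
  utils::write.table(body, con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
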