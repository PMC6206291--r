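#' Soil landscape container
#'
#' A `soil_landscape` couples a raster of mapping-unit identifiers with an
#' attribute table holding one soil record per mapping unit — the structure
#' of harmonized global soil databases, where a single `mu_id` links the GIS
#' layer to the attribute database. Cell (1, 1) is the north-west corner;
#' `origin_lon`/`origin_lat` give the top-left corner of that cell.
#'
#' @param grid integer matrix of mapping-unit ids; `NA` marks NODATA cells.
#' @param attributes data frame with columns `mu_id`, `su_sym90` (soil-unit
#'   symbol), `t_ph_h2o`, `s_ph_h2o` (topsoil/subsoil pH in water),
#'   `t_caco3`, `s_caco3` (CaCO3, percent weight). Subsoil fields may be
#'   `NA`.
#' @param origin_lon,origin_lat top-left corner, decimal degrees WGS84.
#' @param resolution cell size in decimal degrees; must be positive.
#' @return an object of class `soil_landscape`.
#' @export
soil_landscape <- function(grid, attributes, origin_lon, origin_lat,
                           resolution) {
  stopifnot(is.matrix(grid))
  assert_scalar_number(resolution, "resolution", positive = TRUE)
  req <- c("mu_id", "su_sym90", "t_ph_h2o", "s_ph_h2o", "t_caco3", "s_caco3")
  missing_cols <- setdiff(req, names(attributes))
  if (length(missing_cols))
    stop("attribute table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(attributes$mu_id))
    stop("attribute table has duplicated mu_id: each mapping unit must ",
         "carry exactly one soil record", call. = FALSE)
  used <- unique(grid[!is.na(grid)])
  orphan <- setdiff(used, attributes$mu_id)
  if (length(orphan))
    stop("mapping units present in grid but absent from attribute table: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  structure(
    list(grid = grid, attributes = attributes,
         origin_lon = origin_lon, origin_lat = origin_lat,
         resolution = resolution),
    class = "soil_landscape")
}

#' @export
print.soil_landscape <- function(x, ...) {
  cat(sprintf("soil_landscape: %d x %d cells at %.5g deg (%d mapping units)\n",
              nrow(x$grid), ncol(x$grid), x$resolution,
              nrow(x$attributes)))
  cat(sprintf("  origin (top-left): lon %.5f, lat %.5f\n",
              x$origin_lon, x$origin_lat))
  cat(sprintf("  NODATA cells: %d\n", sum(is.na(x$grid))))
  invisible(x)
}

#' @export
dim.soil_landscape <- function(x) dim(x$grid)

#' Write / read a soil landscape as plain-text files
#'
#' The raster goes to an ESRI ASCII grid (`mu_id` integers, NODATA -9999)
#' and the attribute table to a TSV with empty fields for missing values.
#'
#' @param landscape a [soil_landscape()].
#' @param grid_file,attr_file output/input paths.
#' @return `write_landscape()` returns the paths invisibly;
#'   `read_landscape()` returns a `soil_landscape`.
#' @export
write_landscape <- function(landscape, grid_file, attr_file) {
  write_ascii_grid(landscape$grid, landscape$origin_lon,
                   landscape$origin_lat, landscape$resolution, grid_file)
  write_tsv(landscape$attributes, attr_file)
  invisible(c(grid = grid_file, attributes = attr_file))
}

#' @rdname write_landscape
#' @export
read_landscape <- function(grid_file, attr_file) {
  g <- read_ascii_grid(grid_file)
  attr_tab <- read_tsv(attr_file)
  grid <- g$grid
  storage.mode(grid) <- "integer"
  soil_landscape(grid, attr_tab, g$origin_lon, g$origin_lat, g$resolution)
}

# Attribute row for each cell of the grid, as a data frame aligned with
# as.vector(grid) (column-major). NODATA cells yield NA rows.
cell_attributes <- function(landscape) {
  idx <- match(as.vector(landscape$grid), landscape$attributes$mu_id)
  landscape$attributes[idx, , drop = FALSE]
}
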