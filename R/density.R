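#' Quartic-kernel density surface of occurrence points
#'
#' Computes the kernel density surface behind occurrence heat maps: at each
#' cell centre, the sum over points of the quartic (biweight) kernel
#' K(d) = 3/pi * (1 - (d/h)^2)^2 for d < h (zero beyond), scaled by 1/h^2,
#' so each point contributes unit mass to the surface integral. Distances
#' are planar in decimal degrees, matching the kernel family of common GIS
#' heat-map tools; the bandwidth is a required user choice.
#'
#' @param points data frame with columns `lat`, `lon` (decimal degrees).
#' @param origin_lon,origin_lat top-left corner of the output grid; with
#'   `n_rows`/`n_cols` `NULL`, the extent is fitted to the points padded by
#'   one bandwidth.
#' @param n_rows,n_cols output grid size.
#' @param resolution output cell size, decimal degrees.
#' @param bandwidth kernel radius h in decimal degrees (> 0).
#' @return list of class `density_surface`: `grid` (densities, row 1 =
#'   north), `origin_lon`, `origin_lat`, `resolution`, `bandwidth`.
#' @export
kernel_density <- function(points, origin_lon = NULL, origin_lat = NULL,
                           n_rows = NULL, n_cols = NULL,
                           resolution = 0.05, bandwidth = 1.0) {
  assert_scalar_number(bandwidth, "bandwidth", positive = TRUE)
  assert_scalar_number(resolution, "resolution", positive = TRUE)
  if (is.null(origin_lon) || is.null(origin_lat) ||
      is.null(n_rows) || is.null(n_cols)) {
    if (!nrow(points))
      stop("cannot fit an extent to zero points; give origin and size",
           call. = FALSE)
    pad <- bandwidth
    origin_lon <- min(points$lon) - pad
    origin_lat <- max(points$lat) + pad
    n_cols <- ceiling((max(points$lon) + pad - origin_lon) / resolution)
    n_rows <- ceiling((origin_lat - (min(points$lat) - pad)) / resolution)
  }
  grid <- matrix(0, nrow = n_rows, ncol = n_cols)
  if (nrow(points)) {
    cx <- origin_lon + (seq_len(n_cols) - 0.5) * resolution
    cy <- origin_lat - (seq_len(n_rows) - 0.5) * resolution
    for (k in seq_len(nrow(points))) {
      px <- points$lon[k]; py <- points$lat[k]
      js <- which(abs(cx - px) < bandwidth)
      is <- which(abs(cy - py) < bandwidth)
      if (!length(js) || !length(is)) next
      d2 <- outer((cy[is] - py)^2, (cx[js] - px)^2, `+`)
      u2 <- d2 / bandwidth^2
      contrib <- ifelse(u2 < 1, 3 / pi * (1 - u2)^2, 0) / bandwidth^2
      grid[is, js] <- grid[is, js] + contrib
    }
  }
  structure(list(grid = grid, origin_lon = origin_lon,
                 origin_lat = origin_lat, resolution = resolution,
                 bandwidth = bandwidth),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf(
    "density_surface: %d x %d cells at %.4g deg, bandwidth %.4g deg\n",
    nrow(x$grid), ncol(x$grid), x$resolution, x$bandwidth))
  cat(sprintf("  total mass (integral): %.4g\n",
              sum(x$grid) * x$resolution^2))
  invisible(x)
}

#' Write a density surface as an ESRI ASCII grid
#'
#' @param surface a [kernel_density()] result.
#' @param file output path.
#' @export
write_density <- function(surface, file) {
  write_ascii_grid(surface$grid, surface$origin_lon, surface$origin_lat,
                   surface$resolution, file)
}
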