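#' Locate points in the landscape grid
#'
#' Direct grid arithmetic replacing a GIS point-extraction step: cells are
#' half-open rectangles, so a point on an interior boundary belongs to the
#' cell with the higher index and every in-extent point has exactly one
#' cell. Indices are 1-based; cell (1, 1) is the north-west corner.
#'
#' @param lat,lon point coordinates, decimal degrees WGS84.
#' @param landscape a [soil_landscape()].
#' @return data frame with columns `row`, `col` (`NA` when out of extent)
#'   and `in_extent`.
#' @export
locate_cell <- function(lat, lon, landscape) {
  stopifnot(inherits(landscape, "soil_landscape"))
  res <- landscape$resolution
  col <- floor((lon - landscape$origin_lon) / res) + 1
  row <- floor((landscape$origin_lat - lat) / res) + 1
  ok <- row >= 1 & row <= nrow(landscape$grid) &
        col >= 1 & col <= ncol(landscape$grid)
  data.frame(row = ifelse(ok, row, NA_integer_),
             col = ifelse(ok, col, NA_integer_),
             in_extent = ok)
}

#' Join specimens to their cell's soil attributes
#'
#' Each geocoded specimen is located in the mapping-unit grid and joined to
#' the single attribute record of its cell's mapping unit. Specimens outside
#' the grid extent or on NODATA cells are returned separately with the
#' reason `"out_of_region"`.
#'
#' @param specimens data frame with `lat`, `lon` columns (geocoded, i.e.
#'   `matched` true where present).
#' @param landscape a [soil_landscape()].
#' @return list with `linked` (input columns + `row`, `col`, `mu_id` and the
#'   attribute columns) and `unlinked` (input columns + `reason`).
#' @export
link_specimens <- function(specimens, landscape) {
  if ("matched" %in% names(specimens) && any(!specimens$matched))
    stop("link_specimens expects geocoded specimens; drop unmatched rows ",
         "first", call. = FALSE)
  cells <- locate_cell(specimens$lat, specimens$lon, landscape)
  nr <- nrow(landscape$grid)
  mu <- rep(NA_integer_, nrow(specimens))
  inb <- cells$in_extent
  mu[inb] <- landscape$grid[cbind(cells$row[inb], cells$col[inb])]
  linked_ok <- inb & !is.na(mu)

  idx <- match(mu[linked_ok], landscape$attributes$mu_id)
  if (anyNA(idx))
    stop("grid mapping unit absent from attribute table", call. = FALSE)
  attrs <- landscape$attributes[idx, , drop = FALSE]
  linked <- cbind(specimens[linked_ok, , drop = FALSE],
                  row = cells$row[linked_ok], col = cells$col[linked_ok],
                  attrs, stringsAsFactors = FALSE)
  rownames(linked) <- NULL
  unlinked <- specimens[!linked_ok, , drop = FALSE]
  if (nrow(unlinked)) unlinked$reason <- "out_of_region"
  else unlinked$reason <- character(0)
  rownames(unlinked) <- NULL
  list(linked = linked, unlinked = unlinked)
}

#' Apply the cleaning rules and account for every removal
#'
#' Removal rules, applied in a fixed first-match order so the ledger is well
#' defined even when a record violates several:
#' 1. `out_of_region` — missing mapping unit (`NA` `mu_id`), or, when a
#'    `mu_whitelist` is supplied, a mapping unit outside it (reproducing an
#'    id-range test for the study region);
#' 2. `excluded_surface` — soil-unit symbol in `WR`, `RK`, `GG`, `UR`
#'    (inland water, rock debris, glaciers and permanent snow, urban area);
#' 3. `missing_subsoil` — either subsoil attribute absent.
#'
#' @param linked a data frame of linked specimens (columns `mu_id`,
#'   `su_sym90`, `s_ph_h2o`, `s_caco3`), or the list returned by
#'   [link_specimens()] (its `unlinked` part is counted as
#'   `out_of_region`).
#' @param mu_whitelist optional vector of admissible mapping-unit ids.
#' @return list with `retained` (data frame), `removed` (data frame with a
#'   `reason` column) and `ledger` (named integer vector over the three
#'   reasons; sums to `nrow(input) - nrow(retained)`).
#' @export
clean_dataset <- function(linked, mu_whitelist = NULL) {
  if (is.list(linked) && !is.data.frame(linked) &&
      all(c("linked", "unlinked") %in% names(linked))) {
    un <- linked$unlinked
    keep <- intersect(names(linked$linked), names(un))
    df <- linked$linked
    if (nrow(un)) {
      pad <- linked$linked[0, , drop = FALSE]
      for (nm in names(pad)) {
        pad[seq_len(nrow(un)), nm] <-
          if (nm %in% keep) un[[nm]] else NA
      }
      df <- rbind(df, pad)
    }
    linked <- df
  }
  reasons <- c("out_of_region", "excluded_surface", "missing_subsoil")
  reason <- rep(NA_character_, nrow(linked))

  oor <- is.na(linked$mu_id)
  if (!is.null(mu_whitelist))
    oor <- oor | !(linked$mu_id %in% mu_whitelist)
  reason[oor] <- "out_of_region"

  excl <- is.na(reason) & linked$su_sym90 %in% EXCLUDED_SURFACE_CODES
  reason[excl] <- "excluded_surface"

  miss <- is.na(reason) & (is.na(linked$s_ph_h2o) | is.na(linked$s_caco3))
  reason[miss] <- "missing_subsoil"

  ledger <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), 0L)
  retained <- linked[is.na(reason), , drop = FALSE]
  removed <- linked[!is.na(reason), , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!is.na(reason)]
  else removed$reason <- character(0)
  rownames(retained) <- NULL
  rownames(removed) <- NULL
  list(retained = retained, removed = removed, ledger = ledger)
}
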