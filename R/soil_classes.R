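#' Soil attribute classes
#'
#' Bins pH into the five ranges `<4.5`, `4.5-5.5`, `5.5-7.2`, `7.2-8.5`,
#' `>8.5` and CaCO3 (percent weight) into the four classes `<2`, `2-5`,
#' `5-15`, `>15` used by the harmonized soil database. Interior bins are
#' lower-inclusive/upper-exclusive (pH 4.5 falls in `4.5-5.5`; CaCO3 2.0 in
#' `2-5`); the printed ranges do not state the side, so one convention is
#' fixed and documented here.
#'
#' @param v numeric vector of pH values / CaCO3 percentages; `NA` is an
#'   error (classes are only defined for present values).
#' @return ordered factor over the class labels.
#' @export
ph_class <- function(v) {
  if (anyNA(v)) stop("pH value missing; classes need a present value",
                     call. = FALSE)
  cut(v, breaks = c(-Inf, 4.5, 5.5, 7.2, 8.5, Inf),
      labels = PH_CLASS_LABELS, right = FALSE, ordered_result = TRUE)
}

#' @rdname ph_class
#' @export
caco3_class <- function(v) {
  if (anyNA(v)) stop("CaCO3 value missing; classes need a present value",
                     call. = FALSE)
  cut(v, breaks = c(-Inf, 2, 5, 15, Inf),
      labels = CACO3_CLASS_LABELS, right = FALSE, ordered_result = TRUE)
}

#' @rdname ph_class
#' @export
PH_CLASS_LABELS <- c("<4.5", "4.5-5.5", "5.5-7.2", "7.2-8.5", ">8.5")

#' @rdname ph_class
#' @export
CACO3_CLASS_LABELS <- c("<2", "2-5", "5-15", ">15")

attribute_column <- function(attribute = c("ph", "caco3"),
                             layer = c("topsoil", "subsoil")) {
  attribute <- match.arg(attribute)
  layer <- match.arg(layer)
  paste0(substr(layer, 1, 1),
         if (attribute == "ph") "_ph_h2o" else "_caco3")
}

class_fun <- function(attribute) {
  if (attribute == "ph") ph_class else caco3_class
}

#' Per-class distribution of grid cells, specimens and taxa
#'
#' Tallies, for each attribute class, how many landscape grid cells carry a
#' value in the class, how many specimens fall in it, and how many taxa have
#' at least one specimen in it. Cells are counted over the whole landscape
#' (not just occupied cells); a taxon is counted in every class where it
#' occurs, so taxon percentages may sum past 100.
#'
#' @param linked data frame of cleaned linked specimens (with `latin_name`
#'   and the attribute columns).
#' @param landscape a [soil_landscape()].
#' @param attribute `"ph"` or `"caco3"`.
#' @param layer `"topsoil"` or `"subsoil"`.
#' @return data frame, one row per class: `class`, `n_cells`, `pct_cells`,
#'   `n_specimens`, `pct_specimens`, `n_taxa`, `pct_taxa`. Percentages are
#'   exact (round for display); an attribute `empty` flags a zero-specimen
#'   input.
#' @export
distribution_table <- function(linked, landscape,
                               attribute = c("ph", "caco3"),
                               layer = c("topsoil", "subsoil")) {
  attribute <- match.arg(attribute); layer <- match.arg(layer)
  col <- attribute_column(attribute, layer)
  cls <- class_fun(attribute)
  labels <- if (attribute == "ph") PH_CLASS_LABELS else CACO3_CLASS_LABELS

  cell_vals <- cell_attributes(landscape)[[col]]
  cell_vals <- cell_vals[!is.na(cell_vals)]
  n_cells <- table(factor(cls(cell_vals), levels = labels))

  spec_vals <- linked[[col]]
  spec_cls <- if (length(spec_vals)) cls(spec_vals) else
    factor(character(), levels = labels)
  n_spec <- table(factor(spec_cls, levels = labels))

  n_total_taxa <- length(unique(linked$latin_name))
  n_taxa <- vapply(labels, function(lb)
    length(unique(linked$latin_name[spec_cls == lb])), 0L)

  pct <- function(n, total) if (total > 0) 100 * as.numeric(n) / total
         else rep(0, length(n))
  out <- data.frame(
    class = labels,
    n_cells = as.integer(n_cells),
    pct_cells = pct(n_cells, length(cell_vals)),
    n_specimens = as.integer(n_spec),
    pct_specimens = pct(n_spec, nrow(linked)),
    n_taxa = as.integer(n_taxa),
    pct_taxa = pct(n_taxa, n_total_taxa),
    stringsAsFactors = FALSE)
  attr(out, "empty") <- nrow(linked) == 0
  attr(out, "attribute") <- attribute
  attr(out, "layer") <- layer
  out
}

#' Per-value histogram of specimens, taxa and grid cells
#'
#' One row per distinct attribute value found among the specimens or the
#' landscape cells, with specimen/taxon/cell counts and percentages — the
#' data behind per-value occurrence histograms, where a taxon can appear at
#' several values.
#'
#' @inheritParams distribution_table
#' @return data frame: `value`, `n_cells`, `pct_cells`, `n_specimens`,
#'   `pct_specimens`, `n_taxa`, `pct_taxa`, sorted by value.
#' @export
value_histogram <- function(linked, landscape,
                            attribute = c("ph", "caco3"),
                            layer = c("topsoil", "subsoil")) {
  attribute <- match.arg(attribute); layer <- match.arg(layer)
  col <- attribute_column(attribute, layer)

  cell_vals <- cell_attributes(landscape)[[col]]
  cell_vals <- cell_vals[!is.na(cell_vals)]
  spec_vals <- linked[[col]]

  values <- sort(unique(c(cell_vals, spec_vals)))
  n_cells <- vapply(values, function(v) sum(cell_vals == v), 0L)
  n_spec <- vapply(values, function(v) sum(spec_vals == v), 0L)
  n_taxa <- vapply(values, function(v)
    length(unique(linked$latin_name[spec_vals == v])), 0L)
  n_total_taxa <- length(unique(linked$latin_name))

  pct <- function(n, total) if (total > 0) 100 * as.numeric(n) / total
         else rep(0, length(n))
  data.frame(
    value = values,
    n_cells = n_cells, pct_cells = pct(n_cells, length(cell_vals)),
    n_specimens = n_spec, pct_specimens = pct(n_spec, nrow(linked)),
    n_taxa = n_taxa, pct_taxa = pct(n_taxa, n_total_taxa),
    stringsAsFactors = FALSE)
}
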