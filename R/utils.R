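# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Derive a per-stage seed from a top-level seed; result stays below 2^31.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read/write TSV with the conventions used throughout: tab-separated, header,
# empty field = missing, no quoting, no row names.
read_tsv <- function(file, ...) {
  utils::read.delim(file, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(file)
}

# Soil-unit symbols removed at cleaning: inland water, rock debris,
# glaciers/permanent snow, urban area.
EXCLUDED_SURFACE_CODES <- c("WR", "RK", "GG", "UR")

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
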