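#' Per-taxon topsoil quartile summaries
#'
#' For every taxon with at least `min_n` specimens, computes the lower
#' quartile, median and upper quartile of topsoil pH and CaCO3 over its
#' specimens, plus the percentage of its specimens in each pH and CaCO3
#' class. Species, varieties and subspecies are treated as separate taxa at
#' the same level. The median describes a taxon's central soil conditions;
#' the upper quartile captures the more extreme (alkaline, calcareous) end
#' of its realized niche and is the tolerance indicator downstream.
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7, p(k) = (k-1)/(n-1)); the rule is exposed via
#' `quantile_type` since printed quartiles cannot pin it down uniquely.
#'
#' @param linked cleaned linked specimens (columns `latin_name`, `rank`,
#'   `subgenus`, `t_ph_h2o`, `t_caco3`).
#' @param min_n minimum specimen count for a taxon to be summarized
#'   (default 10).
#' @param quantile_type quantile algorithm passed to [stats::quantile()].
#' @return data frame, one row per retained taxon: `latin_name`, `rank`,
#'   `subgenus`, `n`, `ph_lq`, `ph_median`, `ph_uq`, `caco3_lq`,
#'   `caco3_median`, `caco3_uq`, and `pct_ph_<class>` / `pct_caco3_<class>`
#'   columns.
#' @export
taxon_quartiles <- function(linked, min_n = 10L, quantile_type = 7L) {
  stopifnot(min_n >= 1)
  counts <- table(linked$latin_name)
  keep <- names(counts)[counts >= min_n]
  rows <- lapply(keep, function(tx) {
    sub <- linked[linked$latin_name == tx, , drop = FALSE]
    qp <- stats::quantile(sub$t_ph_h2o, c(0.25, 0.5, 0.75),
                          type = quantile_type, names = FALSE)
    qc <- stats::quantile(sub$t_caco3, c(0.25, 0.5, 0.75),
                          type = quantile_type, names = FALSE)
    pcts_ph <- 100 * as.numeric(
      table(factor(ph_class(sub$t_ph_h2o), levels = PH_CLASS_LABELS))) /
      nrow(sub)
    pcts_ca <- 100 * as.numeric(
      table(factor(caco3_class(sub$t_caco3),
                   levels = CACO3_CLASS_LABELS))) / nrow(sub)
    out <- data.frame(
      latin_name = tx, rank = sub$rank[1], subgenus = sub$subgenus[1],
      n = nrow(sub),
      ph_lq = qp[1], ph_median = qp[2], ph_uq = qp[3],
      caco3_lq = qc[1], caco3_median = qc[2], caco3_uq = qc[3],
      stringsAsFactors = FALSE)
    out[paste0("pct_ph_", PH_CLASS_LABELS)] <- as.list(pcts_ph)
    out[paste0("pct_caco3_", CACO3_CLASS_LABELS)] <- as.list(pcts_ca)
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(latin_name = character(), rank = character(),
                      subgenus = character(), n = integer(),
                      ph_lq = numeric(), ph_median = numeric(),
                      ph_uq = numeric(), caco3_lq = numeric(),
                      caco3_median = numeric(), caco3_uq = numeric(),
                      stringsAsFactors = FALSE)
    res[paste0("pct_ph_", PH_CLASS_LABELS)] <- list(numeric())
    res[paste0("pct_caco3_", CACO3_CLASS_LABELS)] <- list(numeric())
  }
  rownames(res) <- NULL
  res
}

#' Upper-quartile threshold prediction of lime tolerance
#'
#' A taxon is predicted lime tolerant when the upper quartile of its
#' specimens' topsoil pH strictly exceeds `ph_threshold` AND the upper
#' quartile of topsoil CaCO3 strictly exceeds `caco3_threshold`. The
#' defaults (pH 7.2, CaCO3 2 percent weight) mark carbonate-rich soils in
#' the harmonized soil database classification; values exactly at a
#' threshold are not tolerant (strict inequality).
#'
#' @param summaries output of [taxon_quartiles()].
#' @param ph_threshold,caco3_threshold thresholds on the upper quartiles.
#' @return data frame `latin_name`, `rank`, `subgenus`, `n`, `ph_uq`,
#'   `caco3_uq`, `tolerant`.
#' @export
predict_tolerance <- function(summaries, ph_threshold = 7.2,
                              caco3_threshold = 2) {
  data.frame(
    latin_name = summaries$latin_name, rank = summaries$rank,
    subgenus = summaries$subgenus, n = summaries$n,
    ph_uq = summaries$ph_uq, caco3_uq = summaries$caco3_uq,
    tolerant = summaries$ph_uq > ph_threshold &
               summaries$caco3_uq > caco3_threshold,
    stringsAsFactors = FALSE)
}

#' Lime/non-lime contingency counts for prediction validation
#'
#' Classifies every cleaned specimen's topsoil as lime (pH > 7.2 and CaCO3
#' > 2 percent weight), non-lime (pH <= 7.2 and CaCO3 <= 2), or mixed
#' (satisfying neither conjunction; excluded from the table but counted),
#' and cross-tabulates against the taxon-level prediction.
#'
#' @param linked cleaned linked specimens.
#' @param predictions output of [predict_tolerance()]. Taxa absent from it
#'   (below the `min_n` cutoff) are assigned to the non-tolerant row by
#'   default, or dropped with `below_min_n = "exclude"`.
#' @param ph_threshold,caco3_threshold lime-soil definition thresholds.
#' @param below_min_n `"non_tolerant"` or `"exclude"`.
#' @return list with `counts` (2x2 integer matrix, rows predicted
#'   tolerant/non-tolerant, columns lime/non-lime), `n_mixed_excluded`, and
#'   `n_below_min_n_excluded` (0 unless `below_min_n = "exclude"`).
#' @export
lime_contingency <- function(linked, predictions, ph_threshold = 7.2,
                             caco3_threshold = 2,
                             below_min_n = c("non_tolerant", "exclude")) {
  below_min_n <- match.arg(below_min_n)
  pred <- predictions$tolerant[match(linked$latin_name,
                                     predictions$latin_name)]
  n_dropped <- 0L
  if (below_min_n == "exclude") {
    drop <- is.na(pred)
    n_dropped <- sum(drop)
    linked <- linked[!drop, , drop = FALSE]
    pred <- pred[!drop]
  } else {
    pred[is.na(pred)] <- FALSE
  }
  lime <- linked$t_ph_h2o > ph_threshold & linked$t_caco3 > caco3_threshold
  nonlime <- linked$t_ph_h2o <= ph_threshold &
             linked$t_caco3 <= caco3_threshold
  mixed <- !lime & !nonlime
  counts <- matrix(c(
    sum(pred & lime), sum(pred & nonlime),
    sum(!pred & lime), sum(!pred & nonlime)),
    nrow = 2, byrow = TRUE,
    dimnames = list(predicted = c("tolerant", "non_tolerant"),
                    soil = c("lime", "non_lime")))
  list(counts = counts, n_mixed_excluded = sum(mixed),
       n_below_min_n_excluded = n_dropped)
}

#' Chi-square test for a 2x2 contingency table
#'
#' Pearson chi-square statistic with optional Yates continuity correction
#' (subtract 0.5 from each |O - E|, floored at zero, before squaring), df =
#' 1, upper-tail p-value. The correction is on by default, matching the
#' default 2x2 behaviour of standard statistical software.
#'
#' @param counts 2x2 matrix of non-negative counts with positive margins.
#' @param correction apply the Yates continuity correction.
#' @return list of class `contingency_result`: `counts`, `statistic`, `df`,
#'   `p_value`, `correction`, and `p_display` (`"< 2.2e-16"` below that
#'   floor).
#' @export
chi_square_2x2 <- function(counts, correction = TRUE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)))
    stop("counts must be a 2x2 matrix", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  r <- rowSums(counts); c_ <- colSums(counts); n <- sum(counts)
  if (any(r == 0) || any(c_ == 0))
    stop("zero margin: expected counts undefined", call. = FALSE)
  expected <- outer(r, c_) / n
  dev <- abs(counts - expected)
  if (correction) dev <- pmax(0, dev - 0.5)
  statistic <- sum(dev^2 / expected)
  p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  structure(list(counts = counts, statistic = statistic, df = 1L,
                 p_value = p, correction = correction,
                 p_display = if (p < 2.2e-16) "< 2.2e-16"
                             else format(p, digits = 4)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 chi-square test",
      if (x$correction) "(Yates continuity correction)" else "(uncorrected)",
      "\n")
  print(x$counts)
  cat(sprintf("X-squared = %.4g, df = %d, p-value %s\n",
              x$statistic, x$df,
              if (startsWith(x$p_display, "<")) x$p_display
              else paste("=", x$p_display)))
  invisible(x)
}

#' Taxonomy coverage and top-taxa summary
#'
#' Counts distinct taxa per rank and distinct species per subgenus, relates
#' them to reference counts of described taxa, and lists the `top_n` taxa
#' by specimen count with their share of all records.
#'
#' @param specimens cleaned specimen data frame (`latin_name`, `rank`,
#'   `subgenus`).
#' @param described_species data frame with columns `subgenus`,
#'   `n_described`: described species per subgenus in the study region.
#' @param described_varieties,described_subspecies described counts for the
#'   other two ranks.
#' @param top_n size of the top-taxa table.
#' @return list with `by_subgenus` (dataset vs described species counts),
#'   `by_rank` (counts + coverage percent, one decimal), `n_taxa_total`,
#'   and `top_taxa` (`latin_name`, `n_specimens`, `pct_of_records`).
#' @export
taxonomy_summary <- function(specimens, described_species,
                             described_varieties = 0L,
                             described_subspecies = 0L, top_n = 20L) {
  species <- unique(specimens$latin_name[specimens$rank == "species"])
  sp_sub <- unique(specimens[specimens$rank == "species",
                             c("latin_name", "subgenus")])
  unknown <- setdiff(unique(sp_sub$subgenus), described_species$subgenus)
  if (length(unknown))
    stop("subgenus absent from reference table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  by_subgenus <- data.frame(
    subgenus = described_species$subgenus,
    n_dataset = vapply(described_species$subgenus, function(sg)
      sum(sp_sub$subgenus == sg), 0L),
    n_described = described_species$n_described,
    stringsAsFactors = FALSE)

  n_rank <- function(rk) length(unique(specimens$latin_name[
    specimens$rank == rk]))
  counts <- c(species = length(species),
              variety = n_rank("variety"),
              subspecies = n_rank("subspecies"))
  described <- c(species = sum(described_species$n_described),
                 variety = described_varieties,
                 subspecies = described_subspecies)
  coverage <- ifelse(described > 0, round(100 * counts / described, 1), NA)
  by_rank <- data.frame(rank = names(counts), n_dataset = as.integer(counts),
                        n_described = as.integer(described),
                        coverage_pct = as.numeric(coverage),
                        stringsAsFactors = FALSE)

  tab <- sort(table(specimens$latin_name), decreasing = TRUE)
  top <- utils::head(tab, top_n)
  n_total <- nrow(specimens)
  top_taxa <- data.frame(
    latin_name = names(top), n_specimens = as.integer(top),
    pct_of_records = if (n_total > 0) 100 * as.integer(top) / n_total
                     else numeric(length(top)),
    stringsAsFactors = FALSE)
  rownames(top_taxa) <- NULL
  list(by_subgenus = by_subgenus, by_rank = by_rank,
       n_taxa_total = sum(counts),
       n_specimens_total = n_total,
       top_taxa = top_taxa,
       top_share_pct = if (n_total > 0)
         round(100 * sum(top_taxa$n_specimens) / n_total, 1) else 0)
}
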