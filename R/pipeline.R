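#' Configuration for an end-to-end pipeline run
#'
#' Bundles the generator settings, analysis thresholds and the seed for a
#' full simulate -> geocode -> link -> clean -> summarize -> predict ->
#' validate run. One top-level seed drives every stage; stage seeds are
#' derived deterministically from it.
#'
#' @param out_dir directory for all stage outputs (created if absent).
#' @param seed top-level integer seed.
#' @param n_taxa,tolerant_fraction,n_specimens_per_taxon generator settings
#'   (see [generate_taxa()]).
#' @param landscape a [landscape_config()] (its `seed` is overridden by the
#'   run seed).
#' @param noise_km geocoding noise (see [generate_gazetteer()]).
#' @param ph_threshold,caco3_threshold,min_n analysis thresholds.
#' @param quantile_type quantile rule for [taxon_quartiles()].
#' @param correction Yates correction flag for [chi_square_2x2()].
#' @param density_resolution,density_bandwidth settings for the occurrence
#'   density surface, decimal degrees.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       n_taxa = 40L, tolerant_fraction = 0.5,
                       n_specimens_per_taxon = 50L,
                       landscape = landscape_config(),
                       noise_km = 0.5,
                       ph_threshold = 7.2, caco3_threshold = 2,
                       min_n = 10L, quantile_type = 7L, correction = TRUE,
                       density_resolution = 0.05, density_bandwidth = 0.2) {
  if (ph_threshold <= 0 || caco3_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  if (min_n < 1) stop("min_n must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' Executes every stage in order, writes all intermediates as plain-text
#' TSV/ASCII-grid/JSON files under `config$out_dir`, and returns a manifest
#' whose per-stage record counts reconcile exactly (linked = retained +
#' removal-ledger total, etc.).
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list: `manifest` (also written as `manifest.json`)
#'   plus the in-memory stage results (`landscape`, `specimens`,
#'   `cleaned`, `summaries`, `predictions`, `contingency`, `test`,
#'   `accuracy`, `density`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("stage simulate: landscape")
  lc <- config$landscape
  lc$seed <- derive_seed(config$seed, 11L)
  landscape <- generate_landscape(lc)
  write_landscape(landscape, path("landscape.asc"), path("attributes.tsv"))

  taxa <- generate_taxa(config$n_taxa, config$tolerant_fraction,
                        seed = derive_seed(config$seed, 12L),
                        n_specimens = config$n_specimens_per_taxon)
  write_tsv(taxa, path("taxa_truth.tsv"))
  specimens <- generate_specimens(taxa, landscape,
                                  seed = derive_seed(config$seed, 13L))
  gz <- generate_gazetteer(specimens, landscape,
                           noise_km = config$noise_km,
                           seed = derive_seed(config$seed, 14L))
  specimens <- gz$specimens
  write_tsv(specimens, path("specimens.tsv"))
  write_tsv(gz$gazetteer, path("gazetteer.tsv"))

  say("stage geocode: %d specimens", nrow(specimens))
  geo <- geocode_specimens(specimens, gz$gazetteer)
  write_tsv(geo, path("specimens_geocoded.tsv"))
  matched <- geo[geo$matched, , drop = FALSE]
  acc <- accuracy_stats(matched[, c("lat", "lon")],
                        data.frame(lat = matched$true_lat,
                                   lon = matched$true_lon))
  write_tsv(acc, path("geocoding_accuracy.tsv"))

  say("stage link")
  link <- link_specimens(matched, landscape)
  write_tsv(link$linked, path("linked.tsv"))

  say("stage clean")
  cleaned <- clean_dataset(link)
  write_tsv(cleaned$retained, path("cleaned.tsv"))
  write_tsv(data.frame(reason = names(cleaned$ledger),
                       n_removed = as.integer(cleaned$ledger)),
            path("removal_ledger.tsv"))

  say("stage summarize")
  for (attrib in c("ph", "caco3")) for (layer in c("topsoil", "subsoil")) {
    write_tsv(distribution_table(cleaned$retained, landscape, attrib, layer),
              path(sprintf("distribution_%s_%s.tsv", attrib, layer)))
  }
  write_tsv(value_histogram(cleaned$retained, landscape, "ph", "topsoil"),
            path("histogram_ph_topsoil.tsv"))

  say("stage predict")
  summaries <- taxon_quartiles(cleaned$retained, min_n = config$min_n,
                               quantile_type = config$quantile_type)
  write_tsv(summaries, path("taxon_quartiles.tsv"))
  predictions <- predict_tolerance(summaries, config$ph_threshold,
                                   config$caco3_threshold)
  write_tsv(predictions, path("predictions.tsv"))

  say("stage validate")
  contingency <- lime_contingency(cleaned$retained, predictions,
                                  config$ph_threshold,
                                  config$caco3_threshold)
  test <- chi_square_2x2(contingency$counts, config$correction)
  jsonlite::write_json(list(
    counts = contingency$counts,
    n_mixed_excluded = contingency$n_mixed_excluded,
    statistic = test$statistic, df = test$df, p_value = test$p_value,
    p_display = test$p_display, correction = test$correction),
    path("contingency.json"), auto_unbox = TRUE, digits = NA)

  say("stage density")
  density <- kernel_density(
    data.frame(lat = cleaned$retained$lat, lon = cleaned$retained$lon),
    resolution = config$density_resolution,
    bandwidth = config$density_bandwidth)
  write_density(density, path("density.asc"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("calciphile")),
    seed = config$seed,
    parameters = list(
      n_taxa = config$n_taxa, tolerant_fraction = config$tolerant_fraction,
      n_specimens_per_taxon = config$n_specimens_per_taxon,
      noise_km = config$noise_km, ph_threshold = config$ph_threshold,
      caco3_threshold = config$caco3_threshold, min_n = config$min_n,
      quantile_type = config$quantile_type, correction = config$correction),
    counts = list(
      simulated = nrow(specimens),
      geocoded = nrow(matched),
      unmatched = sum(!geo$matched),
      linked = nrow(link$linked),
      unlinked = nrow(link$unlinked),
      retained = nrow(cleaned$retained),
      removed = as.list(cleaned$ledger),
      taxa_summarized = nrow(summaries),
      predicted_tolerant = sum(predictions$tolerant),
      contingency_total = sum(contingency$counts),
      mixed_excluded = contingency$n_mixed_excluded),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s", manifest$elapsed_sec)
  invisible(list(manifest = manifest, landscape = landscape, taxa = taxa,
                 specimens = specimens, gazetteer = gz$gazetteer,
                 accuracy = acc, link = link, cleaned = cleaned,
                 summaries = summaries, predictions = predictions,
                 contingency = contingency, test = test,
                 density = density))
}
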