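#' Configuration for the synthetic soil landscape generator
#'
#' The generator emulates the structure of a harmonized mapping-unit soil
#' raster over a region where occurrence data will be simulated: a grid of
#' about-1-km cells, each pointing at one of a limited set of mapping units,
#' each mapping unit carrying exactly one soil attribute record. Topsoil pH
#' is drawn from a four-component Gaussian mixture whose default modes
#' (4.8, 5.7, 6.5, 8.0) and weights reproduce the multimodal pH landscape of
#' the real database over mainland China; CaCO3 is coupled to pH by a
#' piecewise rule (calcite-free below pH 6.5; 2-5 or 5-15 percent weight
#' above), so that calcareous soils are the alkaline ones.
#'
#' @param n_rows,n_cols grid dimensions (cells).
#' @param origin_lon,origin_lat top-left corner, decimal degrees WGS84.
#' @param resolution cell size in decimal degrees (default 0.0083, about
#'   1 km x 1 km).
#' @param n_units number of mapping units; defaults to
#'   `min(936, n_rows * n_cols)` (936 mapping units cover mainland China in
#'   the real database).
#' @param ph_modes data frame with columns `center`, `weight`, `sd`:
#'   the pH mixture. Weights must sum to 1.
#' @param caco3_given_ph function mapping a vector of pH values to CaCO3
#'   percent weight (may use the RNG); `NULL` selects the default piecewise
#'   rule.
#' @param frac_excluded_surface fraction of mapping units labelled as
#'   non-soil surface (`WR`/`RK`/`GG`/`UR`: inland water, rock debris,
#'   glaciers and permanent snow, urban area).
#' @param frac_missing_subsoil fraction of mapping units lacking subsoil
#'   attributes.
#' @param seed integer RNG seed.
#' @return a list of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 120L, n_cols = 120L,
                             origin_lon = 97, origin_lat = 34,
                             resolution = 0.0083,
                             n_units = NULL,
                             ph_modes = default_ph_modes(),
                             caco3_given_ph = NULL,
                             frac_excluded_surface = 0.013,
                             frac_missing_subsoil = 0.103,
                             seed = 1L) {
  if (n_rows <= 0 || n_cols <= 0)
    stop("grid dimensions must be positive", call. = FALSE)
  assert_scalar_number(resolution, "resolution", positive = TRUE)
  if (frac_excluded_surface < 0 || frac_excluded_surface > 1 ||
      frac_missing_subsoil < 0 || frac_missing_subsoil > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(ph_modes$weight) - 1) > 1e-8)
    stop("pH mixture weights must sum to 1", call. = FALSE)
  n_units <- as.integer(n_units %||% min(936L, n_rows * n_cols))
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    origin_lon = origin_lon, origin_lat = origin_lat,
    resolution = resolution, n_units = n_units,
    ph_modes = ph_modes,
    caco3_given_ph = caco3_given_ph %||% default_caco3_rule,
    frac_excluded_surface = frac_excluded_surface,
    frac_missing_subsoil = frac_missing_subsoil,
    seed = as.integer(seed)), class = "landscape_config")
}

#' @rdname landscape_config
#' @export
default_ph_modes <- function() {
  # mode weights proportional to the observed hump heights at 4.8, 5.7,
  # 6.5 and 8 (6.7%, 7.9%, 12.5%, 11%)
  w <- c(6.7, 7.9, 12.5, 11)
  # narrow components: the emulated database's attribute values are strongly
  # discretized, with a handful of values dominating each hump
  data.frame(center = c(4.8, 5.7, 6.5, 8.0), weight = w / sum(w),
             sd = c(0.1, 0.1, 0.1, 0.1))
}

#' @rdname landscape_config
#' @export
default_caco3_rule <- function(ph) {
  out <- numeric(length(ph))
  hi <- !is.na(ph) & ph >= 6.5
  n_hi <- sum(hi)
  if (n_hi) {
    # calcareous units: 40% in the 2-5 class, 60% in the 5-15 class
    in_low <- stats::runif(n_hi) < 0.4
    v <- ifelse(in_low, stats::runif(n_hi, 2, 5), stats::runif(n_hi, 5, 15))
    out[hi] <- round(v, 1)
  }
  out[is.na(ph)] <- NA_real_
  out
}

# Tile an n_rows x n_cols grid with one contiguous patch per mapping unit:
# each cell takes the id of the nearest of n random seed points (uses the
# current RNG stream).
voronoi_grid <- function(n_rows, n_cols, mu_id) {
  n <- length(mu_id)
  seed_r <- stats::runif(n, 0, n_rows)
  seed_c <- stats::runif(n, 0, n_cols)
  grid <- matrix(NA_integer_, n_rows, n_cols)
  col_centres <- seq_len(n_cols) - 0.5
  dc2 <- outer(seed_c, col_centres, function(s, x) (s - x)^2)  # n x n_cols
  for (r in seq_len(n_rows)) {
    d2 <- dc2 + (seed_r - (r - 0.5))^2
    grid[r, ] <- mu_id[max.col(-t(d2), ties.method = "first")]
  }
  grid
}

# ordinary FAO90 soil-unit symbols used for non-excluded units
NORMAL_SURFACE_CODES <- c("I", "ACu", "ALh", "CMd", "CMe", "LVh", "PDd",
                          "RGd", "ANh", "LPd")

#' Generate a synthetic soil landscape
#'
#' Draws one soil attribute record per mapping unit (topsoil pH from the
#' configured mixture rounded to 0.1 pH unit, CaCO3 from the coupling rule,
#' subsoil as a small perturbation of topsoil) and tiles the grid with
#' spatially contiguous mapping-unit patches (a Voronoi tessellation of
#' random unit seeds), mirroring the polygonal soil maps the real database
#' rasterizes. Patch areas are exchangeable across units, so the cell-level
#' pH histogram reproduces the configured mixture in expectation.
#'
#' @param config a [landscape_config()].
#' @return a [soil_landscape()].
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(derive_seed(config$seed, 1L))
  n_units <- config$n_units
  mu_id <- 11000L + seq_len(n_units) - 1L

  comp <- sample.int(nrow(config$ph_modes), n_units, replace = TRUE,
                     prob = config$ph_modes$weight)
  t_ph <- stats::rnorm(n_units, config$ph_modes$center[comp],
                       config$ph_modes$sd[comp])
  t_ph <- round(pmin(pmax(t_ph, 3.5), 9.5), 1)
  t_caco3 <- config$caco3_given_ph(t_ph)

  s_ph <- round(pmin(pmax(t_ph + stats::rnorm(n_units, 0, 0.2), 3.5), 9.5), 1)
  s_caco3 <- config$caco3_given_ph(s_ph)

  excluded <- stats::runif(n_units) < config$frac_excluded_surface
  su_sym90 <- ifelse(
    excluded,
    sample(EXCLUDED_SURFACE_CODES, n_units, replace = TRUE),
    sample(NORMAL_SURFACE_CODES, n_units, replace = TRUE))

  no_subsoil <- stats::runif(n_units) < config$frac_missing_subsoil
  s_ph[no_subsoil] <- NA_real_
  s_caco3[no_subsoil] <- NA_real_

  attributes <- data.frame(
    mu_id = mu_id, su_sym90 = su_sym90,
    t_ph_h2o = t_ph, s_ph_h2o = s_ph,
    t_caco3 = t_caco3, s_caco3 = s_caco3,
    stringsAsFactors = FALSE)

  grid <- voronoi_grid(config$n_rows, config$n_cols, mu_id)
  soil_landscape(grid, attributes, config$origin_lon, config$origin_lat,
                 config$resolution)
}

#' Generate taxa with known soil niches
#'
#' Each taxon gets a Gaussian realized niche on topsoil pH and a
#' ground-truth lime-tolerance label. Tolerant taxa centre near pH 8
#' (calcareous soils); non-tolerant taxa centre near pH 5. The labels are
#' what the downstream quartile-threshold prediction is asked to recover.
#'
#' @param n_taxa number of taxa (> 0).
#' @param tolerant_fraction fraction flagged tolerant; `round(n_taxa *
#'   tolerant_fraction)` taxa get the label.
#' @param seed integer RNG seed.
#' @param ph_mean_tolerant,ph_mean_intolerant niche centres (pH units).
#' @param ph_jitter half-width of the uniform jitter applied to each niche
#'   centre.
#' @param ph_sd within-taxon niche breadth (pH units).
#' @param n_specimens specimen records per taxon.
#' @return data frame with columns `taxon_name`, `rank`, `subgenus`,
#'   `ground_truth_tolerant`, `ph_mean`, `ph_sd`, `n_specimens`.
#' @export
generate_taxa <- function(n_taxa, tolerant_fraction, seed = 1L,
                          ph_mean_tolerant = 8.0, ph_mean_intolerant = 5.0,
                          ph_jitter = 0.2, ph_sd = 0.5, n_specimens = 50L) {
  if (n_taxa <= 0) stop("n_taxa must be > 0", call. = FALSE)
  if (tolerant_fraction < 0 || tolerant_fraction > 1)
    stop("tolerant_fraction must lie in [0, 1]", call. = FALSE)
  set.seed(derive_seed(seed, 2L))
  n_tol <- round(n_taxa * tolerant_fraction)
  tolerant <- rep(c(TRUE, FALSE), c(n_tol, n_taxa - n_tol))
  centre <- ifelse(tolerant, ph_mean_tolerant, ph_mean_intolerant)
  ph_mean <- centre + stats::runif(n_taxa, -ph_jitter, ph_jitter)
  rank <- rep(c("species", "variety", "subspecies"),
              length.out = n_taxa)[order(stats::runif(n_taxa))]
  data.frame(
    taxon_name = sprintf("Taxon %03d", seq_len(n_taxa)),
    rank = rank,
    subgenus = sprintf("Subgenus %d", (seq_len(n_taxa) - 1L) %% 9L + 1L),
    ground_truth_tolerant = tolerant,
    ph_mean = ph_mean, ph_sd = ph_sd,
    n_specimens = as.integer(n_specimens),
    stringsAsFactors = FALSE)
}

#' Generate specimen records over a landscape
#'
#' Each specimen of a taxon is assigned to a grid cell with probability
#' proportional to a Gaussian kernel of that cell's topsoil pH around the
#' taxon's niche centre (cell-level environment, mirroring the cell-level
#' soil lookup of the analysis), then placed uniformly within the cell.
#'
#' @param taxa data frame from [generate_taxa()].
#' @param landscape a [soil_landscape()].
#' @param seed integer RNG seed.
#' @return data frame with columns `specimen_id`, `latin_name`, `rank`,
#'   `subgenus`, `location_text` (`NA` until a gazetteer is generated),
#'   `true_lat`, `true_lon`.
#' @export
generate_specimens <- function(taxa, landscape, seed = 1L) {
  stopifnot(inherits(landscape, "soil_landscape"))
  set.seed(derive_seed(seed, 3L))
  attrs <- cell_attributes(landscape)
  cell_ph <- attrs$t_ph_h2o
  usable <- which(!is.na(cell_ph))
  if (!length(usable))
    stop("landscape has no cell with topsoil pH", call. = FALSE)
  nr <- nrow(landscape$grid)
  res <- landscape$resolution

  out <- vector("list", nrow(taxa))
  for (i in seq_len(nrow(taxa))) {
    n <- taxa$n_specimens[i]
    if (n == 0L) next
    w <- stats::dnorm(cell_ph[usable], taxa$ph_mean[i], taxa$ph_sd[i])
    if (!any(w > 0))
      stop(sprintf("taxon '%s' has zero niche weight over the landscape",
                   taxa$taxon_name[i]), call. = FALSE)
    cells <- usable[sample.int(length(usable), n, replace = TRUE, prob = w)]
    row <- (cells - 1L) %% nr + 1L
    col <- (cells - 1L) %/% nr + 1L
    lon <- landscape$origin_lon + (col - 1L + stats::runif(n)) * res
    lat <- landscape$origin_lat - (row - 1L + stats::runif(n)) * res
    out[[i]] <- data.frame(
      latin_name = taxa$taxon_name[i], rank = taxa$rank[i],
      subgenus = taxa$subgenus[i], location_text = NA_character_,
      true_lat = lat, true_lon = lon, stringsAsFactors = FALSE)
  }
  res_df <- do.call(rbind, out)
  if (is.null(res_df))
    res_df <- data.frame(latin_name = character(), rank = character(),
                         subgenus = character(), location_text = character(),
                         true_lat = numeric(), true_lon = numeric(),
                         stringsAsFactors = FALSE)
  cbind(specimen_id = sprintf("S%06d", seq_len(nrow(res_df))), res_df,
        stringsAsFactors = FALSE)
}

#' Generate a gazetteer and label specimens with location texts
#'
#' Emulates the text-location-to-coordinates step: each specimen receives a
#' location text that matches exactly one gazetteer label, whose coordinates
#' are displaced from the specimen's true position by a half-normal distance
#' with mean `noise_km` in a uniform random bearing. Additional decoy
#' entries (labels no specimen references) can be requested via `n_entries`.
#'
#' @param specimens data frame from [generate_specimens()].
#' @param landscape a [soil_landscape()] (used to place decoy entries).
#' @param n_entries total gazetteer entries; default one per specimen. Must
#'   be at least `nrow(specimens)`.
#' @param noise_km mean geocoding displacement in kilometres (>= 0).
#' @param seed integer RNG seed.
#' @return list with `gazetteer` (data frame `label`, `lat`, `lon`) and
#'   `specimens` (input with `location_text` filled in).
#' @export
generate_gazetteer <- function(specimens, landscape, n_entries = NULL,
                               noise_km = 10, seed = 1L) {
  n_spec <- nrow(specimens)
  n_entries <- as.integer(n_entries %||% max(n_spec, 1L))
  if (n_entries <= 0) stop("n_entries must be >= 1", call. = FALSE)
  if (n_entries < n_spec)
    stop("n_entries must be at least the number of specimens ",
         "(one label per specimen)", call. = FALSE)
  if (noise_km < 0) stop("noise_km must be >= 0", call. = FALSE)
  set.seed(derive_seed(seed, 4L))

  label <- sprintf("loc_%05d", seq_len(n_entries))
  # half-normal displacement with mean noise_km: sigma = noise_km*sqrt(pi/2)
  sigma <- noise_km * sqrt(pi / 2)
  d_km <- abs(stats::rnorm(n_spec, 0, sigma))
  bearing <- stats::runif(n_spec, 0, 2 * pi)
  # local planar displacement on the ellipsoid-ish degree scale
  lat <- specimens$true_lat + d_km * cos(bearing) / 110.574
  lon <- specimens$true_lon +
    d_km * sin(bearing) / (111.320 * cos(specimens$true_lat * pi / 180))

  if (n_entries > n_spec) {
    n_decoy <- n_entries - n_spec
    nr <- nrow(landscape$grid); nc <- ncol(landscape$grid)
    res <- landscape$resolution
    lat <- c(lat, landscape$origin_lat - stats::runif(n_decoy) * nr * res)
    lon <- c(lon, landscape$origin_lon + stats::runif(n_decoy) * nc * res)
  }
  gaz <- data.frame(label = label, lat = lat, lon = lon,
                    stringsAsFactors = FALSE)
  specimens$location_text <- label[seq_len(n_spec)]
  list(gazetteer = gaz, specimens = specimens)
}
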