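# Fixtures and independent oracles, all built in code.

# Small landscape + taxa + specimens world used across module tests.
make_world <- function(seed = 5, n_rows = 60, n_cols = 60, n_taxa = 10,
                       n_specimens = 30, ...) {
  lc <- landscape_config(n_rows = n_rows, n_cols = n_cols, seed = seed, ...)
  landscape <- generate_landscape(lc)
  taxa <- generate_taxa(n_taxa, 0.5, seed = seed, n_specimens = n_specimens)
  specimens <- generate_specimens(taxa, landscape, seed = seed)
  list(config = lc, landscape = landscape, taxa = taxa,
       specimens = specimens)
}

# Linked-specimen table using true coordinates (skips geocoding).
link_true <- function(world) {
  sp <- world$specimens
  sp$lat <- sp$true_lat
  sp$lon <- sp$true_lon
  link_specimens(sp, world$landscape)
}

# Record table with the removal structure of the reference cleaning run:
# 35,574 records of which 382 lack a mapping unit, 458 sit on excluded
# surface classes, 3,588 lack subsoil attributes (disjoint categories).
make_cleaning_fixture <- function(n_total = 35574, n_oor = 382,
                                  n_excl = 458, n_miss = 3588, seed = 42) {
  set.seed(seed)
  n_ok <- n_total - n_oor - n_excl - n_miss
  df <- data.frame(
    specimen_id = sprintf("S%05d", seq_len(n_total)),
    mu_id = 11000L + sample.int(900, n_total, replace = TRUE),
    su_sym90 = sample(c("I", "ACu", "CMd", "LVh"), n_total, replace = TRUE),
    t_ph_h2o = round(runif(n_total, 4, 9), 1),
    s_ph_h2o = round(runif(n_total, 4, 9), 1),
    t_caco3 = round(runif(n_total, 0, 10), 1),
    s_caco3 = round(runif(n_total, 0, 10), 1),
    stringsAsFactors = FALSE)
  idx <- sample.int(n_total)  # scatter the categories through the table
  i_oor <- idx[seq_len(n_oor)]
  i_excl <- idx[n_oor + seq_len(n_excl)]
  i_miss <- idx[n_oor + n_excl + seq_len(n_miss)]
  df$mu_id[i_oor] <- NA
  df$su_sym90[i_excl] <- sample(c("WR", "RK", "GG", "UR"), n_excl,
                                replace = TRUE)
  drop_ph <- rep(c(TRUE, FALSE), length.out = n_miss)
  df$s_ph_h2o[i_miss[drop_ph]] <- NA
  df$s_caco3[i_miss[!drop_ph]] <- NA
  df
}

# Specimen-level table reproducing the reference dataset's taxonomy shape:
# 413 species (subgenus block sizes from the reference table), 78 varieties,
# 34 subspecies, 31,146 records, top-20 specimen counts as printed.
make_taxonomy_fixture <- function() {
  extdata <- function(f) system.file("extdata", f, package = "calciphile")
  top20 <- read.delim(extdata("top20_specimen_counts.tsv"))
  by_sub <- read.delim(extdata("dataset_species_by_subgenus.tsv"))
  n_species <- sum(by_sub$n_dataset)

  species_names <- c(top20$latin_name,
                     sprintf("Species %03d", seq_len(n_species - 20)))
  species_sub <- rep(by_sub$subgenus, by_sub$n_dataset)

  n_var <- 78; n_sub <- 34
  other_names <- c(species_names[-seq_len(20)],
                   sprintf("Variety %02d", seq_len(n_var)),
                   sprintf("Subspecies %02d", seq_len(n_sub)))
  other_ranks <- c(rep("species", n_species - 20),
                   rep("variety", n_var), rep("subspecies", n_sub))
  n_other <- length(other_names)
  remaining <- 31146 - sum(top20$n_specimens)
  counts_other <- rep(remaining %/% n_other, n_other)
  extra <- remaining - sum(counts_other)
  counts_other[seq_len(extra)] <- counts_other[seq_len(extra)] + 1
  stopifnot(all(counts_other < min(top20$n_specimens)))

  all_names <- c(top20$latin_name, other_names)
  all_ranks <- c(rep("species", 20), other_ranks)
  # species keep their subgenus block; infraspecific taxa do not enter the
  # per-subgenus species counts, so their subgenus is arbitrary
  all_sub <- c(species_sub, rep("Rhododendron", n_var + n_sub))
  counts <- c(top20$n_specimens, counts_other)
  data.frame(
    latin_name = rep(all_names, counts),
    rank = rep(all_ranks, counts),
    subgenus = rep(all_sub, counts),
    stringsAsFactors = FALSE)
}

described_species_table <- function() {
  read.delim(system.file("extdata", "described_species_by_subgenus.tsv",
                         package = "calciphile"))
}

# --- independent numeric oracles ------------------------------------------

# linear interpolation between order statistics, p(k) = (k-1)/(n-1)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, 0)
}

# uncorrected 2x2 chi-square closed form N(ad-bc)^2/(r1 r2 c1 c2)
chisq_closed_form <- function(m, correction = FALSE) {
  m <- matrix(as.numeric(m), 2)  # avoid integer overflow in (ad - bc)^2
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c_ + d
  num <- if (correction) max(0, abs(a * d - b * c_) - n / 2)^2
         else (a * d - b * c_)^2
  n * num / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# great-circle distance, spherical earth with WGS84 mean radius
spherical_distance <- function(lat1, lon1, lat2, lon2) {
  r <- 6371008.8
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  h <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(h)))
}

# meridian arc length from the equator to latitude phi_deg, by numeric
# integration of the ellipsoidal meridian curvature radius
meridian_arc <- function(phi_deg, a = 6378137, f = 1 / 298.257223563) {
  e2 <- f * (2 - f)
  a * (1 - e2) * stats::integrate(
    function(phi) (1 - e2 * sin(phi)^2)^(-1.5),
    0, phi_deg * pi / 180, rel.tol = 1e-12)$value
}
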