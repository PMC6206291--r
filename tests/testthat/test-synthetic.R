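test_that("landscape generation is deterministic and internally consistent", {
  cfg <- landscape_config(n_rows = 40, n_cols = 50, seed = 11)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a, b)

  # every mapping unit in the raster has exactly one attribute record
  used <- unique(as.vector(a$grid))
  expect_true(all(used %in% a$attributes$mu_id))
  expect_false(anyDuplicated(a$attributes$mu_id) > 0)
  expect_identical(dim(a), c(40L, 50L))
})

test_that("zero-fraction config yields no excluded surfaces or missing subsoil", {
  cfg <- landscape_config(n_rows = 30, n_cols = 30, seed = 2,
                          frac_excluded_surface = 0,
                          frac_missing_subsoil = 0)
  ls <- generate_landscape(cfg)
  expect_false(any(ls$attributes$su_sym90 %in% c("WR", "RK", "GG", "UR")))
  expect_false(anyNA(ls$attributes$s_ph_h2o))
  expect_false(anyNA(ls$attributes$s_caco3))
})

test_that("excluded-surface and missing-subsoil fractions are realized", {
  cfg <- landscape_config(n_rows = 50, n_cols = 50, n_units = 2000,
                          seed = 7, frac_excluded_surface = 0.05,
                          frac_missing_subsoil = 0.2)
  at <- generate_landscape(cfg)$attributes
  n <- nrow(at)
  p_excl <- mean(at$su_sym90 %in% c("WR", "RK", "GG", "UR"))
  p_miss <- mean(is.na(at$s_ph_h2o))
  # within 4 binomial standard errors
  expect_lt(abs(p_excl - 0.05), 4 * sqrt(0.05 * 0.95 / n))
  expect_lt(abs(p_miss - 0.2), 4 * sqrt(0.2 * 0.8 / n))
})

test_that("cell-level pH histogram peaks at the configured mixture modes", {
  cfg <- landscape_config(n_rows = 320, n_cols = 320, n_units = 5000,
                          seed = 3)
  ls <- generate_landscape(cfg)
  idx <- match(as.vector(ls$grid), ls$attributes$mu_id)
  ph <- ls$attributes$t_ph_h2o[idx]
  tab <- table(ph)
  v <- as.numeric(names(tab))
  for (ctr in cfg$ph_modes$center) {
    near <- v >= ctr - 0.3 & v <= ctr + 0.3
    emp_mode <- v[near][which.max(tab[near])]
    expect_lte(abs(emp_mode - ctr), 0.1)
  }
})

test_that("CaCO3 follows the piecewise coupling rule", {
  ls <- generate_landscape(landscape_config(n_rows = 40, n_cols = 40,
                                            seed = 9))
  at <- ls$attributes
  expect_true(all(at$t_caco3[at$t_ph_h2o < 6.5] == 0))
  hi <- at$t_caco3[at$t_ph_h2o >= 6.5]
  expect_true(all(hi >= 2 & hi <= 15))
})

test_that("config validation rejects bad dimensions, fractions and weights", {
  expect_error(landscape_config(n_rows = 0), "positive")
  expect_error(landscape_config(frac_missing_subsoil = 1.2), "\\[0, 1\\]")
  bad_modes <- data.frame(center = c(5, 8), weight = c(0.6, 0.6),
                          sd = c(0.1, 0.1))
  expect_error(landscape_config(ph_modes = bad_modes), "sum to 1")
})

test_that("taxon generation honours labels, counts and niche separation", {
  expect_equal(sum(generate_taxa(10, 0)$ground_truth_tolerant), 0)
  expect_equal(sum(generate_taxa(10, 0.5)$ground_truth_tolerant), 5)
  expect_error(generate_taxa(0, 0.5), "n_taxa")

  tx <- generate_taxa(40, 0.5, seed = 1)
  gap <- mean(tx$ph_mean[tx$ground_truth_tolerant]) -
         mean(tx$ph_mean[!tx$ground_truth_tolerant])
  expect_gte(gap, 1.7)
  expect_true(all(tx$ph_mean[tx$ground_truth_tolerant] >= 7.2))
  expect_true(all(tx$ph_mean[!tx$ground_truth_tolerant] <= 5.5))
})

test_that("specimen placement tracks narrow niches and is deterministic", {
  world <- make_world(seed = 21, n_taxa = 4, n_specimens = 40)
  again <- generate_specimens(world$taxa, world$landscape, seed = 21)
  expect_identical(world$specimens, again)

  # a near-point niche at pH 8 lands almost entirely on pH ~ 8 cells
  narrow <- data.frame(taxon_name = "narrow", rank = "species",
                       subgenus = "Subgenus 1",
                       ground_truth_tolerant = TRUE,
                       ph_mean = 8.0, ph_sd = 0.01, n_specimens = 200L)
  sp <- generate_specimens(narrow, world$landscape, seed = 3)
  sp$lat <- sp$true_lat; sp$lon <- sp$true_lon
  linked <- link_specimens(sp, world$landscape)$linked
  expect_gte(mean(abs(linked$t_ph_h2o - 8.0) <= 0.2), 0.95)

  none <- narrow; none$n_specimens <- 0L
  expect_equal(nrow(generate_specimens(none, world$landscape)), 0)
})

test_that("gazetteer displacement matches the half-normal noise model", {
  world <- make_world(seed = 13, n_taxa = 10, n_specimens = 50)

  gz0 <- generate_gazetteer(world$specimens, world$landscape,
                            noise_km = 0, seed = 1)
  d0 <- vincenty_distance(gz0$gazetteer$lat[seq_len(nrow(world$specimens))],
                          gz0$gazetteer$lon[seq_len(nrow(world$specimens))],
                          world$specimens$true_lat,
                          world$specimens$true_lon)
  expect_equal(max(d0), 0)

  noise_km <- 30
  gz <- generate_gazetteer(world$specimens, world$landscape,
                           noise_km = noise_km, seed = 8)
  n <- nrow(world$specimens)
  d <- vincenty_distance(gz$gazetteer$lat[seq_len(n)],
                         gz$gazetteer$lon[seq_len(n)],
                         world$specimens$true_lat,
                         world$specimens$true_lon) / 1000
  # half-normal with mean noise_km: sd = noise_km * sqrt(pi/2 - 1)
  se <- noise_km * sqrt(pi / 2 - 1) / sqrt(n)
  expect_lt(abs(mean(d) - noise_km), 3 * se)

  # every specimen text resolves to exactly one label
  expect_true(all(gz$specimens$location_text %in% gz$gazetteer$label))
  expect_false(anyDuplicated(gz$gazetteer$label) > 0)
  expect_error(generate_gazetteer(world$specimens, world$landscape,
                                  n_entries = 3), "at least")
})

test_that("decoy gazetteer entries are never referenced by specimens", {
  world <- make_world(seed = 4, n_taxa = 3, n_specimens = 10)
  gz <- generate_gazetteer(world$specimens, world$landscape,
                           n_entries = 50, noise_km = 1, seed = 2)
  expect_equal(nrow(gz$gazetteer), 50)
  referenced <- unique(gz$specimens$location_text)
  expect_equal(length(setdiff(gz$gazetteer$label, referenced)),
               50 - nrow(world$specimens))
})
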