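fake_linked <- function(name, ph, caco3 = rep(0, length(ph)),
                        rank = "species", subgenus = "S1") {
  data.frame(latin_name = name, rank = rank, subgenus = subgenus,
             t_ph_h2o = ph, t_caco3 = caco3, stringsAsFactors = FALSE)
}

test_that("taxon quartiles follow the interpolation rule and the min-n cutoff", {
  lk <- rbind(fake_linked("nine", 1:9), fake_linked("twelve", rep(7.8, 12)))
  out <- taxon_quartiles(lk, min_n = 10)
  expect_equal(out$latin_name, "twelve")     # 9 specimens -> omitted
  expect_equal(out$ph_lq, 7.8)
  expect_equal(out$ph_median, 7.8)
  expect_equal(out$ph_uq, 7.8)

  out9 <- taxon_quartiles(lk, min_n = 5)
  nine <- out9[out9$latin_name == "nine", ]
  expect_equal(c(nine$ph_lq, nine$ph_median, nine$ph_uq), c(3, 5, 7))
  expect_true(all(out9$ph_lq <= out9$ph_median &
                  out9$ph_median <= out9$ph_uq))
})

test_that("quartiles match a brute-force order-statistic oracle", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    x <- round(runif(n, 3, 9), sample(c(1, 2), 1))
    lk <- fake_linked("t", x, caco3 = round(runif(n, 0, 12), 1))
    got <- taxon_quartiles(lk, min_n = 1)
    expect_equal(c(got$ph_lq, got$ph_median, got$ph_uq),
                 quantile_oracle(x, c(0.25, 0.5, 0.75)))
    expect_equal(c(got$caco3_lq, got$caco3_median, got$caco3_uq),
                 quantile_oracle(lk$t_caco3, c(0.25, 0.5, 0.75)))
  }
})

test_that("per-class specimen percentages in the summary are exact", {
  lk <- fake_linked("t", c(5.0, 6.0, 6.5, 8.0), c(0, 0, 3, 7))
  out <- taxon_quartiles(lk, min_n = 1)
  expect_equal(out$`pct_ph_4.5-5.5`, 25)
  expect_equal(out$`pct_ph_5.5-7.2`, 50)
  expect_equal(out$`pct_ph_7.2-8.5`, 25)
  expect_equal(out$`pct_caco3_<2`, 50)
  expect_equal(out$`pct_caco3_2-5`, 25)
  expect_equal(out$`pct_caco3_5-15`, 25)
})

test_that("tolerance prediction uses strict inequalities on both UQs", {
  s <- data.frame(latin_name = c("a", "b", "c"), rank = "species",
                  subgenus = "S1", n = 12,
                  ph_uq = c(8.0, 7.2, 8.0), caco3_uq = c(7, 5, 2.0))
  p <- predict_tolerance(s)
  expect_equal(p$tolerant, c(TRUE, FALSE, FALSE))
})

test_that("raising a specimen's pH never flips its taxon to non-tolerant", {
  set.seed(73)
  for (i in 1:30) {
    ph <- round(runif(12, 5, 9), 1)
    lk <- fake_linked("t", ph, caco3 = round(runif(12, 0, 8), 1))
    before <- predict_tolerance(taxon_quartiles(lk))$tolerant
    j <- sample(12, 1)
    lk$t_ph_h2o[j] <- lk$t_ph_h2o[j] + runif(1, 0, 3)
    after <- predict_tolerance(taxon_quartiles(lk))$tolerant
    expect_true(after >= before)
  }
})

test_that("lime classification partitions specimens into lime/non-lime/mixed", {
  lk <- fake_linked("t", c(7.5, 7.5, 6.0, 8.0), c(5, 1, 0, 1))
  preds <- data.frame(latin_name = "t", tolerant = TRUE)
  ct <- lime_contingency(lk, preds)
  # 7.5/5 lime; 6.0/0 non-lime; 7.5/1 and 8.0/1 mixed
  expect_equal(ct$counts["tolerant", "lime"], 1L)
  expect_equal(ct$counts["tolerant", "non_lime"], 1L)
  expect_equal(ct$n_mixed_excluded, 2L)
  expect_equal(sum(ct$counts) + ct$n_mixed_excluded, nrow(lk))
})

test_that("contingency cells equal a brute-force filter-and-count", {
  world <- make_world(seed = 43, n_taxa = 12, n_specimens = 40)
  cleaned <- clean_dataset(link_true(world))$retained
  preds <- predict_tolerance(taxon_quartiles(cleaned))
  ct <- lime_contingency(cleaned, preds)

  tol_taxa <- preds$latin_name[preds$tolerant]
  is_tol <- cleaned$latin_name %in% tol_taxa
  lime <- cleaned$t_ph_h2o > 7.2 & cleaned$t_caco3 > 2
  nonlime <- cleaned$t_ph_h2o <= 7.2 & cleaned$t_caco3 <= 2
  expect_equal(ct$counts["tolerant", "lime"], sum(is_tol & lime))
  expect_equal(ct$counts["non_tolerant", "non_lime"], sum(!is_tol & nonlime))
  expect_equal(ct$n_mixed_excluded, sum(!lime & !nonlime))
  expect_equal(sum(ct$counts) + ct$n_mixed_excluded, nrow(cleaned))

  # specimens of below-cutoff taxa can be excluded instead
  small <- cleaned[seq_len(200), ]
  preds2 <- predict_tolerance(taxon_quartiles(small, min_n = 30))
  both <- lime_contingency(small, preds2, below_min_n = "exclude")
  expect_equal(sum(both$counts) + both$n_mixed_excluded +
                 both$n_below_min_n_excluded, nrow(small))
})

test_that("chi-square statistic matches closed forms and the stats oracle", {
  expect_equal(chi_square_2x2(matrix(c(10, 20, 30, 60), 2, byrow = TRUE),
                              correction = FALSE)$statistic, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 20, 20, 10), 2),
                              correction = TRUE)$statistic, 5.4)

  set.seed(83)
  for (i in 1:200) {
    m <- matrix(rpois(4, sample(c(5, 50, 500), 1)) + 1L, 2)
    un <- chi_square_2x2(m, correction = FALSE)
    expect_equal(un$statistic, chisq_closed_form(m),
                 tolerance = 1e-9)
    co <- chi_square_2x2(m, correction = TRUE)
    expect_equal(co$statistic,
                 unname(suppressWarnings(
                   chisq.test(m, correct = TRUE))$statistic),
                 tolerance = 1e-9)
    expect_equal(co$p_value, pchisq(co$statistic, 1, lower.tail = FALSE))
    expect_equal(co$df, 1L)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("taxonomy summary reproduces reference coverage arithmetic", {
  sp <- make_taxonomy_fixture()
  ref <- described_species_table()
  names(ref) <- c("subgenus", "n_described")
  ts <- taxonomy_summary(sp, ref, described_varieties = 180,
                         described_subspecies = 72, top_n = 20)
  expect_equal(ts$n_taxa_total, 525)
  expect_equal(sum(ts$by_subgenus$n_dataset), 413)
  cov <- setNames(ts$by_rank$coverage_pct, ts$by_rank$rank)
  expect_equal(unname(cov[c("species", "variety", "subspecies")]),
               c(72.3, 43.3, 47.2))
  expect_equal(ts$top_share_pct, 36.8)
  expect_equal(ts$top_taxa$n_specimens[1], 1435)

  empty <- taxonomy_summary(sp[0, ], ref, 180, 72)
  expect_equal(empty$n_taxa_total, 0)
  expect_equal(sum(empty$by_rank$n_dataset), 0)

  bad <- sp[1, ]; bad$subgenus <- "Nonexistus"
  expect_error(taxonomy_summary(bad, ref, 180, 72), "absent")
})
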