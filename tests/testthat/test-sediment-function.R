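test_that("pellet chemistry computes AFDW and organic-matter content", {
  chem <- pellet_chemistry(c(1.0, 1.0, 2.50), c(1.0, 0.9, 2.35), c(10, 10, 10))
  expect_equal(chem$afdw_g, c(0, 0.1, 0.15))
  expect_equal(chem$organic_matter_pct[1], 0)
  expect_equal(chem$organic_matter_pct[2], 10)
  expect_equal(chem$organic_matter_pct[3], 6.0)
  expect_error(pellet_chemistry(1.0, 1.1, 10), "furnace")
  # no pellets collected: missing chemistry, not an error
  none <- pellet_chemistry(0, 0, 0)
  expect_true(is.na(none$organic_matter_pct))
})

test_that("organic-matter content is invariant to splitting at the same DW:AW ratio", {
  chem <- pellet_chemistry(c(2.5, 1.25, 0.5), c(2.35, 1.175, 0.47), c(10, 5, 2))
  expect_equal(chem$organic_matter_pct, rep(6.0, 3))
})

test_that("egestion rate is the mean of hourly counts", {
  expect_equal(egestion_rate(c(0, 0, 0)), 0)
  expect_equal(egestion_rate(c(2, 3, 4)), 3.0)
  expect_equal(egestion_rate(5), 5.0) # single-hour window tolerated
  expect_equal(egestion_rate(c(2, NA, 4)), 3.0)
  expect_error(egestion_rate(numeric(0)), "at least one")
  expect_error(egestion_rate(c(NA_real_, NA_real_)), "at least one")
})

test_that("per-pellet weight divides the pooled dry weight", {
  expect_equal(per_pellet_weight(1.0, 10), 0.1)
  expect_equal(per_pellet_weight(0.35, 1), 0.35)
  expect_true(is.na(per_pellet_weight(0, 0)))
})

test_that("processing rates combine egestion, pellet weight and activity budget", {
  obs <- dplyr::bind_rows(
    make_pellets("HMEX", counts = c(2, 2, 2), n_pellets = 2, dw = 1.0, aw = 0.9, id = "H1"),
    make_pellets("AAGA", counts = c(2, 2, 2), n_pellets = 2, dw = 1.0, aw = 0.9, id = "A1")
  )
  r <- processing_rates(obs)
  expect_equal(r$hourly_rate_g_h, c(1.0, 1.0))
  expect_equal(r$annual_rate_kg_yr[r$species == "HMEX"], 1.0 * 12 * 365 / 1000) # 4.38
  expect_equal(r$annual_rate_kg_yr[r$species == "AAGA"], 1.0 * 10 * 365 / 1000) # 3.65
  expect_equal(r$speed_m_h, c(0.2, 0.2))
  zero <- processing_rates(make_pellets("AAGA", counts = c(0, 0, 0)))
  expect_equal(zero$hourly_rate_g_h, 0)
  expect_equal(zero$annual_rate_kg_yr, 0)
})

test_that("an individual with no pellets falls back to the species-mean weight", {
  obs <- dplyr::bind_rows(
    make_pellets("HMEX", n_pellets = 10, dw = 4, id = "H1"),
    make_pellets("HMEX", n_pellets = 10, dw = 6, id = "H2"),
    make_pellets("HMEX", n_pellets = 0, dw = 0, aw = 0, id = "H3")
  )
  r <- processing_rates(obs)
  expect_equal(r$pellet_weight_g[3], 0.5) # mean of 0.4 and 0.6
  forced <- processing_rates(obs, pellet_weight_rule = "species_mean")
  expect_equal(forced$pellet_weight_g, rep(0.5, 3))
})

test_that("processing rate is homogeneous of degree 1 in pellet weight", {
  set.seed(11)
  obs <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_pellets(sample(c("HMEX", "AAGA"), 1), counts = rpois(3, 5),
                 n_pellets = 10, dw = runif(1, 0.5, 3), aw = 0.1, id = paste0("X", i))
  }))
  r1 <- processing_rates(obs)
  obs2 <- obs
  obs2$dw_g <- 2 * obs$dw_g
  obs2$aw_g <- 2 * obs$aw_g
  r2 <- processing_rates(obs2)
  expect_equal(r2$hourly_rate_g_h, 2 * r1$hourly_rate_g_h)
  expect_equal(r2$annual_rate_kg_yr, 2 * r1$annual_rate_kg_yr)
})

test_that("species summary Welch tests match the textbook formula", {
  set.seed(21)
  rates <- tibble::tibble(
    individual_id = paste0("i", 1:40),
    species = rep(c("HMEX", "AAGA"), each = 20),
    egestion_rate_h = c(rnorm(20, 3, 1), rnorm(20, 12, 2)),
    pellet_weight_g = c(rnorm(20, 1, 0.2), rnorm(20, 0.085, 0.02)),
    hourly_rate_g_h = c(rnorm(20, 3, 0.8), rnorm(20, 1, 0.3)),
    organic_matter_pct = c(rnorm(20, 3, 0.8), rnorm(20, 4.5, 0.8)),
    speed_m_h = c(rnorm(20, 0.2, 0.05), rnorm(20, 0.1, 0.05))
  )
  rates$annual_rate_kg_yr <- rates$hourly_rate_g_h * activity_hours(rates$species) * 0.365
  s <- species_rate_summary(rates)
  for (m in s$tests$metric) {
    o <- welch_oracle(rates[[m]][rates$species == "HMEX"],
                      rates[[m]][rates$species == "AAGA"])
    row <- s$tests[s$tests$metric == m, ]
    expect_equal(row$t, o$t, tolerance = 1e-10)
    expect_equal(row$df, o$df, tolerance = 1e-10)
    expect_equal(row$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("degenerate species summaries are handled, not crashed", {
  same <- tibble::tibble(
    species = rep(c("HMEX", "AAGA"), each = 3),
    egestion_rate_h = rep(c(1, 2, 3), 2),
    pellet_weight_g = rep(c(1, 2, 3), 2),
    hourly_rate_g_h = rep(c(1, 2, 3), 2),
    organic_matter_pct = rep(c(1, 2, 3), 2),
    speed_m_h = rep(c(1, 2, 3), 2)
  )
  s <- species_rate_summary(same)
  expect_equal(s$tests$t, rep(0, 5))
  expect_equal(s$tests$p_value, rep(1, 5))
  sep <- same
  sep$hourly_rate_g_h <- rep(c(2, 1), each = 3) # zero variance, unequal means
  expect_warning(s2 <- species_rate_summary(sep), "zero variance")
  expect_equal(s2$tests$p_value[s2$tests$metric == "hourly_rate_g_h"], 0)
  solo <- same[same$species == "HMEX", ]
  expect_warning(s3 <- species_rate_summary(solo), "absent")
  expect_null(s3$tests)
})

test_that("a planted 3x hourly-rate ratio is recovered from generated animals", {
  # generator-calibration property: with HMEX hourly rates ~3x AAGA at
  # n = 20 per species, the summary recovers the ratio within 10%
  hits <- vapply(1:20, function(i) {
    cfg <- synthetic_config(seed = 1000 + i, n_reefs = 2)
    study <- generate_study(cfg)
    s <- species_rate_summary(processing_rates(study$pellets))
    s$hourly_ratio_hmex_aaga
  }, numeric(1))
  expect_lt(abs(mean(hits) - 3) / 3, 0.10)
  expect_gt(min(hits), 1.5) # every replicate preserves the ranking by a margin
})
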