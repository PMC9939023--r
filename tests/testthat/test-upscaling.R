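test_that("degenerate sediment bootstraps are exact", {
  cfg <- bootstrap_config(n_boot = 200, seed = 3)
  zero <- bootstrap_sediment(0, 10, c(1, 2), "HMEX", cfg)
  expect_equal(zero$point_estimate, 0)
  expect_equal(zero$bootstrap_se, 0)
  one <- bootstrap_sediment(1, 1, 1.0, "HMEX", cfg)
  expect_equal(one$point_estimate, 12 * 365 / 1000) # 4.38 kg m-2 yr-1
  expect_equal(one$bootstrap_se, 0)                 # resampling a constant
  expect_error(bootstrap_sediment(2, 1, numeric(0), "AAGA", cfg), "pool")
})

test_that("Monte-Carlo sediment SE matches the enumerated resample SD", {
  cfg <- bootstrap_config(n_boot = 5000, seed = 17)
  k <- 10 * 365 / 1000 # AAGA annual factor, area 1
  est <- bootstrap_sediment(2, 1, c(1, 3), "AAGA", cfg)
  exact <- enumerated_boot_sd(c(1, 3), 2, function(s) s * k)
  expect_equal(exact, sqrt(2) * k, tolerance = 1e-12)  # ~5.163, by hand
  expect_lt(abs(est$bootstrap_se - exact) / exact, 0.05)
  # another small pool, n = 3
  est3 <- bootstrap_sediment(3, 2, c(0.5, 1.2, 2.0), "HMEX", cfg)
  exact3 <- enumerated_boot_sd(c(0.5, 1.2, 2.0), 3,
                               function(s) s * 12 * 365 / 1000 / 2)
  expect_lt(abs(est3$bootstrap_se - exact3) / exact3, 0.05)
})

test_that("bootstrap mean converges to the plug-in estimate", {
  cfg <- bootstrap_config(n_boot = 5000, seed = 9)
  pool <- c(0.4, 1.1, 2.3, 0.9, 1.7)
  plug <- bootstrap_sediment(4, 3, pool, "AAGA", cfg)
  boot <- bootstrap_sediment(4, 3, pool, "AAGA",
                             bootstrap_config(5000, 9, "boot_mean"))
  mc_se <- plug$bootstrap_se / sqrt(cfg$n_boot)
  expect_lt(abs(boot$point_estimate - plug$point_estimate), 3 * mc_se)
})

test_that("ammonium bootstrap honours its degenerate limits", {
  allo <- fit_allometry(c(15, 20, 25, 30), 320 + 17.6 * c(15, 20, 25, 30))
  rates <- tibble::tibble(
    species = rep(c("AAGA", "HMEX"), each = 4),
    rate_umol_h = c(11, 12, 12, 13, 15, 15.5, 16, 16.5),
    wet_weight_g = c(600, 700, 800, 900, 550, 700, 860, 980)
  )
  m <- fit_excretion_model(rates)
  cfg <- bootstrap_config(n_boot = 500, seed = 4)
  none <- bootstrap_ammonium(numeric(0), 5, allo, m, "HMEX", cfg)
  expect_equal(none$point_estimate, 0)
  expect_equal(none$bootstrap_se, 0)
  same <- bootstrap_ammonium(rep(24, 6), 5, allo, m, "HMEX", cfg)
  expect_equal(same$bootstrap_se, 0) # identical lengths resample to themselves
  flat <- m
  flat$beta1 <- 0; flat$beta3 <- 0
  est <- bootstrap_ammonium(c(18, 22, 30), 4, allo, flat, "AAGA", cfg)
  expect_equal(est$point_estimate, 3 * flat$beta0 / 4) # length-independent limit
  expect_error(bootstrap_ammonium(c(20, 25), 4, allo, list(), "AAGA", cfg),
               "fitted")
})

make_upscale_inputs <- function(seed = 42) {
  study <- generate_study(synthetic_config(seed = seed, n_reefs = 8))
  geometry <- compute_geometry(study$surveys)
  rates <- run_rates_in_memory(study)
  list(study = study, geometry = geometry, pools = rates$pools,
       allometry = rates$allometry, model = rates$model)
}

run_rates_in_memory <- function(study) {
  processing <- processing_rates(study$pellets)
  excretion <- excretion_rates(study$incubations)
  animals <- study$incubations[study$incubations$is_control == 0, ]
  allometry <- fit_allometry(animals$length_cm, animals$wet_weight_g)
  model <- fit_excretion_model(excretion)
  list(pools = split(processing$hourly_rate_g_h, processing$species),
       allometry = allometry, model = model)
}

test_that("all-reef upscaling is complete, deterministic and order-invariant", {
  inp <- make_upscale_inputs()
  cfg <- bootstrap_config(n_boot = 200, seed = 13)
  est1 <- upscale_all_reefs(inp$geometry, inp$study$individuals, inp$pools,
                            inp$allometry, inp$model, cfg)
  expect_equal(nrow(est1), 4 * nrow(inp$geometry)) # 2 species x 2 functions
  est2 <- upscale_all_reefs(inp$geometry, inp$study$individuals, inp$pools,
                            inp$allometry, inp$model, cfg)
  expect_identical(est1, est2) # bit-identical rerun
  perm <- sample(nrow(inp$geometry))
  est3 <- upscale_all_reefs(inp$geometry[perm, ], inp$study$individuals,
                            inp$pools, inp$allometry, inp$model, cfg)
  est3 <- est3[order(match(est3$reef_id, est1$reef_id),
                     match(est3$species, species_codes()), est3$fun), ]
  est1s <- est1[order(match(est1$reef_id, est1$reef_id),
                      match(est1$species, species_codes()), est1$fun), ]
  expect_equal(as.data.frame(est3), as.data.frame(est1s))
})

test_that("per-area estimates scale inversely with seagrass area", {
  inp <- make_upscale_inputs(seed = 7)
  cfg <- bootstrap_config(n_boot = 150, seed = 2)
  est1 <- upscale_all_reefs(inp$geometry, inp$study$individuals, inp$pools,
                            inp$allometry, inp$model, cfg)
  doubled <- inp$geometry
  doubled$seagrass_area_m2 <- 2 * doubled$seagrass_area_m2
  est2 <- upscale_all_reefs(doubled, inp$study$individuals, inp$pools,
                            inp$allometry, inp$model, cfg)
  expect_equal(est2$point_estimate, est1$point_estimate / 2)
  expect_equal(est2$bootstrap_se, est1$bootstrap_se / 2)
})

test_that("zero-count species yield exact zero rows, missing geometry errors", {
  inp <- make_upscale_inputs(seed = 3)
  cfg <- bootstrap_config(n_boot = 50, seed = 1)
  est <- upscale_all_reefs(inp$geometry, inp$study$individuals, inp$pools,
                           inp$allometry, inp$model, cfg)
  zero_rows <- est[est$n_individuals == 0, ]
  expect_true(nrow(zero_rows) > 0) # default config leaves HMEX off some reefs
  expect_true(all(zero_rows$point_estimate == 0 & zero_rows$bootstrap_se == 0))
  orphan_ind <- inp$study$individuals
  orphan_ind$reef_id[1] <- "GHOST"
  expect_error(upscale_all_reefs(inp$geometry, orphan_ind, inp$pools,
                                 inp$allometry, inp$model, cfg), "GHOST")
})
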