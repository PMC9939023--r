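test_that("length KS test matches a brute-force ECDF oracle", {
  set.seed(31)
  ind <- tibble::tibble(
    species = rep(c("HMEX", "AAGA"), c(30, 45)),
    length_cm = c(rnorm(30, 26.5, 4.9), rnorm(45, 21.9, 4.3))
  )
  ks <- length_distribution_test(ind)
  expect_equal(ks$statistic,
               ks_oracle(ind$length_cm[ind$species == "HMEX"],
                         ind$length_cm[ind$species == "AAGA"]),
               tolerance = 1e-12)
  same <- tibble::tibble(species = rep(c("HMEX", "AAGA"), each = 10),
                         length_cm = rep(11:20, 2))
  s <- length_distribution_test(same)
  expect_equal(s$statistic, 0)
  expect_equal(s$p_value, 1)
  apart <- tibble::tibble(species = rep(c("HMEX", "AAGA"), each = 5),
                          length_cm = c(30:34, 10:14))
  expect_equal(length_distribution_test(apart)$statistic, 1)
  expect_error(length_distribution_test(same[same$species == "AAGA", ]), ">= 2")
})

test_that("density Welch tests match the formula oracle and validate input", {
  g <- tibble::tibble(reef_id = sprintf("R%d", 1:6),
                      seagrass_area_m2 = c(20, 40, 55, 31, 70, 12))
  set.seed(12)
  ind <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(reef_id = sprintf("R%d", i),
                   species = c(rep("AAGA", 3 + i), rep("HMEX", i)))
  }))
  d <- compute_densities(g, ind)
  res <- density_tests(d)
  h <- d$density_m2[d$species == "HMEX"][order(d$reef_id[d$species == "HMEX"])]
  a <- d$density_m2[d$species == "AAGA"][order(d$reef_id[d$species == "AAGA"])]
  o <- welch_oracle(h, a)
  expect_equal(res$t[res$metric == "density"], o$t, tolerance = 1e-10)
  expect_equal(res$p_value[res$metric == "density"], o$p, tolerance = 1e-10)
  # proportions row: per-reef proportions of the two species sum to 1
  expect_equal(res$mean_hmex[res$metric == "proportion"] +
                 res$mean_aaga[res$metric == "proportion"], 1)
  equal_d <- d
  equal_d$density_m2 <- rep(0.5, nrow(d))
  res_eq <- density_tests(equal_d)
  expect_equal(res_eq$t, c(0, 0))
  expect_equal(res_eq$p_value, c(1, 1))
})

test_that("reef-wise dominance counts and proportions behave", {
  est <- estimates_table(aaga = c(3, 5, 1), hmex = c(2, 4, 6))
  s <- reefwise_summary(est, "AMMONIUM_UMOL_M2_H")
  dom <- s$dominance[s$dominance$scope == "all", ]
  expect_equal(dom$count[dom$outcome == "AAGA_more"], 2)
  expect_equal(dom$proportion[dom$outcome == "AAGA_more"], 2 / 3, tolerance = 1e-12)
  expect_equal(sum(dom$count), s$n_reefs_total)
  expect_equal(sum(dom$proportion), 1)

  tied <- estimates_table(aaga = c(2, 2), hmex = c(2, 2))
  st <- reefwise_summary(tied, "AMMONIUM_UMOL_M2_H")
  domt <- st$dominance[st$dominance$scope == "all", ]
  expect_equal(domt$proportion[domt$outcome == "equal"], 1)

  solo <- estimates_table(aaga = c(1, 2, 3), hmex = c(0, 0, 0))
  expect_warning(ss <- reefwise_summary(solo, "AMMONIUM_UMOL_M2_H"),
                 "both species")
  doms <- ss$dominance[ss$dominance$scope == "all", ]
  expect_equal(doms$proportion[doms$outcome == "AAGA_more"], 1)
  expect_equal(ss$n_reefs_both_present, 0)
})

test_that("dominance proportions are scale invariant and subsets coincide when all co-occur", {
  set.seed(77)
  a <- runif(10, 0.5, 3); h <- runif(10, 0.5, 3)
  s1 <- reefwise_summary(estimates_table(a, h), "AMMONIUM_UMOL_M2_H")
  s2 <- reefwise_summary(estimates_table(13 * a, 13 * h), "AMMONIUM_UMOL_M2_H")
  expect_equal(s1$dominance$proportion, s2$dominance$proportion)
  expect_equal(unname(s1$ratio_aaga_hmex["all"]),
               unname(s1$ratio_aaga_hmex["both_present"]))
  expect_equal(s1$per_species$mean[s1$per_species$scope == "all"],
               s1$per_species$mean[s1$per_species$scope == "both_present"])
})

test_that("paired reef test equals a one-sample t on per-reef differences", {
  set.seed(41)
  a <- runif(12, 0, 4); h <- runif(12, 0, 4)
  s <- reefwise_summary(estimates_table(a, h), "AMMONIUM_UMOL_M2_H", paired = TRUE)
  one <- t.test(a - h)
  expect_equal(s$test$t, unname(one$statistic), tolerance = 1e-12)
  expect_equal(s$test$p_value, one$p.value, tolerance = 1e-12)
  sw <- reefwise_summary(estimates_table(a, h), "AMMONIUM_UMOL_M2_H", paired = FALSE)
  expect_equal(sw$test$type, "WELCH_T")
})

test_that("ratio report rounds cross-reef mean ratios to 2 significant figures", {
  s <- reefwise_summary(estimates_table(aaga = c(3.0, 3.2), hmex = c(0.5, 0.58)),
                        "AMMONIUM_UMOL_M2_H")
  rr <- ratio_report(s)
  expect_equal(rr$ratio_raw[rr$scope == "all"], 3.1 / 0.54)
  expect_equal(rr$ratio_2sf[rr$scope == "all"], 5.7)
  eq <- reefwise_summary(estimates_table(c(2, 2), c(2, 2)), "AMMONIUM_UMOL_M2_H")
  expect_equal(ratio_report(eq)$ratio_2sf, c(1, 1))
  zero <- suppressWarnings(reefwise_summary(estimates_table(c(1, 2), c(0, 0)),
                                            "AMMONIUM_UMOL_M2_H"))
  expect_true(is.na(ratio_report(zero)$ratio_raw[1])) # undefined, not Inf
})

test_that("contribution share expresses summed parts against a background flux", {
  expect_equal(contribution_share(c(3.1, 0.54), 25), 100 * 3.64 / 25)
  expect_error(contribution_share(c(1, 2), 0))
})
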