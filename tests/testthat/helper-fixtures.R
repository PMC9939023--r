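# Small in-code fixtures and independent oracles shared across tests.

tiny_surveys <- function() {
  tibble::tibble(
    reef_id = c("A", "B"),
    hard_perimeter_m = c(10, 2 * pi),
    halo_perimeter_m = c(30, 4 * pi),
    depth_m = c(3.1, 2.8)
  )
}

tiny_individuals <- function() {
  tibble::tibble(
    reef_id = c("A", "A", "A", "B", "B"),
    species = c("AAGA", "AAGA", "HMEX", "AAGA", "AAGA"),
    length_cm = c(20, 22, 27, 19, 25),
    girth_cm = c(NA, 12, 14, NA, NA)
  )
}

# one-row pellet observation in pellets.csv layout
make_pellets <- function(species = "HMEX", counts = c(2, 3, 4),
                         dists = c(0.1, 0.2, 0.3), n_pellets = 10,
                         dw = 1.0, aw = 0.9, id = "P1") {
  out <- tibble::tibble(individual_id = id, species = species,
                        length_cm = 25, girth_cm = NA_real_,
                        n_pellets = n_pellets, dw_g = dw, aw_g = aw)
  for (h in seq_along(counts)) out[[paste0("count_h", h)]] <- counts[h]
  for (h in seq_along(dists)) out[[paste0("dist_h", h, "_m")]] <- dists[h]
  out
}

make_incubations <- function(animal_conc, species, control_conc = c(0.5, 0.5, 0.5),
                             volume = 20, duration = 60, weight = NA_real_,
                             length = NA_real_) {
  n <- length(animal_conc)
  dplyr::bind_rows(
    tibble::tibble(subject_id = paste0("S", seq_len(n)), is_control = 0L,
                   species = rep_len(species, n), bag_volume_l = volume,
                   duration_min = duration, nh4_umol_per_l = animal_conc,
                   wet_weight_g = rep_len(weight, n),
                   length_cm = rep_len(length, n)),
    tibble::tibble(subject_id = paste0("C", seq_along(control_conc)),
                   is_control = 1L, species = NA_character_,
                   bag_volume_l = volume, duration_min = duration,
                   nh4_umol_per_l = control_conc,
                   wet_weight_g = NA_real_, length_cm = NA_real_)
  )
}

# rates tibble with exact species means, for contrast/ratio checks
rates_with_means <- function(mean_hmex, mean_aaga, spread = 0.2) {
  tibble::tibble(
    species = rep(c("HMEX", "AAGA"), each = 4),
    rate_umol_h = c(mean_hmex + spread * c(-1, 1, -2, 2) / 2,
                    mean_aaga + spread * c(-1, 1, -2, 2) / 2)
  )
}

# Welch two-sample t from the textbook formula (independent of t.test)
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# two-sample KS D as the sup of |ECDF difference| by brute force
ks_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# exhaustive bootstrap: population SD of the transformed resample sums
# over all length(pool)^n equally likely resamples
enumerated_boot_sd <- function(pool, n, transform = identity) {
  idx <- do.call(expand.grid, rep(list(seq_along(pool)), n))
  sums <- apply(idx, 1, function(i) sum(pool[i]))
  v <- transform(sums)
  sqrt(mean((v - mean(v))^2))
}

# closed-form truncated-normal mean, independent of the generator's helper
truncnorm_mean_test <- function(m, s, lo, hi) {
  a <- (lo - m) / s; b <- (hi - m) / s
  m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# minimal reef-estimates table with chosen per-reef point estimates
estimates_table <- function(aaga, hmex, fun = "AMMONIUM_UMOL_M2_H",
                            n_aaga = NULL, n_hmex = NULL) {
  n <- length(aaga)
  if (is.null(n_aaga)) n_aaga <- ifelse(aaga > 0, 1L, 0L)
  if (is.null(n_hmex)) n_hmex <- ifelse(hmex > 0, 1L, 0L)
  tibble::tibble(
    reef_id = rep(sprintf("R%02d", seq_len(n)), 2),
    species = rep(c("AAGA", "HMEX"), each = n),
    fun = fun,
    n_individuals = as.integer(c(n_aaga, n_hmex)),
    point_estimate = c(aaga, hmex),
    bootstrap_se = 0, n_boot = 1L, seed = 1L
  )
}
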