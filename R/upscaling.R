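#' Bootstrap configuration
#'
#' @param n_boot number of bootstrap iterations (default 5000, the
#'   convention the reef-level standard errors are defined by: the SE is
#'   the standard deviation of the resampled reef totals).
#' @param seed master integer seed; per-reef streams are derived from it
#'   so results do not depend on reef processing order.
#' @param point_estimate_rule `"plug_in"` (default) reports the
#'   observed-individuals statistic with the bootstrap used only for the
#'   SE; `"boot_mean"` reports the mean over resamples.
#' @return a `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_boot = 5000, seed = 1L,
                             point_estimate_rule = c("plug_in", "boot_mean")) {
  stopifnot(n_boot >= 1)
  structure(list(n_boot = as.integer(n_boot), seed = as.integer(seed),
                 point_estimate_rule = match.arg(point_estimate_rule)),
            class = "bootstrap_config")
}

# Deterministic 32-bit FNV-1a hash of a string, folded with the master
# seed and reduced mod 2^31 - 1 so it is a valid set.seed() argument.
# Gives each (reef, species, function) its own reproducible RNG stream,
# independent of the order in which reefs are processed.
derive_stream_seed <- function(master_seed, ...) {
  key <- paste(master_seed, ..., sep = "|")
  mul32 <- function(a, b) { # a*b mod 2^32, exact in doubles
    hi <- a %/% 65536; lo <- a %% 65536
    (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
  }
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    lo <- h %% 65536 # xor on the low 16 bits keeps h in double-safe range
    h <- h - lo + bitwXor(lo, b %% 65536)
    h <- mul32(h, 16777619)
  }
  as.integer(h %% 2147483647)
}

# g/h -> kg/yr conversion factor for a species' activity budget
annual_factor <- function(species) activity_hours(species) * 365 / 1000

boot_one <- function(pool, n_ind, n_boot, transform) {
  sums <- vapply(seq_len(n_boot), function(i) {
    sum(pool[sample.int(length(pool), n_ind, replace = TRUE)])
  }, numeric(1))
  transform(sums)
}

#' Reef-level sediment-processing estimate for one reef and species
#'
#' The measured animals' hourly processing rates form a species-level
#' empirical pool (the reef's own animals were surveyed but not
#' tracked). Each bootstrap iteration draws, with replacement, as many
#' rates from that pool as the reef hosts individuals of the species,
#' sums them, converts g/h to kg/yr via the species activity budget
#' (x activity hours x 365 / 1000), and divides by the reef's seagrass
#' area. The point estimate is the plug-in value (pool mean x count,
#' converted, per area) by default; the bootstrap SE is the SD over
#' iterations. A reef hosting zero individuals of the species gets an
#' exact-zero estimate and SE.
#'
#' @param n_individuals count of this species on the reef.
#' @param seagrass_area_m2 seagrass area, m^2.
#' @param rate_pool empirical hourly rates (g/h) for this species.
#' @param species species code.
#' @param cfg a [bootstrap_config()].
#' @return one-row tibble: `species`, `fun`, `n_individuals`,
#'   `point_estimate`, `bootstrap_se`, `n_boot`, `seed`. Units: kg
#'   sediment m^-2 yr^-1.
#' @export
bootstrap_sediment <- function(n_individuals, seagrass_area_m2, rate_pool,
                               species, cfg = bootstrap_config()) {
  species <- validate_species(species)
  stopifnot(seagrass_area_m2 > 0)
  k <- annual_factor(species)
  if (n_individuals == 0) {
    return(estimate_row(species, "SEDIMENT_KG_M2_YR", 0L, 0, 0, cfg))
  }
  if (length(rate_pool) == 0 || any(is.na(rate_pool))) {
    stop(sprintf("empty or incomplete hourly-rate pool for %s", species), call. = FALSE)
  }
  point <- mean(rate_pool) * n_individuals * k / seagrass_area_m2
  vals <- withr::with_seed(cfg$seed,
    boot_one(rate_pool, n_individuals, cfg$n_boot,
             function(s) s * k / seagrass_area_m2))
  if (cfg$point_estimate_rule == "boot_mean") point <- mean(vals)
  estimate_row(species, "SEDIMENT_KG_M2_YR", n_individuals, point, sd(vals), cfg)
}

#' Reef-level ammonium-excretion estimate for one reef and species
#'
#' Surveyed lengths are converted to wet weights through the pooled
#' allometry; each bootstrap iteration resamples the reef's own
#' species-specific weight set with replacement (same size), predicts
#' each animal's conditional-mean excretion rate from the fitted model
#' (no residual resampling), sums, and divides by seagrass area.
#'
#' @param lengths_cm surveyed lengths of this species on this reef (cm).
#' @param seagrass_area_m2 seagrass area, m^2.
#' @param allometry an `allometry_fit`.
#' @param model an `excretion_fit`.
#' @param species species code.
#' @param cfg a [bootstrap_config()].
#' @return one-row tibble as in [bootstrap_sediment()]; units umol NH4+
#'   m^-2 h^-1.
#' @export
bootstrap_ammonium <- function(lengths_cm, seagrass_area_m2, allometry, model,
                               species, cfg = bootstrap_config()) {
  species <- validate_species(species)
  stopifnot(seagrass_area_m2 > 0)
  if (!inherits(allometry, "allometry_fit") || !inherits(model, "excretion_fit")) {
    stop("fitted allometry and excretion models are required", call. = FALSE)
  }
  n_ind <- length(lengths_cm)
  if (n_ind == 0) {
    return(estimate_row(species, "AMMONIUM_UMOL_M2_H", 0L, 0, 0, cfg))
  }
  if (any(is.na(lengths_cm))) stop("missing lengths in ammonium bootstrap", call. = FALSE)
  weights <- predict_weight(allometry, lengths_cm)
  rates <- predict_excretion(model, species, weights)
  point <- sum(rates) / seagrass_area_m2
  vals <- withr::with_seed(cfg$seed,
    boot_one(rates, n_ind, cfg$n_boot, function(s) s / seagrass_area_m2))
  if (cfg$point_estimate_rule == "boot_mean") point <- mean(vals)
  estimate_row(species, "AMMONIUM_UMOL_M2_H", n_ind, point, sd(vals), cfg)
}

estimate_row <- function(species, fun, n_ind, point, se, cfg) {
  tibble::tibble(species = species, fun = fun,
                 n_individuals = as.integer(n_ind),
                 point_estimate = point, bootstrap_se = se,
                 n_boot = cfg$n_boot, seed = cfg$seed)
}

#' Reef-level function estimates for every reef, species and function
#'
#' Runs [bootstrap_sediment()] and [bootstrap_ammonium()] for both
#' species on every reef: four estimate rows per reef. Each (reef,
#' species, function) gets its own RNG stream derived from the master
#' seed and the reef id, so the output is bit-identical under any reef
#' ordering and reruns with the same seed.
#'
#' @param geometry output of [compute_geometry()].
#' @param individuals surveyed individuals (`reef_id`, `species`,
#'   `length_cm`).
#' @param sediment_pools named list (by species code) of empirical hourly
#'   processing rates, g/h — e.g. split from [processing_rates()].
#' @param allometry,model fitted models (see [fit_allometry()],
#'   [fit_excretion_model()]).
#' @param cfg a [bootstrap_config()]; `cfg$seed` is the master seed.
#' @return tibble with `reef_id` plus the [bootstrap_sediment()] columns;
#'   `nrow = 4 * nrow(geometry)`.
#' @export
upscale_all_reefs <- function(geometry, individuals, sediment_pools,
                              allometry, model, cfg = bootstrap_config()) {
  check_columns(geometry, c("reef_id", "seagrass_area_m2"), "geometry")
  check_columns(individuals, c("reef_id", "species", "length_cm"), "individuals")
  orphan <- setdiff(unique(individuals$reef_id), geometry$reef_id)
  if (length(orphan) > 0) {
    stop(sprintf("no geometry for surveyed reef(s): %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(geometry)), function(i) {
    reef <- geometry$reef_id[i]
    area <- geometry$seagrass_area_m2[i]
    ind <- individuals[individuals$reef_id == reef, ]
    per_species <- lapply(species_codes(), function(sp) {
      sp_len <- ind$length_cm[ind$species == sp]
      sed_cfg <- cfg
      sed_cfg$seed <- derive_stream_seed(cfg$seed, reef, sp, "sediment")
      sed <- bootstrap_sediment(length(sp_len), area, sediment_pools[[sp]],
                                sp, sed_cfg)
      amm_cfg <- cfg
      amm_cfg$seed <- derive_stream_seed(cfg$seed, reef, sp, "ammonium")
      amm <- bootstrap_ammonium(sp_len, area, allometry, model, sp, amm_cfg)
      dplyr::bind_rows(sed, amm)
    })
    out <- dplyr::bind_rows(per_species)
    out$reef_id <- reef
    out
  })
  out <- dplyr::bind_rows(rows)
  # master seed in the seed column; per-row stream seeds are derived
  out$seed <- cfg$seed
  out[, c("reef_id", "species", "fun", "n_individuals", "point_estimate",
          "bootstrap_se", "n_boot", "seed")]
}
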