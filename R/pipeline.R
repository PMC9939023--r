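#' Pipeline stages
#'
#' File-based stages that chain the package's analysis steps into a
#' reproducible pipeline. Stages communicate only through documented
#' files in a working directory, so any stage can be re-run or swapped:
#'
#' * `run_simulate()`: generate a synthetic study into `dir`
#'   (`surveys.csv`, `individuals.csv`, `pellets.csv`,
#'   `incubations.csv`, `truth.json`).
#' * `run_rates()`: per-individual rates and fitted models
#'   (`processing_rates.csv`, `excretion_rates.csv`, `models.json`).
#' * `run_upscale()`: reef-level bootstrap estimates
#'   (`reef_estimates.csv`).
#' * `run_compare()`: species-contrast statistics
#'   (`comparison_report.json`, `reefwise_summary.csv`).
#' * `run_report()`: human-readable summary of per-capita means,
#'   reef-level means with SEs, ratios and dominance proportions.
#' * `run_all()`: chains all of the above.
#'
#' Every stage writes `run_metadata.json` (seed, config hash, package
#' version) sufficient to reproduce its outputs bit for bit.
#'
#' @param dir working directory holding the stage inputs and outputs.
#' @param seed master seed for the stage's randomness.
#' @param config a [synthetic_config()] for `run_simulate`/`run_all`.
#' @param n_boot,point_estimate_rule bootstrap settings, see
#'   [bootstrap_config()].
#' @param tolerance equal-contribution tolerance, see
#'   [reefwise_summary()].
#' @name pipeline
NULL

config_hash <- function(x) {
  derive_stream_seed(0L, jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                          null = "null", force = TRUE))
}

write_run_metadata <- function(dir, stage, seed, config = NULL) {
  jsonlite::write_json(
    list(stage = stage, seed = seed, config_hash = config_hash(config),
         version = as.character(utils::packageVersion("holofun"))),
    file.path(dir, "run_metadata.json"), auto_unbox = TRUE, digits = NA)
}

#' @rdname pipeline
#' @return `run_simulate`: the generated study, invisibly.
#' @export
run_simulate <- function(dir, seed = 1L, config = synthetic_config(seed = seed)) {
  study <- generate_study(config)
  write_study(study, dir)
  write_run_metadata(dir, "simulate", config$seed, unclass(config))
  invisible(study)
}

#' @rdname pipeline
#' @return `run_rates`: list with `processing`, `excretion`, `allometry`,
#'   `excretion_model`, invisibly.
#' @export
run_rates <- function(dir) {
  pellets <- read_pellets(file.path(dir, "pellets.csv"))
  incub <- read_incubations(file.path(dir, "incubations.csv"))
  processing <- processing_rates(pellets)
  excretion <- excretion_rates(incub)
  allometry <- fit_allometry(incub$length_cm[incub$is_control == 0],
                             incub$wet_weight_g[incub$is_control == 0])
  model <- fit_excretion_model(excretion)
  write_estimates(processing, file.path(dir, "processing_rates.csv"))
  write_estimates(excretion, file.path(dir, "excretion_rates.csv"))
  save_models(allometry, model, file.path(dir, "models.json"))
  write_run_metadata(dir, "rates", NA)
  invisible(list(processing = processing, excretion = excretion,
                 allometry = allometry, excretion_model = model))
}

#' @rdname pipeline
#' @return `run_upscale`: the reef estimates tibble, invisibly.
#' @export
run_upscale <- function(dir, seed = 1L, n_boot = 5000,
                        point_estimate_rule = "plug_in") {
  surveys <- read_surveys(file.path(dir, "surveys.csv"))
  individuals <- read_individuals(file.path(dir, "individuals.csv"))
  rates_path <- file.path(dir, "processing_rates.csv")
  if (!file.exists(rates_path)) {
    stop(sprintf("missing artifact %s (run the rates stage first)", rates_path),
         call. = FALSE)
  }
  processing <- readr::read_csv(rates_path, show_col_types = FALSE, progress = FALSE)
  models <- load_models(file.path(dir, "models.json"))
  geometry <- compute_geometry(surveys)
  pools <- split(processing$hourly_rate_g_h, processing$species)
  cfg <- bootstrap_config(n_boot = n_boot, seed = seed,
                          point_estimate_rule = point_estimate_rule)
  estimates <- upscale_all_reefs(geometry, individuals, pools,
                                 models$allometry, models$excretion, cfg)
  write_estimates(estimates, file.path(dir, "reef_estimates.csv"),
                  meta = list(seed = seed, n_boot = n_boot,
                              units = list(SEDIMENT_KG_M2_YR = "kg m-2 yr-1",
                                           AMMONIUM_UMOL_M2_H = "umol NH4+ m-2 h-1")))
  write_run_metadata(dir, "upscale", seed,
                     list(n_boot = n_boot, rule = point_estimate_rule))
  invisible(estimates)
}

#' @rdname pipeline
#' @return `run_compare`: the comparison report list, invisibly.
#' @export
run_compare <- function(dir, tolerance = 0.01) {
  estimates_path <- file.path(dir, "reef_estimates.csv")
  if (!file.exists(estimates_path)) {
    stop(sprintf("missing artifact %s (run the upscale stage first)", estimates_path),
         call. = FALSE)
  }
  estimates <- readr::read_csv(estimates_path, show_col_types = FALSE, progress = FALSE)
  surveys <- read_surveys(file.path(dir, "surveys.csv"))
  individuals <- read_individuals(file.path(dir, "individuals.csv"))
  excretion <- readr::read_csv(file.path(dir, "excretion_rates.csv"),
                               show_col_types = FALSE, progress = FALSE)
  processing <- readr::read_csv(file.path(dir, "processing_rates.csv"),
                                show_col_types = FALSE, progress = FALSE)
  geometry <- compute_geometry(surveys)
  densities <- compute_densities(geometry, individuals)

  summaries <- lapply(
    c(SEDIMENT_KG_M2_YR = "SEDIMENT_KG_M2_YR", AMMONIUM_UMOL_M2_H = "AMMONIUM_UMOL_M2_H"),
    function(f) reefwise_summary(estimates, f, tolerance = tolerance))
  report <- list(
    individual = list(
      sediment = species_rate_summary(processing),
      excretion = per_capita_contrast(excretion),
      length_ks = length_distribution_test(individuals)
    ),
    density = density_tests(densities),
    reef = lapply(summaries, function(s) {
      list(per_species = s$per_species, ratio_aaga_hmex = as.list(s$ratio_aaga_hmex),
           dominance = s$dominance, test = s$test,
           n_reefs_total = s$n_reefs_total,
           n_reefs_both_present = s$n_reefs_both_present)
    }),
    n_tests_run = 5 + 2 + 1 + 2, # no multiple-testing correction applied
    equality_tolerance = tolerance
  )
  jsonlite::write_json(report, file.path(dir, "comparison_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  reefwise <- dplyr::bind_rows(lapply(summaries, function(s) {
    out <- s$per_species
    out$fun <- s$fun
    out
  }))
  write_estimates(reefwise, file.path(dir, "reefwise_summary.csv"))
  write_run_metadata(dir, "compare", NA, list(tolerance = tolerance))
  invisible(c(report, list(summaries = summaries)))
}

#' @rdname pipeline
#' @return `run_report`: the rendered text, invisibly; the text is also
#'   written to `report.txt` and printed.
#' @export
run_report <- function(dir) {
  path <- file.path(dir, "comparison_report.json")
  if (!file.exists(path)) {
    stop(sprintf("missing artifact %s (run the compare stage first)", path),
         call. = FALSE)
  }
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  lines <- c("Ecosystem-function summary", "==========================", "")
  exc <- rep$individual$excretion
  lines <- c(lines, "Per-capita ammonium excretion (umol NH4+/h):")
  for (i in seq_len(nrow(exc$means))) {
    lines <- c(lines, sprintf("  %s: %.1f +- %.1f (n = %d)",
                              exc$means$species[i], exc$means$mean[i],
                              exc$means$se[i], exc$means$n[i]))
  }
  lines <- c(lines, sprintf("  percent difference (base = larger mean): %.0f%%",
                            exc$pct_diff_base_larger), "")
  sed <- rep$individual$sediment
  lines <- c(lines, sprintf(
    "Per-capita sediment processing: HMEX:AAGA hourly ratio %.2f (%.0f%% difference, base = larger)",
    sed$hourly_ratio_hmex_aaga, sed$hourly_pct_diff), "")
  for (f in names(rep$reef)) {
    r <- rep$reef[[f]]
    for (scope in unique(r$per_species$scope)) {
      ps <- r$per_species[r$per_species$scope == scope, ]
      dom <- r$dominance[r$dominance$scope == scope, ]
      lines <- c(lines, sprintf("%s [%s reefs: %d]", f, scope,
                                if (scope == "all") r$n_reefs_total else r$n_reefs_both_present))
      for (i in seq_len(nrow(ps))) {
        lines <- c(lines, sprintf("  %s: %.3g +- %.3g per m2", ps$species[i],
                                  ps$mean[i], ps$se[i]))
      }
      lines <- c(lines, sprintf("  AAGA:HMEX ratio of means: %.2g",
                                r$ratio_aaga_hmex[[scope]]))
      lines <- c(lines, sprintf("  dominance: AAGA %.0f%%, HMEX %.0f%%, equal %.0f%%",
                                100 * dom$proportion[dom$outcome == "AAGA_more"],
                                100 * dom$proportion[dom$outcome == "HMEX_more"],
                                100 * dom$proportion[dom$outcome == "equal"]))
      lines <- c(lines, "")
    }
  }
  text <- paste(lines, collapse = "\n")
  writeLines(text, file.path(dir, "report.txt"))
  cat(text, "\n")
  invisible(text)
}

#' @rdname pipeline
#' @return `run_all`: list of all stage outputs, invisibly.
#' @export
run_all <- function(dir, seed = 1L, n_boot = 5000,
                    config = synthetic_config(seed = seed)) {
  study <- run_simulate(dir, seed = seed, config = config)
  rates <- run_rates(dir)
  estimates <- run_upscale(dir, seed = seed, n_boot = n_boot)
  comparison <- run_compare(dir)
  invisible(list(study = study, rates = rates, estimates = estimates,
                 comparison = comparison))
}
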