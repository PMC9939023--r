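#' Ammonium excretion rates from sealed-bag incubations
#'
#' Each animal is incubated alone in a sealed bag of filtered sea water;
#' the ammonium accumulated over the incubation, above the mean of the
#' empty control bags, gives the hourly excretion rate:
#'
#' rate (umol/h) = (conc_animal - mean conc_control) x volume (L) x 60 / duration (min)
#'
#' Negative control-corrected rates are retained (not floored at zero) to
#' avoid biasing species means upward; they are flagged in the output and
#' a warning is emitted.
#'
#' @param incubations tibble in `incubations.csv` layout (see
#'   [read_incubations()]): animal rows with `is_control == 0` and at
#'   least one control row with `is_control == 1`.
#' @return tibble with `subject_id`, `species`, `rate_umol_h`,
#'   `wet_weight_g`, `length_cm`, `negative_flag`.
#' @export
excretion_rates <- function(incubations) {
  check_columns(incubations,
    c("subject_id", "is_control", "bag_volume_l", "duration_min", "nh4_umol_per_l"),
    "incubations")
  is_ctrl <- as.logical(incubations$is_control)
  controls <- incubations[is_ctrl, ]
  animals <- incubations[!is_ctrl, ]
  if (nrow(controls) == 0) stop("at least one control bag is required", call. = FALSE)
  if (any(animals$duration_min <= 0)) stop("incubation duration must be > 0", call. = FALSE)
  if (any(animals$bag_volume_l <= 0)) stop("bag volume must be > 0", call. = FALSE)
  validate_species(animals$species, "incubations")
  ctrl_mean <- mean(controls$nh4_umol_per_l)
  rate <- (animals$nh4_umol_per_l - ctrl_mean) * animals$bag_volume_l *
    (60 / animals$duration_min)
  neg <- rate < 0
  if (any(neg)) {
    warning(sprintf("%d negative control-corrected excretion rate(s) retained and flagged",
                    sum(neg)), call. = FALSE)
  }
  tibble::tibble(
    subject_id = animals$subject_id,
    species = animals$species,
    rate_umol_h = rate,
    wet_weight_g = if ("wet_weight_g" %in% names(animals)) animals$wet_weight_g else NA_real_,
    length_cm = if ("length_cm" %in% names(animals)) animals$length_cm else NA_real_,
    negative_flag = neg
  )
}

#' Length-to-wet-weight allometry
#'
#' Ordinary least squares of wet weight (g) on total length (cm), pooled
#' across both species (a single common relationship; per-species fits
#' are available via `by_species = TRUE`). Used to convert surveyed
#' lengths, which divers can measure underwater, into the wet weights the
#' excretion model needs.
#'
#' @param length_cm,wet_weight_g paired measurements; rows with either
#'   missing are dropped.
#' @param by_species optional species vector; if `TRUE`-like input is
#'   given per-species models are fitted (not the default).
#' @return object of class `allometry_fit`: list with `intercept`,
#'   `slope`, `f_statistic`, `df_num`, `df_den`, `p_value`, `r_squared`,
#'   `n`, and the underlying `lm` fit.
#' @export
fit_allometry <- function(length_cm, wet_weight_g) {
  ok <- complete.cases(length_cm, wet_weight_g)
  length_cm <- length_cm[ok]; wet_weight_g <- wet_weight_g[ok]
  if (length(length_cm) < 3) {
    stop("allometry fit requires >= 3 animals with both length and weight", call. = FALSE)
  }
  if (length(unique(length_cm)) < 2) {
    stop("allometry fit is singular: all lengths equal", call. = FALSE)
  }
  fit <- lm(wet_weight_g ~ length_cm)
  # an exactly linear input is legitimate (r^2 = 1); silence summary.lm's
  # "essentially perfect fit" notice for that case only
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("perfect fit", conditionMessage(w))) invokeRestart("muffleWarning")
  })
  structure(list(
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    f_statistic = unname(sm$fstatistic["value"]),
    df_num = unname(sm$fstatistic["numdf"]),
    df_den = unname(sm$fstatistic["dendf"]),
    p_value = unname(pf_upper(sm$fstatistic)),
    r_squared = sm$r.squared,
    slope_se = sm$coefficients["length_cm", "Std. Error"],
    n = length(length_cm),
    fit = fit
  ), class = "allometry_fit")
}

pf_upper <- function(fstat) {
  stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"], lower.tail = FALSE)
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("Length-weight allometry (pooled, n = %d)\n", x$n))
  cat(sprintf("  weight(g) = %.2f + %.2f x length(cm)\n", x$intercept, x$slope))
  cat(sprintf("  F(%d,%d) = %.2f, p = %.3g, r^2 = %.3f\n",
              x$df_num, x$df_den, x$f_statistic, x$p_value, x$r_squared))
  invisible(x)
}

#' Predict wet weight from length
#'
#' @param model an `allometry_fit`.
#' @param length_cm lengths in cm.
#' @return predicted wet weights in g.
#' @export
predict_weight <- function(model, length_cm) {
  stopifnot(inherits(model, "allometry_fit"))
  model$intercept + model$slope * length_cm
}

#' Excretion rate model: centred weight x species
#'
#' OLS of hourly ammonium excretion rate on data-centred wet weight,
#' species, and their interaction. The weight centring constant (grand
#' mean wet weight of the fitted animals) is stored in the model so
#' predictions are reproducible independent of the fitting data. The
#' reference species is AAGA, so the intercept is the AAGA mean rate at
#' the centring weight and the species term is the HMEX offset.
#'
#' @param rates output of [excretion_rates()] (needs `rate_umol_h`,
#'   `wet_weight_g`, `species`); both species must be present with >= 3
#'   animals each.
#' @return object of class `excretion_fit`: `beta0` (AAGA intercept,
#'   umol/h), `beta1` (weight slope, umol/h/g), `beta2` (HMEX offset),
#'   `beta3` (interaction), `weight_center` (g), `coef_table` (estimate,
#'   SE, p per term), `r_squared`, `n`, and the `lm` fit.
#' @export
fit_excretion_model <- function(rates) {
  check_columns(rates, c("species", "rate_umol_h", "wet_weight_g"), "rates")
  ok <- complete.cases(rates$rate_umol_h, rates$wet_weight_g)
  d <- rates[ok, ]
  validate_species(d$species, "rates")
  tab <- table(factor(d$species, levels = species_codes()))
  if (any(tab < 3)) {
    stop("excretion model requires both species with >= 3 animals each", call. = FALSE)
  }
  wc <- mean(d$wet_weight_g)
  d$w_centred <- d$wet_weight_g - wc
  d$sp <- factor(d$species, levels = c("AAGA", "HMEX"))
  fit <- lm(rate_umol_h ~ w_centred * sp, data = d)
  # residual-free inputs (exact species-offset structure) are a valid case
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("perfect fit", conditionMessage(w))) invokeRestart("muffleWarning")
  })
  cf <- sm$coefficients
  b <- coef(fit)
  structure(list(
    beta0 = unname(b["(Intercept)"]),
    beta1 = unname(b["w_centred"]),
    beta2 = unname(b["spHMEX"]),
    beta3 = unname(b["w_centred:spHMEX"]),
    weight_center = wc,
    coef_table = tibble::tibble(
      term = rownames(cf),
      estimate = cf[, "Estimate"],
      se = cf[, "Std. Error"],
      p_value = cf[, "Pr(>|t|)"]
    ),
    r_squared = sm$r.squared,
    n = nrow(d),
    fit = fit
  ), class = "excretion_fit")
}

#' @export
print.excretion_fit <- function(x, ...) {
  cat(sprintf("Excretion model (n = %d, weight centred at %.0f g, r^2 = %.3f)\n",
              x$n, x$weight_center, x$r_squared))
  cat(sprintf("  AAGA: %.2f + %.4f x (W - %.0f) umol NH4+/h\n",
              x$beta0, x$beta1, x$weight_center))
  cat(sprintf("  HMEX: %.2f + %.4f x (W - %.0f) umol NH4+/h\n",
              x$beta0 + x$beta2, x$beta1 + x$beta3, x$weight_center))
  invisible(x)
}

#' Predict hourly ammonium excretion
#'
#' Conditional-mean prediction from the fitted excretion model: no
#' residual noise is added. Extrapolation beyond the fitted weight range
#' is allowed (the model is affine in weight).
#'
#' @param model an `excretion_fit`.
#' @param species species codes, recycled against `wet_weight_g`.
#' @param wet_weight_g wet weights in g.
#' @return predicted rates, umol NH4+ per hour.
#' @export
predict_excretion <- function(model, species, wet_weight_g) {
  stopifnot(inherits(model, "excretion_fit"))
  species <- validate_species(species)
  n <- max(length(species), length(wet_weight_g))
  species <- rep_len(species, n); wet_weight_g <- rep_len(wet_weight_g, n)
  w <- wet_weight_g - model$weight_center
  hmex <- species == "HMEX"
  model$beta0 + model$beta1 * w + hmex * (model$beta2 + model$beta3 * w)
}

#' Per-capita species contrast in excretion rate
#'
#' Species means and standard errors of the per-individual excretion
#' rates, with the percent difference expressed relative to the larger
#' (HMEX) mean — the base convention under which means of 15.6 and 12.0
#' umol/h differ by 23% — alongside the conventional smaller-mean base.
#'
#' @param rates output of [excretion_rates()], or any tibble with
#'   `species` and `rate_umol_h`.
#' @return list with `means` (tibble species, n, mean, se),
#'   `pct_diff_base_larger`, `pct_diff_base_smaller`, and a Welch test
#'   (`t`, `df`, `p_value`).
#' @export
per_capita_contrast <- function(rates) {
  check_columns(rates, c("species", "rate_umol_h"), "rates")
  present <- intersect(species_codes(), unique(rates$species))
  if (length(present) < 2) stop("both species required for a contrast", call. = FALSE)
  means <- dplyr::summarise(dplyr::group_by(rates, .data$species),
    n = sum(!is.na(.data$rate_umol_h)),
    mean = mean(.data$rate_umol_h, na.rm = TRUE),
    se = sd(.data$rate_umol_h, na.rm = TRUE) / sqrt(sum(!is.na(.data$rate_umol_h))),
    .groups = "drop")
  m <- setNames(means$mean, means$species)
  hi <- max(m); lo <- min(m)
  w <- welch_t(rates$rate_umol_h[rates$species == "HMEX"],
               rates$rate_umol_h[rates$species == "AAGA"])
  list(
    means = means,
    pct_diff_base_larger = 100 * (hi - lo) / hi,
    pct_diff_base_smaller = if (lo != 0) 100 * (hi - lo) / lo else NA_real_,
    t = w$statistic, df = w$df, p_value = w$p_value
  )
}

#' Save / load fitted models as JSON
#'
#' Serialises the allometry and excretion models (coefficients, SEs,
#' centring constant, fit statistics — everything needed for prediction
#' and reporting, but not the raw `lm` objects) to a JSON file for reuse
#' by the upscaling stage.
#'
#' @param allometry an `allometry_fit`.
#' @param excretion an `excretion_fit`.
#' @param path JSON file path.
#' @return `path` invisibly (`save_models`); a list with elements
#'   `allometry` and `excretion` (`load_models`).
#' @export
save_models <- function(allometry, excretion, path) {
  stopifnot(inherits(allometry, "allometry_fit"), inherits(excretion, "excretion_fit"))
  strip <- function(m) m[setdiff(names(m), "fit")]
  jsonlite::write_json(
    list(allometry = strip(unclass(allometry)),
         excretion = strip(unclass(excretion)),
         version = as.character(utils::packageVersion("holofun"))),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname save_models
#' @export
load_models <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("fitted-model file not found: %s (run the rates stage first)", path),
         call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allometry <- structure(raw$allometry, class = "allometry_fit")
  excretion <- raw$excretion
  excretion$coef_table <- tibble::as_tibble(excretion$coef_table)
  excretion <- structure(excretion, class = "excretion_fit")
  list(allometry = allometry, excretion = excretion)
}
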