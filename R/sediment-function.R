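#' Fecal pellet chemistry
#'
#' Ash-free dry weight (AFDW) of a pooled pellet sample is dry weight
#' minus ash weight after combustion; organic-matter content is AFDW as a
#' percentage of dry weight. Individuals from which no pellets were
#' collected get missing (NA) chemistry rather than an error. An ash
#' weight exceeding the dry weight is physically impossible (a furnace
#' artefact) and raises a validation error.
#'
#' @param dw_g pooled dry weight, g.
#' @param aw_g pooled ash weight, g.
#' @param n_pellets number of pellets in the pooled sample (0-10).
#' @return tibble with `dry_weight_g`, `ash_weight_g`, `afdw_g`,
#'   `organic_matter_pct` (all NA where `n_pellets == 0`).
#' @export
pellet_chemistry <- function(dw_g, aw_g, n_pellets) {
  n <- max(length(dw_g), length(aw_g), length(n_pellets))
  dw_g <- rep_len(dw_g, n); aw_g <- rep_len(aw_g, n)
  n_pellets <- rep_len(n_pellets, n)
  have <- n_pellets > 0
  bad <- which(have & aw_g > dw_g)
  if (length(bad) > 0) {
    stop(sprintf("ash weight exceeds dry weight (row %s): furnace artefact",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(have & dw_g <= 0)) {
    stop("dry weight must be > 0 when pellets were collected", call. = FALSE)
  }
  afdw <- ifelse(have, dw_g - aw_g, NA_real_)
  tibble::tibble(
    dry_weight_g = ifelse(have, dw_g, NA_real_),
    ash_weight_g = ifelse(have, aw_g, NA_real_),
    afdw_g = afdw,
    organic_matter_pct = 100 * afdw / ifelse(have, dw_g, NA_real_)
  )
}

#' Hourly egestion rate from repeated pellet counts
#'
#' The egestion rate is the arithmetic mean of the hourly pellet counts
#' (pellets per hour). Using the mean rather than total/3 supports
#' variable-length observation windows: missing hours (NA) are dropped.
#'
#' @param counts numeric vector of hourly pellet counts for one
#'   individual, or a matrix/data frame with one row per individual.
#' @return pellets per hour (scalar or one value per row).
#' @export
egestion_rate <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (is.matrix(counts)) {
    if (ncol(counts) == 0) stop("at least one hourly count is required", call. = FALSE)
    return(rowMeans(counts, na.rm = TRUE))
  }
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0) stop("at least one hourly count is required", call. = FALSE)
  if (any(counts < 0)) stop("pellet counts must be non-negative", call. = FALSE)
  mean(counts)
}

#' Per-pellet dry weight
#'
#' Pooled dry weight divided by the number of pellets in the pool.
#' Individuals with no collected pellets get NA; downstream,
#' [processing_rates()] substitutes the species-mean pellet weight.
#'
#' @param dw_g pooled dry weight, g.
#' @param n_pellets pellets in the pool.
#' @return g per pellet (NA where `n_pellets == 0`).
#' @export
per_pellet_weight <- function(dw_g, n_pellets) {
  ifelse(n_pellets > 0, dw_g / n_pellets, NA_real_)
}

#' Per-individual sediment processing rates
#'
#' Combines egestion rate (pellets per hour) with per-pellet weight to
#' give an hourly sediment processing rate (g per hour, assuming egested
#' mass equals ingested mass), then extrapolates to an annual rate using
#' the species activity budget:
#' annual (kg/yr) = hourly (g/h) x activity hours x 365 / 1000.
#' The annual figure assumes rates are constant year-round. Movement
#' speed is the mean of the hourly distances.
#'
#' @param pellets tibble in `pellets.csv` layout (see [read_pellets()]).
#' @param pellet_weight_rule `"individual"` (default) uses each animal's
#'   own per-pellet weight, falling back to the species mean when no
#'   pellets were collected; `"species_mean"` uses the species mean for
#'   every animal.
#' @return tibble with `individual_id`, `species`, `egestion_rate_h`,
#'   `pellet_weight_g`, `hourly_rate_g_h`, `annual_rate_kg_yr`,
#'   `speed_m_h`, `organic_matter_pct`.
#' @export
processing_rates <- function(pellets,
                             pellet_weight_rule = c("individual", "species_mean")) {
  pellet_weight_rule <- match.arg(pellet_weight_rule)
  check_columns(pellets, c("individual_id", "species", "n_pellets", "dw_g", "aw_g"),
                "pellets")
  validate_species(pellets$species, "pellets")
  count_cols <- grep("^count_h", names(pellets), value = TRUE)
  dist_cols <- grep("^dist_h", names(pellets), value = TRUE)
  if (length(count_cols) == 0) stop("pellets needs at least one count_h* column", call. = FALSE)
  eg <- egestion_rate(pellets[count_cols])
  speed <- if (length(dist_cols) > 0) {
    rowMeans(as.matrix(pellets[dist_cols]), na.rm = TRUE)
  } else {
    rep(NA_real_, nrow(pellets))
  }
  chem <- pellet_chemistry(pellets$dw_g, pellets$aw_g, pellets$n_pellets)
  own_w <- per_pellet_weight(pellets$dw_g, pellets$n_pellets)
  species_mean_w <- tapply(own_w, pellets$species, mean, na.rm = TRUE)
  w <- switch(pellet_weight_rule,
    individual = ifelse(is.na(own_w), species_mean_w[pellets$species], own_w),
    species_mean = species_mean_w[pellets$species]
  )
  w <- unname(as.numeric(w))
  hourly <- eg * w
  tibble::tibble(
    individual_id = pellets$individual_id,
    species = pellets$species,
    egestion_rate_h = eg,
    pellet_weight_g = w,
    hourly_rate_g_h = hourly,
    annual_rate_kg_yr = hourly * activity_hours(pellets$species) * 365 / 1000,
    speed_m_h = speed,
    organic_matter_pct = chem$organic_matter_pct
  )
}

# Welch two-sample t with degenerate-variance handling shared by the
# summary/comparison functions. Groups with zero variance and unequal
# means are exact separation: t is +-Inf in the limit, p reported as 0
# with a warning instead of t.test()'s hard error.
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("Welch t-test needs at least 2 observations per group", call. = FALSE)
  }
  if (var(x) == 0 && var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(statistic = 0, df = length(x) + length(y) - 2, p_value = 1))
    }
    warning("both groups have zero variance with unequal means; p reported as 0",
            call. = FALSE)
    return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p_value = 0))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Species contrasts on sediment-processing metrics
#'
#' Per-species means and standard errors plus two-sided Welch t-tests for
#' five per-individual metrics: egestion rate, pellet weight, hourly
#' processing rate, organic-matter content, and movement speed. Also
#' reports the HMEX:AAGA hourly-rate ratio under both conventions (ratio
#' of means, and percent difference relative to the larger mean).
#'
#' @param rates output of [processing_rates()].
#' @return list with `summary` (tibble: metric, species, n, mean, se),
#'   `tests` (tibble: metric, t, df, p_value), `hourly_ratio_hmex_aaga`,
#'   and `hourly_pct_diff` (percent by which the larger species mean
#'   exceeds the smaller, base = larger).
#' @export
species_rate_summary <- function(rates) {
  metrics <- c(egestion_rate_h = "egestion_rate_h",
               pellet_weight_g = "pellet_weight_g",
               hourly_rate_g_h = "hourly_rate_g_h",
               organic_matter_pct = "organic_matter_pct",
               speed_m_h = "speed_m_h")
  metrics <- metrics[metrics %in% names(rates)]
  present <- intersect(species_codes(), unique(rates$species))
  summ <- dplyr::bind_rows(lapply(names(metrics), function(m) {
    dplyr::summarise(dplyr::group_by(rates, .data$species),
      metric = m,
      n = sum(!is.na(.data[[m]])),
      mean = mean(.data[[m]], na.rm = TRUE),
      se = sd(.data[[m]], na.rm = TRUE) / sqrt(sum(!is.na(.data[[m]]))),
      .groups = "drop")
  }))
  tests <- NULL
  if (length(present) == 2) {
    tests <- dplyr::bind_rows(lapply(names(metrics), function(m) {
      w <- welch_t(rates[[m]][rates$species == "HMEX"],
                   rates[[m]][rates$species == "AAGA"])
      tibble::tibble(metric = m, t = w$statistic, df = w$df, p_value = w$p_value)
    }))
  } else {
    warning("a species is absent; Welch tests skipped", call. = FALSE)
  }
  hr <- tapply(rates$hourly_rate_g_h, rates$species, mean, na.rm = TRUE)
  ratio <- if (all(c("HMEX", "AAGA") %in% names(hr))) unname(hr["HMEX"] / hr["AAGA"]) else NA_real_
  pct <- if (!is.na(ratio)) 100 * abs(diff(range(hr))) / max(hr) else NA_real_
  list(summary = summ[, c("metric", "species", "n", "mean", "se")],
       tests = tests,
       hourly_ratio_hmex_aaga = ratio,
       hourly_pct_diff = pct)
}
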