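#' Two-sample Kolmogorov-Smirnov test on body lengths
#'
#' Compares the length distributions of the two species across all
#' surveyed individuals (two-sided, asymptotic p to tolerate the ties
#' produced by lengths recorded to the nearest cm).
#'
#' @param individuals tibble with `species` and `length_cm`.
#' @return list: `statistic` (D), `p_value`, `n` (per-species counts).
#' @export
length_distribution_test <- function(individuals) {
  check_columns(individuals, c("species", "length_cm"), "individuals")
  x <- individuals$length_cm[individuals$species == "HMEX"]
  y <- individuals$length_cm[individuals$species == "AAGA"]
  if (length(x) < 2 || length(y) < 2) {
    stop("KS test needs >= 2 lengths per species", call. = FALSE)
  }
  ks <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n = c(HMEX = length(x), AAGA = length(y)))
}

#' Welch tests on per-reef densities and density proportions
#'
#' Tests whether the two species differ in mean density (individuals per
#' m^2 of seagrass, across reefs) and in mean proportion of the total
#' density at each reef.
#'
#' @param densities output of [compute_densities()] (both species per
#'   reef, zeros included).
#' @return tibble with one row per metric (`density`, `proportion`):
#'   per-species means, SEs, Welch `t`, `df`, `p_value`.
#' @export
density_tests <- function(densities) {
  check_columns(densities, c("reef_id", "species", "density_m2"), "densities")
  wide <- split(densities, densities$species)
  if (!all(species_codes() %in% names(wide))) {
    stop("densities must include rows (possibly zero) for both species", call. = FALSE)
  }
  h <- wide$HMEX[order(wide$HMEX$reef_id), ]
  a <- wide$AAGA[order(wide$AAGA$reef_id), ]
  if (nrow(h) < 2) stop("density tests need >= 2 reefs", call. = FALSE)
  stopifnot(identical(h$reef_id, a$reef_id))
  total <- h$density_m2 + a$density_m2
  if (any(total <= 0)) {
    stop("reef(s) with zero total density cannot contribute a proportion", call. = FALSE)
  }
  one <- function(metric, x, y) {
    w <- welch_t(x, y)
    tibble::tibble(metric = metric,
                   mean_hmex = mean(x), se_hmex = sd(x) / sqrt(length(x)),
                   mean_aaga = mean(y), se_aaga = sd(y) / sqrt(length(y)),
                   t = w$statistic, df = w$df, p_value = w$p_value)
  }
  dplyr::bind_rows(
    one("density", h$density_m2, a$density_m2),
    one("proportion", h$density_m2 / total, a$density_m2 / total)
  )
}

#' Cross-reef summary of reef-level function estimates
#'
#' For one function (sediment or ammonium), summarises the per-reef
#' species estimates across reefs: cross-reef means and SEs per species
#' over all reefs and over the subset where both species are present;
#' the ratio of the cross-reef means on both scopes; counts and
#' proportions of reefs at which each species contributes more (two
#' per-reef estimates within `tolerance` relative difference count as
#' equal); and a species comparison test across reefs — paired t by
#' default (each reef contributes both species' estimates), with an
#' unpaired Welch option.
#'
#' @param estimates output of [upscale_all_reefs()].
#' @param fun `"SEDIMENT_KG_M2_YR"` or `"AMMONIUM_UMOL_M2_H"`.
#' @param tolerance relative difference below which two per-reef
#'   estimates are called equal (default 0.01, i.e. 1%).
#' @param paired logical; paired t across reefs (default) or Welch.
#' @return list of class `reefwise_summary`; see Details in the fields:
#'   `per_species` (tibble: scope, species, n_reefs, mean, se),
#'   `ratio_aaga_hmex` (named: all, both_present), `dominance` (tibble:
#'   species/equal counts and proportions over the both-present subset,
#'   and over all reefs), `test` (t, df, p_value, type),
#'   `n_reefs_total`, `n_reefs_both_present`, `equality_tolerance`.
#' @export
reefwise_summary <- function(estimates, fun, tolerance = 0.01, paired = TRUE) {
  check_columns(estimates, c("reef_id", "species", "fun", "n_individuals",
                             "point_estimate"), "estimates")
  d <- estimates[estimates$fun == fun, ]
  if (nrow(d) == 0) stop(sprintf("no estimates for function %s", fun), call. = FALSE)
  h <- d[d$species == "HMEX", ]; a <- d[d$species == "AAGA", ]
  h <- h[order(h$reef_id), ]; a <- a[order(a$reef_id), ]
  stopifnot(identical(h$reef_id, a$reef_id))
  both <- h$n_individuals > 0 & a$n_individuals > 0
  if (!any(both)) warning("no reef hosts both species; both-present summaries are empty",
                          call. = FALSE)

  scope_summary <- function(scope, keep) {
    tibble::tibble(
      scope = scope,
      species = c("AAGA", "HMEX"),
      n_reefs = sum(keep),
      mean = c(mean(a$point_estimate[keep]), mean(h$point_estimate[keep])),
      se = c(sd(a$point_estimate[keep]), sd(h$point_estimate[keep])) / sqrt(sum(keep))
    )
  }
  per_species <- dplyr::bind_rows(
    scope_summary("all", rep(TRUE, nrow(h))),
    if (any(both)) scope_summary("both_present", both)
  )
  ratio_of <- function(keep) {
    mh <- mean(h$point_estimate[keep]); ma <- mean(a$point_estimate[keep])
    if (mh <= 0) NA_real_ else ma / mh
  }
  ratio <- c(all = ratio_of(rep(TRUE, nrow(h))),
             both_present = if (any(both)) ratio_of(both) else NA_real_)

  dominance_of <- function(keep) {
    av <- a$point_estimate[keep]; hv <- h$point_estimate[keep]
    denom <- pmax(abs(av), abs(hv))
    rel <- ifelse(denom == 0, 0, abs(av - hv) / denom)
    equal <- rel <= tolerance
    n <- sum(keep)
    tibble::tibble(
      outcome = c("AAGA_more", "HMEX_more", "equal"),
      count = c(sum(!equal & av > hv), sum(!equal & hv > av), sum(equal)),
      proportion = c(sum(!equal & av > hv), sum(!equal & hv > av), sum(equal)) / n
    )
  }
  dominance <- dplyr::bind_rows(
    dplyr::mutate(dominance_of(rep(TRUE, nrow(h))), scope = "all"),
    if (any(both)) dplyr::mutate(dominance_of(both), scope = "both_present")
  )

  test <- if (nrow(h) >= 2) {
    if (paired) {
      diffs <- a$point_estimate - h$point_estimate
      scale <- max(abs(diffs), 1)
      if (sd(diffs) <= 1e-12 * scale) {
        # constant differences: t is 0 (all zero) or +-Inf in the limit
        if (max(abs(diffs)) <= 1e-12 * scale) {
          list(t = 0, df = length(diffs) - 1, p_value = 1, type = "PAIRED_T")
        } else {
          warning("constant nonzero per-reef differences; p reported as 0",
                  call. = FALSE)
          list(t = sign(diffs[1]) * Inf, df = length(diffs) - 1, p_value = 0,
               type = "PAIRED_T")
        }
      } else {
        tt <- t.test(a$point_estimate, h$point_estimate, paired = TRUE)
        list(t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, type = "PAIRED_T")
      }
    } else {
      w <- welch_t(a$point_estimate, h$point_estimate)
      list(t = w$statistic, df = w$df, p_value = w$p_value, type = "WELCH_T")
    }
  } else NULL

  structure(list(
    fun = fun,
    n_reefs_total = nrow(h),
    n_reefs_both_present = sum(both),
    per_species = per_species,
    ratio_aaga_hmex = ratio,
    dominance = dominance,
    test = test,
    equality_tolerance = tolerance
  ), class = "reefwise_summary")
}

#' @export
print.reefwise_summary <- function(x, ...) {
  cat(sprintf("Reef-wise summary: %s (%d reefs, %d with both species)\n",
              x$fun, x$n_reefs_total, x$n_reefs_both_present))
  print(x$per_species)
  cat(sprintf("AAGA:HMEX ratio of cross-reef means: all %.3g, both-present %.3g\n",
              x$ratio_aaga_hmex["all"], x$ratio_aaga_hmex["both_present"]))
  print(x$dominance)
  invisible(x)
}

#' Ratio report with 2-significant-figure rounding
#'
#' Formats the cross-reef mean ratios of a [reefwise_summary()] to two
#' significant figures (the raw ratios are carried alongside). A zero or
#' negative denominator mean yields an undefined (NA) ratio.
#'
#' @param summary a `reefwise_summary`.
#' @return tibble: `scope`, `ratio_raw`, `ratio_2sf`.
#' @export
ratio_report <- function(summary) {
  stopifnot(inherits(summary, "reefwise_summary"))
  r <- summary$ratio_aaga_hmex
  tibble::tibble(scope = names(r), ratio_raw = unname(r),
                 ratio_2sf = signif(unname(r), 2))
}

#' Share of a combined contribution relative to a background flux
#'
#' Expresses the summed per-area contributions of a set of sources as a
#' percentage of a reference flux in the same units — e.g. both sea
#' cucumber species' ammonium output against the ammonium released by
#' the resident reef fish community.
#'
#' @param parts numeric vector of contributions (same units as `total`).
#' @param total reference flux; must be > 0.
#' @return percentage, `100 * sum(parts) / total`.
#' @export
contribution_share <- function(parts, total) {
  stopifnot(total > 0)
  100 * sum(parts) / total
}
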