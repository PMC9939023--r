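#' Convert a measured perimeter to an enclosed area
#'
#' Reef patches and their seagrass halos are quasi-circular, so the
#' default shape model treats a measured perimeter P as the circumference
#' of a circle and returns A = P^2 / (4 * pi). The shape model is an
#' explicit argument so an ellipse variant can be added without changing
#' callers; only the circular model is currently implemented.
#'
#' @param perimeter numeric vector of perimeters in metres; all > 0.
#' @param shape geometric model; only `"circle"`.
#' @return areas in square metres.
#' @examples
#' perimeter_to_area(4 * pi) # circle of radius 2 -> 4*pi m^2
#' @export
perimeter_to_area <- function(perimeter, shape = c("circle")) {
  shape <- match.arg(shape)
  if (!is.numeric(perimeter) || any(!is.finite(perimeter)) || any(perimeter <= 0)) {
    stop("perimeter must be finite and > 0", call. = FALSE)
  }
  perimeter^2 / (4 * pi)
}

#' Compute reef geometry from surveyed perimeters
#'
#' Converts the hard-bottom and outer seagrass-halo perimeters of each
#' reef to areas and subtracts the hard-bottom area from the total to
#' obtain the seagrass area, the denominator of all per-unit-area
#' function estimates.
#'
#' @param surveys tibble with columns `reef_id`, `hard_perimeter_m`,
#'   `halo_perimeter_m` (and optionally `depth_m`), one row per reef.
#' @param shape geometric model passed to [perimeter_to_area()].
#' @return tibble with `reef_id`, `hard_area_m2`, `total_area_m2`,
#'   `seagrass_area_m2`.
#' @export
compute_geometry <- function(surveys, shape = "circle") {
  req <- c("reef_id", "hard_perimeter_m", "halo_perimeter_m")
  check_columns(surveys, req, "surveys")
  bad <- which(surveys$halo_perimeter_m < surveys$hard_perimeter_m)
  if (length(bad) > 0) {
    stop(sprintf("halo perimeter smaller than hard perimeter for reef(s) %s",
                 paste(surveys$reef_id[bad], collapse = ", ")), call. = FALSE)
  }
  hard <- perimeter_to_area(surveys$hard_perimeter_m, shape)
  total <- perimeter_to_area(surveys$halo_perimeter_m, shape)
  seagrass <- total - hard
  bad <- which(seagrass <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive seagrass area for reef(s) %s",
                 paste(surveys$reef_id[bad], collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(
    reef_id = surveys$reef_id,
    hard_area_m2 = hard,
    total_area_m2 = total,
    seagrass_area_m2 = seagrass
  )
}

#' Per-reef species densities
#'
#' Counts surveyed individuals per reef and species and expresses them as
#' individuals per square metre of seagrass. Species absent from a reef
#' are materialised as explicit zero-count, zero-density rows so that
#' downstream reef-level function estimates exist (with value 0) for
#' absent species.
#'
#' @param geometry output of [compute_geometry()].
#' @param individuals tibble with columns `reef_id`, `species` (and
#'   usually `length_cm`), one row per surveyed animal. Every `reef_id`
#'   must appear in `geometry`.
#' @return tibble `reef_id`, `species`, `count`, `density_m2`.
#' @export
compute_densities <- function(geometry, individuals) {
  check_columns(geometry, c("reef_id", "seagrass_area_m2"), "geometry")
  check_columns(individuals, c("reef_id", "species"), "individuals")
  validate_species(individuals$species, "individuals")
  orphan <- setdiff(unique(individuals$reef_id), geometry$reef_id)
  if (length(orphan) > 0) {
    stop(sprintf("individuals reference reef_id(s) with no geometry: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  grid <- tidyr_expand_grid(geometry$reef_id, species_codes())
  counts <- dplyr::count(individuals, .data$reef_id, .data$species, name = "count")
  out <- dplyr::left_join(grid, counts, by = c("reef_id", "species"))
  out$count[is.na(out$count)] <- 0L
  out <- dplyr::left_join(out, geometry[, c("reef_id", "seagrass_area_m2")],
                          by = "reef_id")
  out$density_m2 <- out$count / out$seagrass_area_m2
  out$seagrass_area_m2 <- NULL
  out
}

# expand.grid in reef-major order with stable column names, as a tibble
tidyr_expand_grid <- function(reef_ids, species) {
  tibble::tibble(
    reef_id = rep(reef_ids, each = length(species)),
    species = rep(species, times = length(reef_ids))
  )
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

read_table_checked <- function(path, required, what, numeric_cols = character()) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, required, what)
  for (col in intersect(numeric_cols, names(df))) {
    if (!is.numeric(df[[col]])) {
      parsed <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(parsed) & !is.na(df[[col]]))
      if (length(bad) > 0) {
        stop(sprintf("unparseable numeric in %s column '%s' (row %s)",
                     what, col, paste(bad, collapse = ", ")), call. = FALSE)
      }
      df[[col]] <- parsed
    }
  }
  df
}

#' Read survey input tables
#'
#' Readers for the four delimited-text input tables. All are
#' comma-separated UTF-8 with a mandatory header row and "." decimal
#' separator; unknown extra columns are preserved and ignored. Species
#' labels must be valid codes (see [species_codes()]); violations are
#' reported with their row number.
#'
#' * `surveys.csv`: `reef_id`, `hard_perimeter_m`, `halo_perimeter_m`, `depth_m`
#' * `individuals.csv`: `reef_id`, `species`, `length_cm`, optional `girth_cm`
#' * `pellets.csv`: `individual_id`, `species`, `length_cm`, `girth_cm`,
#'   `count_h1..count_h3`, `dist_h1_m..dist_h3_m`, `n_pellets`, `dw_g`, `aw_g`
#' * `incubations.csv`: `subject_id`, `is_control`, `species`,
#'   `bag_volume_l`, `duration_min`, `nh4_umol_per_l`, `wet_weight_g`,
#'   `length_cm`, `girth_cm`, `temp_c`
#'
#' @param path file path.
#' @param length_window plausibility window (cm) for surveyed lengths;
#'   values outside it raise a warning, not an error.
#' @return a tibble, one row per record.
#' @export
read_surveys <- function(path) {
  read_table_checked(path,
    c("reef_id", "hard_perimeter_m", "halo_perimeter_m"), "surveys",
    numeric_cols = c("hard_perimeter_m", "halo_perimeter_m", "depth_m"))
}

#' @rdname read_surveys
#' @export
read_individuals <- function(path, length_window = c(5, 60)) {
  df <- read_table_checked(path, c("reef_id", "species", "length_cm"),
                           "individuals", numeric_cols = c("length_cm", "girth_cm"))
  validate_species(df$species, "individuals")
  bad <- which(df$length_cm < length_window[1] | df$length_cm > length_window[2])
  if (length(bad) > 0) {
    warning(sprintf(
      "%d individual length(s) outside the plausibility window [%g, %g] cm (row %s)",
      length(bad), length_window[1], length_window[2],
      paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname read_surveys
#' @export
read_pellets <- function(path) {
  df <- read_table_checked(path,
    c("individual_id", "species", "n_pellets", "dw_g", "aw_g"), "pellets",
    numeric_cols = c("length_cm", "girth_cm", "count_h1", "count_h2", "count_h3",
                     "dist_h1_m", "dist_h2_m", "dist_h3_m", "n_pellets",
                     "dw_g", "aw_g"))
  validate_species(df$species, "pellets")
  df
}

#' @rdname read_surveys
#' @export
read_incubations <- function(path) {
  df <- read_table_checked(path,
    c("subject_id", "is_control", "bag_volume_l", "duration_min", "nh4_umol_per_l"),
    "incubations",
    numeric_cols = c("is_control", "bag_volume_l", "duration_min",
                     "nh4_umol_per_l", "wet_weight_g", "length_cm", "girth_cm",
                     "temp_c"))
  animals <- !as.logical(df$is_control)
  if (any(animals)) validate_species(df$species[animals], "incubations")
  df
}

#' Write an output table with a run-metadata sidecar
#'
#' Writes `x` as CSV and a JSON sidecar (same path with a `.json`
#' extension) recording the seed, a config hash, and the package version,
#' so any output can be traced back to the run that produced it.
#'
#' @param x data frame to write.
#' @param path output CSV path.
#' @param meta named list merged into the sidecar (e.g. `seed`, `config`).
#' @return `path`, invisibly.
#' @export
write_estimates <- function(x, path, meta = list()) {
  readr::write_csv(x, path, progress = FALSE)
  sidecar <- c(meta, list(
    version = as.character(utils::packageVersion("holofun")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rows = nrow(x)
  ))
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
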