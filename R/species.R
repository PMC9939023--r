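#' Species codes and activity budgets
#'
#' Two sympatric Caribbean sea cucumbers are supported: *Holothuria
#' mexicana* (`"HMEX"`) and *Actinopyga agassizii* (`"AAGA"`). Daily
#' activity budgets (hours spent feeding) are species-specific and are
#' used to scale hourly sediment-processing rates to daily and annual
#' rates: 12 h for HMEX, 10 h for AAGA.
#'
#' @return `species_codes()` returns the character vector of valid codes.
#' @export
species_codes <- function() c("HMEX", "AAGA")

.ACTIVITY_HOURS <- c(HMEX = 12, AAGA = 10)

#' @rdname species_codes
#' @param species character vector of species codes.
#' @return `activity_hours()` returns the daily feeding hours for each
#'   element of `species`.
#' @export
activity_hours <- function(species) {
  species <- validate_species(species)
  unname(.ACTIVITY_HOURS[species])
}

#' Validate species codes
#'
#' @param species character vector.
#' @param where context string used in error messages (e.g. a file name).
#' @return `species`, unchanged, invisibly usable.
#' @keywords internal
validate_species <- function(species, where = "input") {
  bad <- which(!species %in% species_codes())
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown species label(s) %s in %s (row %s); expected one of %s",
      paste(unique(species[bad]), collapse = ", "), where,
      paste(bad, collapse = ", "),
      paste(species_codes(), collapse = ", ")
    ), call. = FALSE)
  }
  species
}
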