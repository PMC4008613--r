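#' Published reference tables shipped with the package
#'
#' Two small plain-text tables from the 2007-2011 Murray-Goulburn golden
#' perch acoustic-telemetry study ship under `extdata` so that worked
#' examples are recomputable without the (unpublished) raw telemetry data:
#'
#' * `golden_perch_tags()` — the 79 tagged fish: id, capture river, tagging
#'   year, total length (mm), weight (g), and whether the fish was caught
#'   and kept by an angler.
#' * `murray_model_average()` — the published model-average coefficient
#'   table for the diagonal-A transition model (persistence of fish
#'   currently in the Murray River): term (in this package's vocabulary),
#'   printed label, estimate, 95% CI bounds and relative importance.
#'
#' @return a tibble.
#' @examples
#' cohort_summary(golden_perch_tags())
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
golden_perch_tags <- function() {
  readr::read_csv(
    system.file("extdata", "golden_perch_tags.csv", package = "tribmove",
                mustWork = TRUE),
    col_types = readr::cols(
      fish_id = readr::col_character(),
      capture_river = readr::col_character(),
      tag_year = readr::col_integer(),
      length_mm = readr::col_double(),
      weight_g = readr::col_double(),
      angler_removed = readr::col_logical()
    ))
}

#' @rdname reference_tables
#' @export
murray_model_average <- function() {
  readr::read_csv(
    system.file("extdata", "murray_model_average.csv", package = "tribmove",
                mustWork = TRUE),
    col_types = readr::cols(
      term = readr::col_character(),
      label = readr::col_character(),
      estimate = readr::col_double(),
      lower_ci = readr::col_double(),
      upper_ci = readr::col_double(),
      relative_importance = readr::col_double()
    ))
}
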