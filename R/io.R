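#' Read the pipeline's CSV interchange formats
#'
#' Four plain CSV schemas tie the stages together: a detection log
#' (`fish_id,timestamp,station_id`), station metadata
#' (`station_id,river,rkm_from_junction`), tag metadata
#' (`fish_id,capture_river,release_date,length_mm,weight_g,battery_days`
#' with an optional `removal_date`), and daily gauge series
#' (`gauge_id,river,date,flow_ml_day,temp_c`). Timestamps and dates are
#' ISO-8601; river labels are normalised case-insensitively to
#' `Goulburn`/`Murray`. Exact duplicate detection rows are dropped (receiver
#' downloads overlap), with the count recorded in the `"n_duplicates"`
#' attribute.
#'
#' @param path path to a CSV file.
#' @return a validated tibble, one row per record.
#' @name read_inputs
NULL

check_header <- function(df, expected, optional = character(), what) {
  nms <- if (is.character(df)) df else names(df)
  missing <- setdiff(expected, nms)
  extra <- setdiff(nms, c(expected, optional))
  if (length(missing) || length(extra)) {
    abort(paste0(
      "unexpected ", what, " header: expected columns {",
      paste(c(expected, optional), collapse = ","), "}",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ",")),
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ","))
    ))
  }
  invisible(df)
}

# validate the header first, then parse with the typed spec restricted to
# the columns actually present (readr warns about unmatched named parsers)
read_schema <- function(path, collectors, expected, optional = character(),
                        what) {
  hdr <- names(readr::read_csv(path, n_max = 0,
                               col_types = readr::cols(.default = "c"),
                               show_col_types = FALSE))
  check_header(hdr, expected, optional, what)
  readr::read_csv(path,
                  col_types = do.call(readr::cols, collectors[hdr]),
                  show_col_types = FALSE)
}

#' @rdname read_inputs
#' @export
read_detections <- function(path) {
  df <- read_schema(path, list(
    fish_id = readr::col_character(),
    timestamp = readr::col_datetime(),
    station_id = readr::col_character()
  ), c("fish_id", "timestamp", "station_id"), what = "detections")
  if (anyNA(df$timestamp)) {
    abort(paste0("unparseable timestamp at line(s) ",
                 paste(which(is.na(df$timestamp)) + 1L, collapse = ", ")))
  }
  n0 <- nrow(df)
  df <- dplyr::distinct(df)
  structure(dplyr::arrange(df, .data$fish_id, .data$timestamp),
            n_duplicates = n0 - nrow(df))
}

#' @rdname read_inputs
#' @export
read_stations <- function(path) {
  df <- read_schema(path, list(
    station_id = readr::col_character(),
    river = readr::col_character(),
    rkm_from_junction = readr::col_double()
  ), c("station_id", "river", "rkm_from_junction"), what = "stations")
  df$river <- normalize_river(df$river)
  df
}

#' @rdname read_inputs
#' @export
read_tags <- function(path) {
  df <- read_schema(path, list(
    fish_id = readr::col_character(),
    capture_river = readr::col_character(),
    release_date = readr::col_date(),
    length_mm = readr::col_double(),
    weight_g = readr::col_double(),
    battery_days = readr::col_integer(),
    removal_date = readr::col_date()
  ), c("fish_id", "capture_river", "release_date", "length_mm",
       "weight_g", "battery_days"),
  optional = "removal_date", what = "tags")
  if (!"removal_date" %in% names(df)) df$removal_date <- as.Date(NA)
  df$capture_river <- normalize_river(df$capture_river)
  if (any(df$battery_days <= 0)) abort("battery_days must be positive")
  bad <- !is.na(df$removal_date) & df$removal_date < df$release_date
  if (any(bad)) abort("removal_date before release_date for some fish")
  df
}

#' @rdname read_inputs
#' @export
read_environment <- function(path) {
  df <- read_schema(path, list(
    gauge_id = readr::col_character(),
    river = readr::col_character(),
    date = readr::col_date(),
    flow_ml_day = readr::col_double(),
    temp_c = readr::col_double()
  ), c("gauge_id", "river", "date", "flow_ml_day", "temp_c"),
  what = "environment")
  df$river <- normalize_river(df$river)
  validate_env(df)
  df
}

validate_env <- function(env) {
  for (r in unique(env$river)) {
    d <- sort(env$date[env$river == r])
    if (length(d) > 1 && any(diff(d) != 1)) {
      abort(paste0("gauge series for ", r, " has non-contiguous dates"))
    }
  }
  if (any(env$flow_ml_day <= 0)) abort("flow must be positive")
  if (any(!is.finite(env$temp_c))) abort("temperature must be finite")
  invisible(env)
}

#' Write a report bundle to disk
#'
#' Writes every tabular element of a [run_pipeline()] bundle as a CSV under
#' `dir`, plus a plain-text run report. Deterministic inputs give
#' byte-identical output.
#'
#' @param bundle a list as returned by [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, name) readr::write_csv(x, file.path(dir, paste0(name, ".csv")))
  wr(bundle$states, "weekly_states")
  wr(bundle$design, "design")
  wr(dplyr::select(tidy(bundle$candidates$A), -"spec"), "fits_A")
  wr(dplyr::select(tidy(bundle$candidates$B), -"spec"), "fits_B")
  wr(tidy(bundle$average$A), "model_average_A")
  wr(tidy(bundle$average$B), "model_average_B")
  wr(bundle$cohort_summary, "cohort_summary")
  wr(bundle$movement$by_river, "movement_by_river")
  wr(bundle$movement$visits, "visits")
  wr(bundle$curves, "prediction_curves")
  writeLines(c(
    sprintf("AUC (current river Murray): %.6f", bundle$auc[["A"]]),
    sprintf("AUC (current river Goulburn): %.6f", bundle$auc[["B"]]),
    sprintf("observed fish-weeks: %d", bundle$report$n_observed),
    sprintf("imputed fish-weeks: %d", bundle$report$n_imputed),
    sprintf("dropped detections: %d", bundle$report$n_dropped),
    sprintf("design rows dropped (no fortnight lead-in): %d",
            bundle$report$n_design_dropped)
  ), file.path(dir, "run_report.txt"))
  invisible(dir)
}
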