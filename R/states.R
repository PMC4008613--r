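#' Assign a river to one fish-week of detections
#'
#' The river of the chronologically last detection in the week wins; an empty
#' week returns `NA`. The last-detection rule (rather than majority vote)
#' reflects that the weekly state feeds a next-week transition, so the latest
#' known position is the natural "current location".
#'
#' @param detections detection rows for one fish and one week.
#' @param stations station metadata.
#' @return `"Goulburn"`, `"Murray"`, or `NA_character_`.
#' @export
assign_week_river <- function(detections, stations) {
  if (nrow(detections) == 0) return(NA_character_)
  idx <- match(detections$station_id, stations$station_id)
  if (anyNA(idx)) {
    abort(paste0("unknown station id(s): ",
                 paste(unique(detections$station_id[is.na(idx)]), collapse = ", ")))
  }
  ord <- order(detections$timestamp, detections$station_id)
  stations$river[idx[ord[length(ord)]]]
}

#' Classify detections into descriptive river zones
#'
#' Goulburn stations map to `Goulburn`; Murray stations within
#' `junction_radius_km` river km of the confluence (inclusive) map to
#' `junction`; other Murray stations to `Murray_beyond`.
#'
#' @param detections detection-log tibble.
#' @param stations station metadata.
#' @param junction_radius_km half-width of the junction zone, km.
#' @return a character vector, one zone per detection.
#' @export
classify_zone <- function(detections, stations, junction_radius_km = 2) {
  idx <- match(detections$station_id, stations$station_id)
  if (anyNA(idx)) {
    abort(paste0("unknown station id(s): ",
                 paste(unique(detections$station_id[is.na(idx)]), collapse = ", ")))
  }
  river <- stations$river[idx]
  rkm <- stations$rkm_from_junction[idx]
  dplyr::case_when(
    river == "Goulburn" ~ "Goulburn",
    abs(rkm) <= junction_radius_km ~ "junction",
    TRUE ~ "Murray_beyond"
  )
}

#' Reconstruct censored weekly river states from a detection log
#'
#' For each tagged fish, builds a complete weekly state series from the first
#' week after release up to the week containing
#' `min(release + battery_days, removal_date)`. A week with detections gets
#' the river of its last detection (provenance `observed`); a silent week
#' inherits the previous week's river (provenance `imputed`) — under paired
#' exit stations an unseen fish has not crossed a monitored boundary. A fish
#' never detected yields a fully imputed series at its capture river and is
#' flagged in the run report. Detections on the release day are discarded
#' (post-surgery recovery), and detections after the censoring date are
#' dropped with a warning.
#'
#' @param detections detection-log tibble.
#' @param stations station metadata.
#' @param tags tag metadata; every detected fish must appear here.
#' @param week_origin date starting analysis week 0.
#' @return a tibble `fish_id, week_index, river, provenance`, with a
#'   `"report"` attribute (counts of observed/imputed weeks, dropped
#'   detections, never-detected fish).
#' @export
build_weekly_states <- function(detections, stations, tags, week_origin) {
  week_origin <- as.Date(week_origin)
  unknown <- setdiff(detections$fish_id, tags$fish_id)
  if (length(unknown)) {
    abort(paste0("fish in detections but not in tags: ",
                 paste(unknown, collapse = ", ")))
  }
  idx <- match(detections$station_id, stations$station_id)
  if (anyNA(idx)) {
    abort(paste0("unknown station id(s): ",
                 paste(unique(detections$station_id[is.na(idx)]), collapse = ", ")))
  }
  det <- detections
  det$river <- stations$river[idx]
  det$date <- as.Date(det$timestamp, tz = "UTC")
  det <- dplyr::left_join(
    det, dplyr::select(tags, "fish_id", "release_date", "battery_days",
                       "removal_date"),
    by = "fish_id")
  det$end_date <- pmin(det$release_date + det$battery_days,
                       dplyr::coalesce(det$removal_date, as.Date("9999-12-31")))
  n_release_day <- sum(det$date == det$release_date)
  n_late <- sum(det$date > det$end_date)
  if (n_late > 0) {
    warn(paste0(n_late, " detection(s) after battery expiry or removal dropped"))
  }
  det <- det[det$date > det$release_date & det$date <= det$end_date, ]
  det$week_index <- week_index(det$date, week_origin)

  observed <- dplyr::summarise(
    dplyr::group_by(det, .data$fish_id, .data$week_index),
    river = .data$river[order(.data$timestamp, .data$station_id)][dplyr::n()],
    .groups = "drop")

  end_date <- pmin(tags$release_date + tags$battery_days,
                   dplyr::coalesce(tags$removal_date, as.Date("9999-12-31")))
  w_from <- week_index(tags$release_date, week_origin) + 1L
  w_to <- week_index(end_date, week_origin)
  frame <- purrr::map_dfr(seq_len(nrow(tags)), function(i) {
    if (w_to[i] < w_from[i]) return(NULL)
    tibble::tibble(fish_id = tags$fish_id[i],
                   week_index = seq(w_from[i], w_to[i]),
                   capture_river = tags$capture_river[i])
  })
  states <- dplyr::left_join(frame, observed, by = c("fish_id", "week_index"))
  states <- dplyr::mutate(
    dplyr::group_by(dplyr::arrange(states, .data$fish_id, .data$week_index),
                    .data$fish_id),
    provenance = ifelse(is.na(.data$river), "imputed", "observed"),
    river = locf(.data$river, .data$capture_river[1]))
  states <- dplyr::ungroup(states)
  never_detected <- setdiff(tags$fish_id, unique(det$fish_id))
  structure(
    dplyr::select(states, "fish_id", "week_index", "river", "provenance"),
    report = list(
      n_observed = sum(states$provenance == "observed"),
      n_imputed = sum(states$provenance == "imputed"),
      n_dropped = n_late,
      n_release_day_dropped = n_release_day,
      never_detected = never_detected
    ))
}

# last observation carried forward, seeded with `initial` for leading NAs
locf <- function(x, initial) {
  filled <- c(initial, x)
  idx <- cummax(seq_along(filled) * !is.na(filled))
  filled[idx][-1]
}

#' Persistence responses from a weekly state table
#'
#' For every consecutive fish-week pair (t, t+1), emits one row with
#' `current_river` = river at t and `response` = 1 if the fish is in the same
#' river at t+1, else 0. Split by `current_river` these rows are the two
#' conditional datasets behind the diagonals of the transition matrix
#' (A: currently Murray, B: currently Goulburn).
#'
#' @param states a weekly state tibble (from [build_weekly_states()] or
#'   [simulate_movement()]).
#' @return a tibble `fish_id, week_index, current_river, response`.
#' @export
persistence_response <- function(states) {
  out <- dplyr::mutate(
    dplyr::group_by(dplyr::arrange(states, .data$fish_id, .data$week_index),
                    .data$fish_id),
    next_river = dplyr::lead(.data$river),
    consecutive = dplyr::lead(.data$week_index) == .data$week_index + 1L)
  out <- dplyr::ungroup(out)
  out <- out[!is.na(out$next_river) & out$consecutive, ]
  tibble::tibble(fish_id = out$fish_id, week_index = out$week_index,
                 current_river = out$river,
                 response = as.integer(out$next_river == out$river))
}
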