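#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation: the probability that a randomly
#' chosen positive row receives a higher prediction than a randomly chosen
#' negative row, with ties counted one half. 0.5 indicates no
#' discrimination, 1.0 perfect discrimination.
#'
#' @param predicted numeric predictions (any monotone score).
#' @param observed 0/1 outcomes; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0)) # 0.75
#' @export
auc <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  observed <- as.integer(observed)
  n1 <- sum(observed == 1)
  n0 <- sum(observed == 0)
  if (n1 == 0 || n0 == 0) {
    abort("undefined AUC: both outcome classes must be present")
  }
  r <- rank(predicted, ties.method = "average")
  (sum(r[observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predicted persistence curves over a covariate grid
#'
#' Evaluates [persistence_probability()] along a grid of one covariate, one
#' curve per scenario. The default scenarios cross capture river with
#' spawning season; all other covariates sit at 0, which is "average
#' conditions" when the model was fitted on mean-centred covariates.
#'
#' @param object a fitted or averaged model (anything with `coef()`), or a
#'   named coefficient vector.
#' @param varying name of the covariate swept along the grid.
#' @param grid strictly increasing numeric grid.
#' @param scenarios a data frame of fixed covariate settings, one row per
#'   curve. Default: all four capture x spawning combinations.
#' @return a `prediction_curve` tibble: scenario columns, `varying`,
#'   `value`, `probability`.
#' @export
prediction_curve <- function(object, varying, grid,
                             scenarios = NULL) {
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("grid must be strictly increasing")
  }
  coefs <- if (is.numeric(object)) object else coef(object)
  parts <- unique(unlist(strsplit(names(coefs), ":", fixed = TRUE)))
  if (!varying %in% parts) {
    abort(paste0("unknown covariate: '", varying,
                 "' is not a term or constituent of the model"))
  }
  if (is.null(scenarios)) {
    scenarios <- tidyr::expand_grid(capture_murray = c(0L, 1L),
                                    spawning = c(0L, 1L))
    scenarios <- scenarios[names(scenarios) %in% parts]
    if (ncol(scenarios) == 0) scenarios <- tibble::tibble(.rows = 1)
  }
  out <- purrr::map_dfr(seq_len(nrow(scenarios)), function(i) {
    fixed <- as.list(scenarios[i, , drop = FALSE])
    p <- vapply(grid, function(v) {
      vals <- fixed
      vals[[varying]] <- v
      persistence_probability(coefs, vals)
    }, numeric(1))
    dplyr::bind_cols(scenarios[i, , drop = FALSE],
                     tibble::tibble(varying = varying, value = grid,
                                    probability = p))
  })
  class(out) <- c("prediction_curve", class(out))
  out
}

#' Summarise the tagged cohort
#'
#' Per capture river and overall: fish count, mean and standard error
#' (sample sd / sqrt(n)) of length and weight, and ranges. With a single
#' fish the SE is reported as `NA`.
#'
#' @param tags tag-metadata tibble (needs `capture_river`, `length_mm`,
#'   `weight_g`).
#' @return a tibble with one row per river plus an `Overall` row.
#' @export
cohort_summary <- function(tags) {
  if (nrow(tags) == 0) abort("no data: empty tag table")
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  one <- function(df, label) {
    tibble::tibble(
      group = label, n = nrow(df),
      mean_length = mean(df$length_mm), se_length = se(df$length_mm),
      min_length = min(df$length_mm), max_length = max(df$length_mm),
      mean_weight = mean(df$weight_g), se_weight = se(df$weight_g),
      min_weight = min(df$weight_g), max_weight = max(df$weight_g))
  }
  dplyr::bind_rows(
    purrr::map_dfr(split(tags, tags$capture_river),
                   ~ one(.x, .x$capture_river[1])),
    one(tags, "Overall"))
}

#' Summarise mainstem-tributary movement
#'
#' From a weekly state table: per capture river, how many fish ever occupied
#' the other river; per excursion ("visit" = maximal run of consecutive
#' weeks in the non-capture river), its duration and whether the fish later
#' returned to its capture river; and the monthly distribution of
#' river-switch events.
#'
#' @param states weekly state tibble.
#' @param tags tag metadata.
#' @param week_origin date starting week 0 (for the monthly switch
#'   distribution).
#' @return a list of tibbles: `by_river`, `visits`, `per_fish`,
#'   `switches_by_month`.
#' @export
movement_summary <- function(states, tags, week_origin) {
  st <- dplyr::inner_join(
    dplyr::arrange(states, .data$fish_id, .data$week_index),
    dplyr::select(tags, "fish_id", "capture_river"), by = "fish_id")
  per_fish <- dplyr::summarise(
    dplyr::group_by(st, .data$fish_id, .data$capture_river),
    moved = any(.data$river != .data$capture_river), .groups = "drop")
  by_river <- dplyr::summarise(
    dplyr::group_by(per_fish, .data$capture_river),
    n_fish = dplyr::n(), n_movers = sum(.data$moved),
    pct_movers = 100 * mean(.data$moved), .groups = "drop")

  visits <- purrr::map_dfr(split(st, st$fish_id), function(d) {
    r <- rle(d$river)
    away <- which(r$values != d$capture_river[1])
    if (!length(away)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tibble::tibble(
      fish_id = d$fish_id[1], capture_river = d$capture_river[1],
      start_week = d$week_index[starts[away]],
      duration_weeks = r$lengths[away],
      returned = ends[away] < nrow(d))
  })
  per_fish_visits <- if (nrow(visits)) {
    dplyr::summarise(dplyr::group_by(visits, .data$fish_id),
                     n_visits = dplyr::n(),
                     ever_returned = any(.data$returned), .groups = "drop")
  } else {
    tibble::tibble(fish_id = character(), n_visits = integer(),
                   ever_returned = logical())
  }

  switches <- dplyr::mutate(
    dplyr::group_by(st, .data$fish_id),
    switch = .data$river != dplyr::lag(.data$river))
  switches <- dplyr::ungroup(switches)
  switches <- switches[!is.na(switches$switch) & switches$switch, ]
  switches_by_month <- dplyr::count(
    dplyr::mutate(switches, month = as.integer(format(
      week_midpoint(.data$week_index, as.Date(week_origin)), "%m"))),
    .data$month, name = "n_switches")

  list(by_river = by_river, visits = visits, per_fish = per_fish_visits,
       switches_by_month = switches_by_month)
}
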