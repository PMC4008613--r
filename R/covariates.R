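#' Weekly and fortnight environmental covariates
#'
#' The transition models use eight explanatory variables per fish-week; the
#' six continuous ones are windowed summaries of the daily gauge series of
#' the river the fish currently occupies:
#' \itemize{
#'   \item `weekly_mean()`: arithmetic mean flow (ML/day) and water
#'     temperature (deg C) over the week's 7 calendar days;
#'   \item `pct_change_fortnight()`: (current-week mean - previous-fortnight
#'     mean) / previous-fortnight mean, a dimensionless proportion (0.10 is a
#'     10\% rise). The previous fortnight is the 14 calendar days strictly
#'     before the week's first day;
#'   \item `cv_fortnight()`: sample (n-1) standard deviation / mean of the
#'     previous fortnight's 14 daily values.
#' }
#'
#' @param series daily gauge series for one river (columns `date`,
#'   `flow_ml_day`, `temp_c`).
#' @param week integer analysis week index.
#' @param week_origin date starting week 0.
#' @param var which series to summarise, `"flow"` or `"temp"`.
#' @return `weekly_mean()`: a named list `mean_flow`, `mean_temp`; the others
#'   a single number.
#' @name env_covariates
NULL

window_values <- function(series, from, to, what) {
  days <- seq(from, to, by = "day")
  idx <- match(days, series$date)
  if (anyNA(idx)) {
    abort(paste0("missing gauge days: ",
                 paste(format(days[is.na(idx)]), collapse = ", ")))
  }
  series[[what]][idx]
}

#' @rdname env_covariates
#' @export
weekly_mean <- function(series, week, week_origin) {
  from <- week_start(week, week_origin)
  list(mean_flow = mean(window_values(series, from, from + 6L, "flow_ml_day")),
       mean_temp = mean(window_values(series, from, from + 6L, "temp_c")))
}

fortnight_window <- function(series, week, week_origin, var) {
  col <- switch(var, flow = "flow_ml_day", temp = "temp_c",
                abort("var must be 'flow' or 'temp'"))
  from <- week_start(week, week_origin)
  window_values(series, from - 14L, from - 1L, col)
}

#' @rdname env_covariates
#' @export
pct_change_fortnight <- function(series, week, week_origin, var = "flow") {
  prev <- mean(fortnight_window(series, week, week_origin, var))
  if (prev == 0) abort("undefined covariate: previous-fortnight mean is zero")
  col <- if (var == "flow") "flow_ml_day" else "temp_c"
  from <- week_start(week, week_origin)
  cur <- mean(window_values(series, from, from + 6L, col))
  (cur - prev) / prev
}

#' @rdname env_covariates
#' @export
cv_fortnight <- function(series, week, week_origin, var = "flow") {
  x <- fortnight_window(series, week, week_origin, var)
  m <- mean(x)
  if (m == 0) abort("undefined covariate: previous-fortnight mean is zero")
  sd(x) / m
}

#' Spawning-season indicator for an analysis week
#'
#' TRUE when the week's midpoint date falls in the September-February
#' spawning season of golden perch (the midpoint rule decides weeks that
#' straddle a season boundary).
#'
#' @inheritParams env_covariates
#' @param months integer months making up the spawning season.
#' @return logical.
#' @export
spawning_flag <- function(week, week_origin, months = c(9:12, 1:2)) {
  as.integer(format(week_midpoint(week, week_origin), "%m")) %in% months
}

#' All weekly covariates for each river's gauge
#'
#' Computes the six continuous covariates plus the spawning flag for every
#' requested week and every river present in `env`. Weeks whose 7 days or
#' 14-day lead-in extend beyond the series are returned as `NA` rather than
#' an error, so callers can drop and count them.
#'
#' @param env daily gauge series (both rivers).
#' @param weeks integer week indices.
#' @param week_origin date starting week 0.
#' @return a tibble with one row per river-week.
#' @export
weekly_env_covariates <- function(env, weeks, week_origin) {
  week_origin <- as.Date(week_origin)
  # windowed sums via cumulative series: equivalent to the per-week
  # functions above, but one pass per gauge
  purrr::map_dfr(split(env, env$river), function(series) {
    series <- dplyr::arrange(series, .data$date)
    n <- nrow(series)
    win <- function(x) {
      C <- c(0, cumsum(x))
      C2 <- c(0, cumsum(x^2))
      list(C = C, C2 = C2)
    }
    fl <- win(series$flow_ml_day)
    tp <- win(series$temp_c)
    # s = 1-based position of the week's first day in the series
    s <- as.numeric(week_start(weeks, week_origin) - series$date[1]) + 1
    ok <- s - 14 >= 1 & s + 6 <= n
    stat <- function(z, s) {
      wk_mean <- (z$C[s + 7] - z$C[s]) / 7
      fn_sum <- z$C[s] - z$C[s - 14]
      fn_mean <- fn_sum / 14
      fn_var <- (z$C2[s] - z$C2[s - 14] - fn_sum^2 / 14) / 13
      fn_sd <- sqrt(pmax(fn_var, 0))
      list(mean = wk_mean, pct = (wk_mean - fn_mean) / fn_mean,
           cv = fn_sd / fn_mean)
    }
    out <- tibble::tibble(
      river = series$river[1], week_index = weeks,
      spawning = spawning_flag(weeks, week_origin),
      mean_flow = NA_real_, mean_temp = NA_real_,
      pct_change_flow = NA_real_, cv_flow = NA_real_,
      pct_change_temp = NA_real_, cv_temp = NA_real_)
    if (any(ok)) {
      f <- stat(fl, s[ok])
      t <- stat(tp, s[ok])
      out$mean_flow[ok] <- f$mean
      out$pct_change_flow[ok] <- f$pct
      out$cv_flow[ok] <- f$cv
      out$mean_temp[ok] <- t$mean
      out$pct_change_temp[ok] <- t$pct
      out$cv_temp[ok] <- t$cv
    }
    out
  })
}

#' Build the fish-week design table for the transition models
#'
#' Joins the persistence responses from [persistence_response()] to the
#' weekly covariates of each row's *current* river, and adds the
#' capture-river indicator (`capture_murray`, 1 = tagged in the Murray).
#' Rows whose 14-day fortnight lead-in is not covered by the gauge series
#' are dropped; their count is stored in the `"n_dropped"` attribute.
#' Split by `current_river`, the table yields the two conditional datasets:
#' diagonal A (currently Murray) and diagonal B (currently Goulburn); see
#' [split_diagonals()].
#'
#' @param response_table output of [persistence_response()].
#' @param env daily gauge series for both rivers.
#' @param tags tag metadata.
#' @param week_origin date starting week 0.
#' @param centre if TRUE, mean-centre the six continuous covariates on this
#'   dataset (means stored in the `"centres"` attribute), so covariate value
#'   0 means "average conditions".
#' @return a design tibble, one row per fish-week transition.
#' @export
build_design <- function(response_table, env, tags, week_origin,
                         centre = FALSE) {
  if (!all(.rivers %in% unique(env$river))) {
    abort("missing gauge: need one daily series per river")
  }
  weeks <- sort(unique(response_table$week_index))
  cov <- weekly_env_covariates(env, weeks, week_origin)
  design <- dplyr::inner_join(response_table, cov,
                              by = c(current_river = "river", "week_index"))
  design <- dplyr::left_join(
    design, dplyr::select(tags, "fish_id", "capture_river"), by = "fish_id")
  design$capture_murray <- as.integer(design$capture_river == "Murray")
  design$spawning <- as.integer(design$spawning)
  n0 <- nrow(design)
  design <- tidyr::drop_na(design, "mean_flow")
  centres <- NULL
  if (centre) {
    cont <- c("mean_flow", "mean_temp", "pct_change_flow", "cv_flow",
              "pct_change_temp", "cv_temp")
    centres <- vapply(design[cont], mean, numeric(1))
    design[cont] <- purrr::map2(design[cont], centres, `-`)
  }
  structure(
    dplyr::select(design, "fish_id", "week_index", "current_river",
                  "capture_river", "capture_murray", "spawning", "response",
                  "mean_flow", "mean_temp", "pct_change_flow", "cv_flow",
                  "pct_change_temp", "cv_temp"),
    n_dropped = n0 - nrow(design), centres = centres)
}

#' @rdname build_design
#' @param design a design tibble.
#' @return `split_diagonals()`: a named list `A` (current river Murray) and
#'   `B` (current river Goulburn).
#' @export
split_diagonals <- function(design) {
  list(A = design[design$current_river == "Murray", ],
       B = design[design$current_river == "Goulburn", ])
}
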