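#' Configuration for the synthetic gauge-series generator
#'
#' Daily flow is a seasonal sinusoid (peaking in early spring, Southern
#' Hemisphere) multiplied by Poisson-timed freshes — short within-channel
#' pulses that jump to `fresh_magnitude` times the ambient flow and decay
#' exponentially with time constant `fresh_decay_days` — and by multiplicative
#' lognormal noise with coefficient of variation `flow_noise_cv`. Daily water
#' temperature is an annual sinusoid peaking in late January plus Gaussian
#' noise. Defaults give a mid-sized regulated lowland river: base flow
#' 5000 ML/day with a 3000 ML/day seasonal swing, ~6 freshes/year, water
#' temperature 15 +/- 8 deg C, and a series long enough (1750 days from
#' January 2007) to cover the last tagging cohort's transmitter life.
#'
#' @param start_date first day of the series.
#' @param n_days series length in days (>= 28, so fortnight windows exist).
#' @param base_flow mean annual flow, ML/day.
#' @param seasonal_flow_amplitude seasonal swing about `base_flow`, ML/day
#'   (must be `< base_flow` so flow stays positive).
#' @param fresh_rate expected freshes per year.
#' @param fresh_magnitude peak multiplicative factor of a fresh (> 1).
#' @param fresh_decay_days e-folding time of a fresh, days.
#' @param temp_mean,temp_amplitude annual mean and seasonal amplitude, deg C.
#' @param temp_noise_sd daily temperature noise SD, deg C.
#' @param flow_noise_cv coefficient of variation of the lognormal flow noise.
#' @param seed integer seed; identical seeds give identical series.
#' @return an `env_config` list.
#' @export
env_config <- function(start_date = as.Date("2007-01-01"),
                       n_days = 1750L,
                       base_flow = 5000,
                       seasonal_flow_amplitude = 3000,
                       fresh_rate = 6,
                       fresh_magnitude = 3,
                       fresh_decay_days = 10,
                       temp_mean = 15,
                       temp_amplitude = 8,
                       temp_noise_sd = 0.6,
                       flow_noise_cv = 0.15,
                       seed = 1L) {
  cfg <- list(start_date = as.Date(start_date), n_days = as.integer(n_days),
              base_flow = base_flow,
              seasonal_flow_amplitude = seasonal_flow_amplitude,
              fresh_rate = fresh_rate, fresh_magnitude = fresh_magnitude,
              fresh_decay_days = fresh_decay_days, temp_mean = temp_mean,
              temp_amplitude = temp_amplitude, temp_noise_sd = temp_noise_sd,
              flow_noise_cv = flow_noise_cv, seed = as.integer(seed))
  if (cfg$n_days < 28L) abort("invalid configuration: n_days must be >= 28")
  if (cfg$base_flow <= 0) abort("invalid configuration: base_flow must be positive")
  if (cfg$seasonal_flow_amplitude < 0 || cfg$seasonal_flow_amplitude >= cfg$base_flow)
    abort("invalid configuration: seasonal_flow_amplitude must be in [0, base_flow)")
  if (cfg$fresh_magnitude <= 1) abort("invalid configuration: fresh_magnitude must exceed 1")
  if (cfg$fresh_decay_days <= 0) abort("invalid configuration: fresh_decay_days must be positive")
  structure(cfg, class = "env_config")
}

day_of_year <- function(date) as.numeric(format(date, "%j"))

simulate_gauge <- function(cfg, gauge_id, river) {
  date <- cfg$start_date + seq_len(cfg$n_days) - 1L
  doy <- day_of_year(date)
  # high flow centred on early September (day 245), high temperature on
  # late January (day 28): Southern Hemisphere seasonality
  flow <- cfg$base_flow +
    cfg$seasonal_flow_amplitude * cos(2 * pi * (doy - 245) / 365.25)
  n_fresh <- rpois(1L, cfg$fresh_rate * cfg$n_days / 365.25)
  fresh_days <- sort(runif(n_fresh, 1, cfg$n_days))
  t <- seq_len(cfg$n_days)
  for (t0 in fresh_days) {
    dt <- t - t0
    flow <- flow * (1 + (cfg$fresh_magnitude - 1) *
                      ifelse(dt >= 0, exp(-dt / cfg$fresh_decay_days), 0))
  }
  if (cfg$flow_noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$flow_noise_cv^2))
    flow <- flow * rlnorm(cfg$n_days, -sdlog^2 / 2, sdlog)
  }
  temp <- cfg$temp_mean +
    cfg$temp_amplitude * cos(2 * pi * (doy - 28) / 365.25) +
    rnorm(cfg$n_days, 0, cfg$temp_noise_sd)
  tibble::tibble(gauge_id = gauge_id, river = river, date = date,
                 flow_ml_day = flow, temp_c = temp)
}

#' Simulate daily gauge series for the two rivers
#'
#' Generates one daily flow/temperature series per river (mainstem Murray and
#' tributary Goulburn gauges) from a shared [env_config()], with independent
#' fresh timings and noise per gauge.
#'
#' @param config an [env_config()].
#' @return a tibble with columns `gauge_id, river, date, flow_ml_day, temp_c`,
#'   `2 * n_days` rows.
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "env_config"))
  set.seed(config$seed)
  env <- dplyr::bind_rows(
    simulate_gauge(config, "MURRAY_GAUGE", "Murray"),
    simulate_gauge(config, "GOULBURN_GAUGE", "Goulburn")
  )
  validate_env(env)
  env
}

#' Configuration for the synthetic tagged cohort
#'
#' Emulates a three-cohort autumn tagging design: adult fish tagged each
#' April in two rivers, transmitter battery life fixed per cohort
#' (611/660/880 days for the 2007/2008/2009 cohorts), lengths from a
#' truncated normal, weight allometric in length, and occasional permanent
#' removals by anglers.
#'
#' @param n_murray,n_goulburn fish tagged per release cohort in each river.
#' @param release_dates one date per cohort (April releases).
#' @param battery_days one transmitter battery life per cohort, days.
#' @param length_mean,length_sd,length_min truncated-normal length
#'   distribution, mm.
#' @param detection_prob_per_week probability in (0, 1] that a fish present
#'   in a monitored river is logged at least once in a week.
#' @param angler_removal_rate per-fish per-year probability of capture and
#'   removal by an angler.
#' @param seed integer seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_murray = c(15L, 14L, 13L),
                          n_goulburn = c(12L, 11L, 14L),
                          release_dates = as.Date(c("2007-04-15",
                                                    "2008-04-15",
                                                    "2009-04-15")),
                          battery_days = c(611L, 660L, 880L),
                          length_mean = 430, length_sd = 55, length_min = 315,
                          detection_prob_per_week = 0.9,
                          angler_removal_rate = 0.04,
                          seed = 1L) {
  release_dates <- as.Date(release_dates)
  if (length(release_dates) == 0) abort("invalid configuration: no release dates")
  if (length(n_murray) != length(release_dates) ||
      length(n_goulburn) != length(release_dates) ||
      length(battery_days) != length(release_dates))
    abort("invalid configuration: per-cohort vectors must match release_dates")
  if (any(battery_days <= 0)) abort("invalid configuration: battery_days must be positive")
  if (detection_prob_per_week <= 0 || detection_prob_per_week > 1)
    abort("invalid configuration: detection_prob_per_week must be in (0, 1]")
  structure(list(n_murray = as.integer(n_murray),
                 n_goulburn = as.integer(n_goulburn),
                 release_dates = release_dates,
                 battery_days = as.integer(battery_days),
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = length_min,
                 detection_prob_per_week = detection_prob_per_week,
                 angler_removal_rate = angler_removal_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate the tag-metadata table
#'
#' One row per tagged fish: id, capture river, release date, length (mm),
#' allometric weight (g, W = a L^b with b = 3.1 and lognormal scatter),
#' transmitter battery life, and an angler removal date for the randomly
#' removed subset.
#'
#' @param config a [cohort_config()].
#' @return a tibble in the tag-metadata schema of [read_tags()].
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  rows <- purrr::map(seq_along(config$release_dates), function(i) {
    n <- c(config$n_murray[i], config$n_goulburn[i])
    tibble::tibble(
      capture_river = rep(c("Murray", "Goulburn"), n),
      release_date = config$release_dates[i],
      battery_days = config$battery_days[i]
    )
  })
  tags <- dplyr::bind_rows(rows)
  tags <- dplyr::mutate(
    dplyr::group_by(tags, .data$capture_river),
    fish_id = sprintf("%s%02d", substr(.data$capture_river[1], 1, 1),
                      dplyr::row_number())
  )
  tags <- dplyr::ungroup(tags)
  n <- nrow(tags)
  tags$length_mm <- round(rtrunc_norm(n, config$length_mean, config$length_sd,
                                      config$length_min))
  # allometry calibrated so a 430 mm fish weighs ~1.5 kg
  a <- 1500 / 430^3.1
  tags$weight_g <- round(a * tags$length_mm^3.1 * rlnorm(n, 0, 0.12))
  p_rem <- 1 - (1 - config$angler_removal_rate)^(tags$battery_days / 365.25)
  removed <- runif(n) < p_rem
  tags$removal_date <- as.Date(ifelse(
    removed,
    tags$release_date + round(runif(n, 30, tags$battery_days - 1)),
    NA
  ), origin = "1970-01-01")
  dplyr::select(tags, "fish_id", "capture_river", "release_date",
                "length_mm", "weight_g", "battery_days", "removal_date")
}

#' Specify the transition model that generates synthetic movement
#'
#' A truth model holds one linear predictor per diagonal of the weekly
#' transition matrix: `terms_G` for persistence in the Goulburn and `terms_M`
#' for persistence in the Murray. Each is a named numeric vector over the
#' covariate vocabulary (`intercept`, `capture_murray`, `spawning`,
#' `mean_flow`, `mean_temp`, `pct_change_flow`, `cv_flow`, `pct_change_temp`,
#' `cv_temp`, and `:`-joined interactions of these).
#'
#' @param terms_G,terms_M named numeric coefficient vectors.
#' @return a `truth_model` list.
#' @examples
#' truth_model(c(intercept = 1.8, capture_murray = 3, spawning = 2.9,
#'               pct_change_flow = -1.7))
#' @export
truth_model <- function(terms_G, terms_M = terms_G) {
  stopifnot(is.numeric(terms_G), !is.null(names(terms_G)),
            is.numeric(terms_M), !is.null(names(terms_M)))
  if (any(!is.finite(terms_G)) || any(!is.finite(terms_M)))
    abort("truth-model coefficients must be finite")
  structure(list(terms_G = terms_G, terms_M = terms_M), class = "truth_model")
}

# evaluate a named coefficient vector on one row of base covariate values;
# interaction terms are products of their `:`-separated components
eval_linear_predictor <- function(coefficients, values) {
  values <- c(as.list(values), list(intercept = 1))
  total <- 0
  for (term in names(coefficients)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    parts[parts %in% c("(Intercept)", "1")] <- "intercept"
    missing <- setdiff(parts, names(values))
    if (length(missing)) {
      abort(paste0("unknown term component(s): ", paste(missing, collapse = ", ")))
    }
    total <- total + coefficients[[term]] *
      prod(vapply(parts, function(p) as.numeric(values[[p]]), numeric(1)))
  }
  unname(total)
}

# per-week linear predictor for one river's gauge, for both capture classes;
# returns a matrix [week, capture_murray in 0/1]
truth_eta_matrix <- function(coefficients, weekly_cov) {
  vapply(c(0, 1), function(cap) {
    vapply(seq_len(nrow(weekly_cov)), function(i) {
      vals <- as.list(weekly_cov[i, ])
      vals$capture_murray <- cap
      eval_linear_predictor(coefficients, vals)
    }, numeric(1))
  }, numeric(nrow(weekly_cov)))
}

#' Simulate true weekly movement as a two-state Markov chain
#'
#' Each fish starts in its capture river on the first analysis week after
#' release and each week persists in its current river with probability
#' `plogis(eta)`, where `eta` is the truth model's linear predictor for that
#' river evaluated on that week's covariates from the currently occupied
#' river's gauge; otherwise it switches. The chain runs until the week
#' containing battery expiry.
#'
#' @param truth a [truth_model()].
#' @param env daily gauge series covering all fish-weeks plus a 14-day
#'   lead-in (as from [simulate_environment()]).
#' @param tags tag metadata (as from [simulate_cohort()]).
#' @param week_origin date starting analysis week 0.
#' @param seed integer seed.
#' @return a tibble `fish_id, week_index, river` of true states.
#' @export
simulate_movement <- function(truth, env, tags, week_origin, seed = 1L) {
  stopifnot(inherits(truth, "truth_model"))
  week_origin <- as.Date(week_origin)
  set.seed(seed)
  w_from <- week_index(tags$release_date, week_origin) + 1L
  w_to <- week_index(tags$release_date + tags$battery_days, week_origin)
  weeks <- seq(min(w_from), max(w_to))
  cov <- weekly_env_covariates(env, weeks, week_origin)
  cov <- tidyr::drop_na(cov)
  have <- split(cov$week_index, cov$river)
  needed <- setdiff(weeks, intersect(have$Murray, have$Goulburn))
  if (length(needed)) {
    abort(paste0("gauge series do not cover analysis weeks ",
                 paste(range(needed), collapse = ".."),
                 " (including the 14-day lead-in)"))
  }
  cov_split <- split(cov, cov$river)
  eta <- list(
    Goulburn = truth_eta_matrix(truth$terms_G, cov_split$Goulburn),
    Murray = truth_eta_matrix(truth$terms_M, cov_split$Murray)
  )
  widx <- lapply(cov_split, function(d) match(weeks, d$week_index))

  n <- nrow(tags)
  cap <- as.integer(tags$capture_river == "Murray")
  state <- matrix(NA_character_, n, length(weeks))
  current <- tags$capture_river
  for (j in seq_along(weeks)) {
    w <- weeks[j]
    alive <- w_from <= w & w <= w_to
    entering <- alive & w_from == w
    current[entering] <- tags$capture_river[entering]
    state[alive, j] <- current[alive]
    if (j == length(weeks)) break
    stepping <- alive & w < w_to
    if (!any(stepping)) next
    p <- numeric(n)
    for (r in .rivers) {
      sel <- stepping & current == r
      if (!any(sel)) next
      p[sel] <- plogis(eta[[r]][widx[[r]][j], cap[sel] + 1L])
    }
    u <- runif(n)
    switch_now <- stepping & u >= p
    current[switch_now] <- other_river(current[switch_now])
  }
  out <- tibble::tibble(
    fish_id = rep(tags$fish_id, each = length(weeks)),
    week_index = rep(weeks, n),
    river = as.vector(t(state))
  )
  tidyr::drop_na(out, "river")
}

#' Simulate an imperfect detection log from true states
#'
#' For each fish-week, with probability `detection_prob_per_week` the fish is
#' logged 1-3 times at a randomly chosen station in its occupied river, at
#' random times within the week. No records are emitted after battery expiry
#' or an angler removal date.
#'
#' @param true_states tibble from [simulate_movement()].
#' @param stations station metadata; every river needs at least one station.
#' @param tags tag metadata.
#' @param detection_prob_per_week probability in (0, 1].
#' @param week_origin date starting analysis week 0.
#' @param seed integer seed.
#' @return a detection-log tibble (`fish_id, timestamp, station_id`).
#' @export
simulate_detections <- function(true_states, stations, tags,
                                detection_prob_per_week = 0.9,
                                week_origin, seed = 1L) {
  week_origin <- as.Date(week_origin)
  if (!all(.rivers %in% stations$river)) {
    abort("each river needs at least one station")
  }
  set.seed(seed)
  stn <- split(stations$station_id, stations$river)
  st <- dplyr::inner_join(true_states, tags, by = "fish_id")
  end_date <- pmin(st$release_date + st$battery_days,
                   dplyr::coalesce(st$removal_date, as.Date("9999-12-31")))
  from <- week_start(st$week_index, week_origin)
  to <- pmin(from + 6L, end_date)
  keep <- runif(nrow(st)) < detection_prob_per_week & from <= to
  st <- st[keep, ]; from <- from[keep]; to <- to[keep]
  n_det <- sample(1:3, nrow(st), replace = TRUE)
  out <- tibble::tibble(
    fish_id = rep(st$fish_id, n_det),
    river = rep(st$river, n_det),
    day = rep(from, n_det) +
      floor(runif(sum(n_det)) * (rep(as.numeric(to - from), n_det) + 1)),
    secs = round(runif(sum(n_det), 0, 86399))
  )
  out$timestamp <- as.POSIXct(out$day, tz = "UTC") + out$secs
  out$station_id <- vapply(out$river, function(r) {
    ids <- stn[[r]]
    ids[sample.int(length(ids), 1L)]
  }, character(1))
  out <- dplyr::arrange(out, .data$fish_id, .data$timestamp)
  dplyr::select(out, "fish_id", "timestamp", "station_id")
}

#' Default paired-station layout for simulations
#'
#' Twelve listening stations mirroring the study design: eight in the Murray
#' mainstem (paired up- and downstream of the junction, two pairs inside the
#' 2 km junction zone) and four in the lower Goulburn. Distances are signed
#' river km from the confluence (negative = downstream along the Murray).
#'
#' @return a station-metadata tibble.
#' @export
station_layout <- function() {
  tibble::tibble(
    station_id = c(sprintf("MUR%02d", 1:8), sprintf("GOU%02d", 1:4)),
    river = rep(c("Murray", "Goulburn"), c(8, 4)),
    rkm_from_junction = c(-22, -12, -2, -1.2, 1.2, 2, 12, 22, 1.5, 3, 4.5, 6)
  )
}
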