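# shared fixtures: all built in code, sized for fast tests

MONDAY <- as.Date("2007-01-01") # a Monday; week origin for every test

# constant-environment gauge pair: flow/temperature flat at given values
constant_env <- function(n_days = 400, start = MONDAY,
                         flow = c(Murray = 1000, Goulburn = 1000),
                         temp = c(Murray = 15, Goulburn = 15)) {
  dates <- start + seq_len(n_days) - 1L
  dplyr::bind_rows(lapply(c("Murray", "Goulburn"), function(r) {
    tibble::tibble(gauge_id = paste0(toupper(r), "_G"), river = r,
                   date = dates, flow_ml_day = flow[[r]], temp_c = temp[[r]])
  }))
}

# deterministic mini station set: one junction + one distant Murray station,
# two Goulburn stations
mini_stations <- function() {
  tibble::tibble(
    station_id = c("M_JUNC", "M_FAR", "G_LOW", "G_UP"),
    river = c("Murray", "Murray", "Goulburn", "Goulburn"),
    rkm_from_junction = c(1.5, 8, 1.5, 4))
}

mini_tags <- function(release = as.Date("2007-04-15"), battery = 611L) {
  tibble::tibble(
    fish_id = c("F1", "F2"),
    capture_river = c("Goulburn", "Murray"),
    release_date = release, length_mm = c(420, 455), weight_g = c(1300, 1600),
    battery_days = battery, removal_date = as.Date(NA))
}

det_row <- function(fish, date, station, hour = 12) {
  tibble::tibble(fish_id = fish,
                 timestamp = as.POSIXct(paste0(date, " ", hour, ":00:00"),
                                        tz = "UTC"),
                 station_id = station)
}

# design tibble with iid covariates and a known logistic response
random_design <- function(n, beta, seed = 1,
                          current_river = "Goulburn") {
  set.seed(seed)
  d <- tibble::tibble(
    fish_id = paste0("F", seq_len(n)), week_index = seq_len(n),
    current_river = current_river,
    capture_river = sample(c("Murray", "Goulburn"), n, replace = TRUE),
    spawning = sample(0:1, n, replace = TRUE),
    mean_flow = runif(n, 500, 5000), mean_temp = runif(n, 8, 25),
    pct_change_flow = rnorm(n, 0, 0.3), cv_flow = abs(rnorm(n, 0.1, 0.05)),
    pct_change_temp = rnorm(n, 0, 0.1), cv_temp = abs(rnorm(n, 0.05, 0.02)))
  d$capture_murray <- as.integer(d$capture_river == "Murray")
  eta <- vapply(seq_len(n), function(i)
    tribmove:::eval_linear_predictor(beta, as.list(d[i, ])), numeric(1))
  d$response <- as.integer(runif(n) < plogis(eta))
  d
}
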