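test_that("noise-free environment is the pure seasonal sinusoid", {
  cfg <- env_config(n_days = 365, fresh_rate = 0, flow_noise_cv = 0,
                    temp_noise_sd = 0, temp_mean = 15, temp_amplitude = 8,
                    seed = 3)
  env <- simulate_environment(cfg)
  mur <- env[env$river == "Murray", ]
  expect_equal(min(mur$temp_c), 7, tolerance = 0.01)
  expect_equal(max(mur$temp_c), 23, tolerance = 0.01)
  expect_true(all(env$flow_ml_day > 0))
  # away from the seasonal extremes the fortnight CV of noise-free flow is ~0
  cv_mid <- cv_fortnight(mur, week = 10, week_origin = MONDAY)
  expect_lt(cv_mid, 0.05)
})

test_that("environment generation is deterministic given the seed", {
  cfg <- env_config(n_days = 120, seed = 11)
  expect_identical(simulate_environment(cfg), simulate_environment(cfg))
  cfg2 <- env_config(n_days = 120, seed = 12)
  expect_false(identical(simulate_environment(cfg), simulate_environment(cfg2)))
})

test_that("invalid environment configurations are rejected", {
  expect_error(env_config(n_days = 10), "n_days")
  expect_error(env_config(base_flow = -5), "base_flow")
  expect_error(env_config(seasonal_flow_amplitude = 9000, base_flow = 5000),
               "amplitude")
})

test_that("cohort generation honours sizes, truncation and removal settings", {
  cfg <- cohort_config(n_murray = 15L, n_goulburn = 12L,
                       release_dates = as.Date("2007-04-15"),
                       battery_days = 611L,
                       length_mean = 430, length_sd = 55, length_min = 315,
                       angler_removal_rate = 0, seed = 5)
  tags <- simulate_cohort(cfg)
  expect_equal(nrow(tags), 27)
  expect_equal(sum(tags$capture_river == "Murray"), 15)
  expect_true(all(tags$length_mm >= 315))
  expect_true(all(is.na(tags$removal_date)))
  expect_identical(tags, simulate_cohort(cfg))
  expect_error(cohort_config(release_dates = as.Date(character())),
               "release dates")
})

test_that("a strongly persistent truth model produces no switches", {
  env <- constant_env(n_days = 200)
  tags <- mini_tags(release = MONDAY + 20, battery = 140L)
  tm <- truth_model(c(intercept = 20))
  st <- simulate_movement(tm, env, tags, MONDAY, seed = 2)
  expect_equal(dplyr::n_distinct(st$river[st$fish_id == "F1"]), 1)
  expect_equal(st$river[st$fish_id == "F1"][1], "Goulburn")
  expect_equal(st$river[st$fish_id == "F2"][1], "Murray")
})

test_that("unresolvable truth terms are reported by name", {
  env <- constant_env(n_days = 100)
  tags <- mini_tags(release = MONDAY + 20, battery = 50L)
  tm <- truth_model(c(intercept = 1, nonsense_term = 2))
  expect_error(simulate_movement(tm, env, tags, MONDAY, seed = 1),
               "nonsense_term")
})

test_that("constant persistence probabilities reach the two-state stationary distribution", {
  # p_G = 0.7, p_M = 0.9 -> long-run occupancy of the Goulburn
  # (1 - 0.9)/((1 - 0.7) + (1 - 0.9)) = 0.25
  env <- constant_env(n_days = 400 * 7 + 40)
  n_side <- 250L
  tags <- tibble::tibble(
    fish_id = sprintf("F%03d", 1:(2 * n_side)),
    capture_river = rep(c("Murray", "Goulburn"), each = n_side),
    release_date = MONDAY + 14, length_mm = 430, weight_g = 1500,
    battery_days = 400L * 7L + 3L, removal_date = as.Date(NA))
  tm <- truth_model(terms_G = c(intercept = qlogis(0.7)),
                    terms_M = c(intercept = qlogis(0.9)))
  st <- simulate_movement(tm, env, tags, MONDAY, seed = 9)
  # drop a short burn-in so the initial 50/50 split has washed out
  st <- st[st$week_index > min(st$week_index) + 19, ]
  per_fish <- tapply(st$river == "Goulburn", st$fish_id, mean)
  occ <- mean(per_fish)
  mc_se <- sd(per_fish) / sqrt(length(per_fish))
  expect_lt(abs(occ - 0.25), 3 * mc_se)
})

test_that("switching concentrates in weeks with rising flow under a negative flow-change effect", {
  cfg <- env_config(n_days = 800, fresh_rate = 10, fresh_magnitude = 4,
                    flow_noise_cv = 0.05, seed = 21)
  env <- simulate_environment(cfg)
  tags <- tibble::tibble(
    fish_id = sprintf("F%03d", 1:200),
    capture_river = rep(c("Murray", "Goulburn"), each = 100),
    release_date = MONDAY + 20, length_mm = 430, weight_g = 1500,
    battery_days = 700L, removal_date = as.Date(NA))
  tm <- truth_model(c(intercept = 2.5, pct_change_flow = -1.7))
  st <- simulate_movement(tm, env, tags, MONDAY, seed = 22)
  resp <- persistence_response(st)
  design <- build_design(resp, env, tags, MONDAY)
  rising <- design$pct_change_flow > 0.2
  expect_gt(mean(design$response[!rising]), mean(design$response[rising]))
})

test_that("detections stop at battery expiry and appear every week when p = 1", {
  env <- constant_env(n_days = 740, start = MONDAY)
  tags <- mini_tags(release = as.Date("2007-04-15"), battery = 611L)
  tm <- truth_model(c(intercept = 2))
  st <- simulate_movement(tm, env, tags, MONDAY, seed = 3)
  det <- simulate_detections(st, mini_stations(), tags,
                             detection_prob_per_week = 1,
                             week_origin = MONDAY, seed = 4)
  expect_lte(max(as.Date(det$timestamp, tz = "UTC")), as.Date("2008-12-16"))
  weeks_with_det <- unique(paste(det$fish_id,
                                 week_index(as.Date(det$timestamp, tz = "UTC"),
                                            MONDAY)))
  expect_setequal(weeks_with_det, unique(paste(st$fish_id, st$week_index)))
})

test_that("round trip: perfect detection reproduces the true state table exactly", {
  cfg <- env_config(n_days = 500, seed = 31)
  env <- simulate_environment(cfg)
  tags <- simulate_cohort(cohort_config(
    n_murray = 10L, n_goulburn = 10L,
    release_dates = as.Date("2007-04-15"), battery_days = 350L,
    angler_removal_rate = 0, seed = 32))
  tm <- truth_model(c(intercept = 1.8, capture_murray = 3, spawning = 2.9,
                      pct_change_flow = -1.7))
  st <- simulate_movement(tm, env, tags, MONDAY, seed = 33)
  det <- simulate_detections(st, station_layout(), tags,
                             detection_prob_per_week = 1,
                             week_origin = MONDAY, seed = 34)
  rebuilt <- build_weekly_states(det, station_layout(), tags, MONDAY)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(rebuilt)[, c("fish_id", "week_index", "river")],
                   fish_id, week_index),
    dplyr::arrange(st, fish_id, week_index),
    ignore_attr = TRUE)
  expect_true(all(rebuilt$provenance == "observed"))
})

test_that("imperfect detection still recovers nearly all true states via imputation", {
  cfg <- env_config(n_days = 500, seed = 41)
  env <- simulate_environment(cfg)
  tags <- simulate_cohort(cohort_config(
    n_murray = 10L, n_goulburn = 10L,
    release_dates = as.Date("2007-04-15"), battery_days = 350L,
    angler_removal_rate = 0, seed = 42))
  tm <- truth_model(c(intercept = 1.8, capture_murray = 3, spawning = 2.9,
                      pct_change_flow = -1.7))
  st <- simulate_movement(tm, env, tags, MONDAY, seed = 43)
  det <- simulate_detections(st, station_layout(), tags,
                             detection_prob_per_week = 0.8,
                             week_origin = MONDAY, seed = 44)
  rebuilt <- build_weekly_states(det, station_layout(), tags, MONDAY)
  cmp <- dplyr::inner_join(st, tibble::as_tibble(rebuilt),
                           by = c("fish_id", "week_index"),
                           suffix = c("_true", "_rebuilt"))
  expect_equal(nrow(cmp), nrow(st))
  expect_gte(mean(cmp$river_true == cmp$river_rebuilt), 0.95)
})
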