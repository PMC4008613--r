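#' Run the full movement analysis end to end
#'
#' Chains every stage: weekly state reconstruction from the detection log,
#' covariate construction from the gauge series, all-subsets fitting of the
#' two diagonal persistence models, AICc model averaging with relative
#' importance, in-sample AUC, prediction curves, and cohort/movement
#' summaries. Inputs may be tibbles or paths to CSVs in the schemas of
#' [read_detections()] and friends.
#'
#' @param detections,stations,tags,environment input tables or CSV paths.
#' @param week_origin date starting analysis week 0 (choose a Monday for
#'   ISO-style weeks).
#' @param vocabulary continuous covariates entering the candidate set.
#' @param interactions,max_covariates passed to [enumerate_models()].
#' @param delta_threshold,average_method passed to [model_average()].
#' @param centre mean-centre continuous covariates before fitting (so
#'   prediction "average conditions" = 0); see [build_design()].
#' @param curve_covariates named list: per diagonal (`A`/`B`), the covariate
#'   swept in the prediction curves; a covariate absent from the diagonal's
#'   averaged model falls back to the first usable vocabulary entry.
#' @param out_dir if given, the bundle is also written there as CSVs via
#'   [write_bundle()].
#' @return a bundle list: `states`, `design`, `candidates`, `average`,
#'   `auc`, `curves`, `cohort_summary`, `movement`, `report`.
#' @export
run_pipeline <- function(detections, stations, tags, environment,
                         week_origin,
                         vocabulary = c("mean_flow", "mean_temp",
                                        "pct_change_flow", "cv_flow"),
                         interactions = c("spawning", "capture"),
                         max_covariates = 2,
                         delta_threshold = 4,
                         average_method = "conditional",
                         centre = TRUE,
                         curve_covariates = list(A = "mean_temp",
                                                 B = "pct_change_flow"),
                         out_dir = NULL) {
  if (is.character(detections)) detections <- read_detections(detections)
  if (is.character(stations)) stations <- read_stations(stations)
  if (is.character(tags)) tags <- read_tags(tags)
  if (is.character(environment)) environment <- read_environment(environment)
  if (nrow(detections) == 0) abort("no data: empty detection log")
  week_origin <- as.Date(week_origin)

  states <- build_weekly_states(detections, stations, tags, week_origin)
  response <- persistence_response(states)
  design <- build_design(response, environment, tags, week_origin,
                         centre = centre)
  diags <- split_diagonals(design)
  specs <- enumerate_models(vocabulary, interactions = interactions,
                            max_covariates = max_covariates)
  candidates <- purrr::map2(diags, names(diags), function(d, nm)
    fit_candidates(d, specs, diagonal = nm))
  average <- purrr::map(candidates, model_average,
                        delta_threshold = delta_threshold,
                        method = average_method)

  auc_by_diag <- purrr::map2_dbl(diags, average, function(d, avg) {
    pred <- vapply(seq_len(nrow(d)), function(i)
      persistence_probability(avg, as.list(d[i, ])), numeric(1))
    auc(pred, d$response)
  })

  curves <- purrr::map_dfr(names(average), function(nm) {
    in_model <- unique(unlist(strsplit(names(coef(average[[nm]])), ":",
                                       fixed = TRUE)))
    cv <- intersect(c(curve_covariates[[nm]], vocabulary), in_model)[1]
    if (is.na(cv)) return(NULL)
    d <- diags[[nm]]
    grid <- seq(min(d[[cv]]), max(d[[cv]]), length.out = 50)
    dplyr::mutate(prediction_curve(average[[nm]], cv, grid),
                  diagonal = nm, .before = 1)
  })

  bundle <- list(
    states = states, design = design, candidates = candidates,
    average = average, auc = auc_by_diag, curves = curves,
    cohort_summary = cohort_summary(tags),
    movement = movement_summary(states, tags, week_origin),
    report = c(attr(states, "report"),
               list(n_design_dropped = attr(design, "n_dropped")))
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Simulate a full synthetic study and analyse it
#'
#' Generates gauge series, a tagged cohort, true Markov movement under a
#' known truth model and an imperfect detection log, then runs
#' [run_pipeline()] on the simulated inputs. The returned bundle additionally
#' carries the simulation truth (`true_states`, `truth`) so recovery can be
#' checked.
#'
#' @param env_cfg an [env_config()].
#' @param cohort_cfg a [cohort_config()].
#' @param truth a [truth_model()].
#' @param week_origin date starting week 0; defaults to the Monday on or
#'   before the env series start.
#' @param seed master seed; stage seeds are derived from it.
#' @param ... passed on to [run_pipeline()].
#' @return a bundle list (see [run_pipeline()]).
#' @export
run_scenario <- function(env_cfg = env_config(),
                         cohort_cfg = cohort_config(),
                         truth, week_origin = NULL, seed = 1L, ...) {
  env_cfg$seed <- seed
  cohort_cfg$seed <- seed + 1L
  if (is.null(week_origin)) {
    d <- env_cfg$start_date
    week_origin <- d - (as.integer(format(d, "%u")) - 1L)
  }
  env <- simulate_environment(env_cfg)
  tags <- simulate_cohort(cohort_cfg)
  true_states <- simulate_movement(truth, env, tags, week_origin,
                                   seed = seed + 2L)
  detections <- simulate_detections(
    true_states, station_layout(), tags,
    detection_prob_per_week = cohort_cfg$detection_prob_per_week,
    week_origin = week_origin, seed = seed + 3L)
  bundle <- run_pipeline(detections, station_layout(), tags, env,
                         week_origin, ...)
  bundle$true_states <- true_states
  bundle$truth <- truth
  bundle$inputs <- list(env = env, tags = tags, detections = detections,
                        week_origin = week_origin)
  bundle
}
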