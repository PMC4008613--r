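# ---- information criteria ------------------------------------------------

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`. The correction term
#' vanishes as `n` grows, recovering AIC.
#'
#' @param log_likelihood maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations (fish-week rows of the diagonal's
#'   conditional dataset).
#' @return AICc.
#' @examples
#' aicc(-10, 2, 100) # 24.1237
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) {
    abort(paste0("small-sample error: AICc undefined for n = ", n,
                 ", k = ", k, " (need n > k + 1)"))
  }
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`. Non-finite entries (excluded models) get
#' weight 0.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return weights summing to 1 over the finite entries.
#' @examples
#' akaike_weights(c(100, 102)) # 0.7311, 0.2689
#' @export
akaike_weights <- function(aicc_values) {
  ok <- is.finite(aicc_values)
  if (!any(ok)) abort("no finite AICc values")
  delta <- aicc_values - min(aicc_values[ok])
  w <- ifelse(ok, exp(-delta / 2), 0)
  w / sum(w)
}

# ---- candidate-set enumeration -------------------------------------------

#' Enumerate the constrained all-subsets candidate model set
#'
#' Generates every term subset in which each continuous covariate enters at
#' one of up to six levels — absent; main effect; main + interaction with
#' spawning; main + interaction with capture river; main + both two-way
#' interactions; main + both two-ways + the three-way — and the categoricals
#' (`spawning`, `capture_murray`) are present whenever marginality requires
#' them, and otherwise toggle freely. An optional cap limits how many
#' continuous covariates a single model may contain, which keeps the
#' enumeration tractable with the full six-covariate vocabulary.
#'
#' @param covariates character vector of continuous covariate names.
#' @param interactions which interaction structures to allow per covariate:
#'   any of `"spawning"`, `"capture"`, `"three_way"` (`"three_way"` requires
#'   both two-ways).
#' @param max_covariates cap on continuous covariates per model
#'   (default unlimited).
#' @return a list of [model_spec()]s.
#' @examples
#' length(enumerate_models("pct_change_flow", interactions = "spawning")) # 10
#' @export
enumerate_models <- function(covariates,
                             interactions = c("spawning", "capture",
                                              "three_way"),
                             max_covariates = Inf) {
  if (anyDuplicated(covariates)) {
    abort("invalid configuration: duplicate covariate names")
  }
  interactions <- match.arg(interactions, several.ok = TRUE,
                            choices = c("spawning", "capture", "three_way"))
  # inclusion levels for one covariate: list of (terms, needs_s, needs_c)
  levels_for <- function(x) {
    lv <- list(list(terms = character(), s = FALSE, c = FALSE),
               list(terms = x, s = FALSE, c = FALSE))
    if ("spawning" %in% interactions) {
      lv <- c(lv, list(list(terms = c(x, paste0(x, ":spawning")),
                            s = TRUE, c = FALSE)))
    }
    if ("capture" %in% interactions) {
      lv <- c(lv, list(list(terms = c(x, paste0(x, ":capture_murray")),
                            s = FALSE, c = TRUE)))
    }
    if (all(c("spawning", "capture") %in% interactions)) {
      both <- c(x, paste0(x, ":spawning"), paste0(x, ":capture_murray"))
      lv <- c(lv, list(list(terms = both, s = TRUE, c = TRUE)))
      if ("three_way" %in% interactions) {
        lv <- c(lv, list(list(
          terms = c(both, paste0(x, ":capture_murray:spawning"),
                    "capture_murray:spawning"),
          s = TRUE, c = TRUE)))
      }
    }
    lv
  }
  per_cov <- lapply(covariates, levels_for)
  grid <- if (length(per_cov)) expand.grid(lapply(per_cov, seq_along))
          else data.frame(row.names = 1)
  specs <- list()
  for (i in seq_len(nrow(grid))) {
    chosen <- purrr::map2(per_cov, as.integer(grid[i, ]), ~ .x[[.y]])
    n_active <- sum(vapply(chosen, function(l) length(l$terms) > 0, logical(1)))
    if (n_active > max_covariates) next
    terms <- unlist(lapply(chosen, `[[`, "terms"))
    need_s <- any(vapply(chosen, `[[`, logical(1), "s"))
    need_c <- any(vapply(chosen, `[[`, logical(1), "c"))
    s_opts <- if (need_s) TRUE else c(FALSE, TRUE)
    c_opts <- if (need_c) TRUE else c(FALSE, TRUE)
    for (s_in in s_opts) {
      for (c_in in c_opts) {
        specs[[length(specs) + 1L]] <- model_spec(c(
          terms,
          if (s_in) "spawning", if (c_in) "capture_murray"))
      }
    }
  }
  unique(specs)
}

#' Fit every candidate model of one diagonal
#'
#' Fits each spec with [fit_persistence()], scores converged fits by AICc,
#' and attaches Akaike weights. Non-converged (separated) fits and fits with
#' undefined AICc are kept in the table with weight 0 and excluded from all
#' downstream inference; their count is reported by `glance()`.
#'
#' @param design one diagonal's design tibble.
#' @param specs list of [model_spec()]s, e.g. from [enumerate_models()].
#' @param diagonal label for reporting (`"A"` = currently Murray,
#'   `"B"` = currently Goulburn).
#' @return a `candidate_set`.
#' @export
fit_candidates <- function(design, specs, diagonal = NA_character_) {
  fits <- purrr::map(specs, function(s) {
    tryCatch(fit_persistence(design, s),
             error = function(e) structure(
               list(spec = s, converged = FALSE, aicc = NA_real_,
                    log_likelihood = NA_real_, k = length(s) + 1L,
                    n = nrow(design), coefficients = NULL,
                    standard_errors = NULL,
                    diagnostic = conditionMessage(e)),
               class = "persistence_fit"))
  })
  aiccs <- vapply(fits, function(f)
    if (isTRUE(f$converged)) f$aicc else NA_real_, numeric(1))
  w <- akaike_weights(aiccs)
  structure(list(
    diagonal = diagonal, specs = specs, fits = fits, aicc = aiccs,
    delta_aicc = aiccs - min(aiccs, na.rm = TRUE), weights = w,
    n_excluded = sum(!is.finite(aiccs))
  ), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> diagonal ", x$diagonal, ": ", length(x$fits),
      " models (", x$n_excluded, " excluded), best AICc = ",
      format(min(x$aicc, na.rm = TRUE), digits = 6), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_candidates
#' @param x a `candidate_set`.
#' @param ... unused.
#' @return `tidy()`: one row per candidate with formula, `k`, `logLik`,
#'   `AICc`, `delta_AICc`, `weight`, `converged`.
#' @export
tidy.candidate_set <- function(x, ...) {
  dplyr::arrange(tibble::tibble(
    spec = vapply(x$specs, format, character(1)),
    k = vapply(x$fits, `[[`, numeric(1), "k"),
    logLik = vapply(x$fits, function(f)
      if (is.null(f$log_likelihood)) NA_real_ else f$log_likelihood, numeric(1)),
    AICc = x$aicc,
    delta_AICc = x$delta_aicc,
    weight = x$weights,
    converged = vapply(x$fits, function(f) isTRUE(f$converged), logical(1))
  ), .data$AICc)
}

#' Per-term relative importance
#'
#' The relative importance of a term is 100 times the sum of the Akaike
#' weights of every candidate model containing it, computed over the full
#' candidate set (not just the averaging subset).
#'
#' @param candidate_set a `candidate_set`.
#' @return a tibble `term`, `relative_importance` (percent), sorted
#'   decreasing.
#' @export
relative_importance <- function(candidate_set) {
  terms <- unique(unlist(lapply(candidate_set$specs, unclass)))
  ri <- vapply(terms, function(t) {
    has <- vapply(candidate_set$specs, function(s) t %in% unclass(s),
                  logical(1))
    100 * sum(candidate_set$weights[has])
  }, numeric(1))
  dplyr::arrange(tibble::tibble(term = terms, relative_importance = unname(ri)),
                 dplyr::desc(.data$relative_importance))
}

#' Model-average the best-supported candidates
#'
#' Averages coefficients over the models within `delta_threshold` AICc of
#' the best model, with weights renormalised over that subset. The default
#' conditional (subset) average divides each term's weighted coefficient sum
#' by the summed weight of the models that contain the term; the `"full"`
#' mode instead treats the coefficient as 0 in models omitting the term.
#' Unconditional standard errors follow the revised multimodel formula
#' `sqrt(sum_i w_i (SE_i^2 + (b_i - b_bar)^2))`, and 95% CIs are
#' `estimate +/- 1.96 SE`. Only terms appearing in at least one included
#' model are reported. Relative importance (over the full set) is attached
#' per term.
#'
#' @param candidate_set a `candidate_set` with at least one converged fit.
#' @param delta_threshold AICc distance defining the averaging subset.
#' @param method `"conditional"` (default) or `"full"` averaging.
#' @return an `averaged_model`.
#' @export
model_average <- function(candidate_set, delta_threshold = 4,
                          method = c("conditional", "full")) {
  method <- match.arg(method)
  if (delta_threshold <= 0) abort("delta_threshold must be positive")
  ok <- vapply(candidate_set$fits, function(f) isTRUE(f$converged), logical(1)) &
    is.finite(candidate_set$aicc)
  if (!any(ok)) abort("no converged models to average")
  inc <- ok & candidate_set$delta_aicc < delta_threshold
  w <- candidate_set$weights[inc] / sum(candidate_set$weights[inc])
  fits <- candidate_set$fits[inc]
  terms <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  rows <- purrr::map_dfr(terms, function(t) {
    b <- vapply(fits, function(f)
      if (t %in% names(f$coefficients)) f$coefficients[[t]] else NA_real_,
      numeric(1))
    se <- vapply(fits, function(f)
      if (t %in% names(f$coefficients)) f$standard_errors[[t]] else NA_real_,
      numeric(1))
    has <- !is.na(b)
    if (method == "conditional") {
      wt <- w[has] / sum(w[has])
      est <- sum(wt * b[has])
      use_b <- b[has]; use_se <- se[has]
    } else {
      wt <- w
      est <- sum(wt * ifelse(has, b, 0))
      use_b <- ifelse(has, b, 0); use_se <- ifelse(has, se, 0)
    }
    se_u <- sqrt(sum(wt * (use_se^2 + (use_b - est)^2)))
    tibble::tibble(term = t, estimate = est, std.error = se_u,
                   conf.low = est - 1.96 * se_u, conf.high = est + 1.96 * se_u)
  })
  ri <- relative_importance(candidate_set)
  rows <- dplyr::left_join(rows, ri, by = "term")
  structure(list(
    diagonal = candidate_set$diagonal, terms = rows,
    n_included = sum(inc), method = method,
    delta_threshold = delta_threshold,
    weights = w
  ), class = "averaged_model")
}

#' @export
coef.averaged_model <- function(object, ...) {
  setNames(object$terms$estimate, object$terms$term)
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("<averaged_model> diagonal ", x$diagonal, ": ", x$n_included,
      " models averaged (", x$method, ", delta AICc < ",
      x$delta_threshold, ")\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' Tidy an averaged transition model
#'
#' One row per averaged term: estimate, unconditional SE, 95% CI bounds and
#' relative importance — the shape of a published model-average table.
#'
#' @param x an `averaged_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.averaged_model <- function(x, ...) {
  x$terms
}

#' @rdname tidy.averaged_model
#' @export
glance.averaged_model <- function(x, ...) {
  tibble::tibble(n_included = x$n_included, method = x$method,
                 delta_threshold = x$delta_threshold)
}
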