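# ---- model specifications ------------------------------------------------

# canonical ordering of term components: covariate, then capture_murray,
# then spawning; e.g. "spawning:mean_temp" -> "mean_temp:spawning"
.vocabulary <- c("mean_flow", "mean_temp", "pct_change_flow", "cv_flow",
                 "pct_change_temp", "cv_temp", "capture_murray", "spawning")

canonical_term <- function(term) {
  vapply(term, function(t) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    pos <- match(parts, .vocabulary)
    if (anyNA(pos)) abort(paste0("unknown term component(s) in '", t, "'"))
    paste(parts[order(pos)], collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

#' Specify one candidate transition model
#'
#' A model spec is the ordered set of terms of one diagonal's logistic
#' regression (the intercept is always present and implicit). Terms are drawn
#' from the covariate vocabulary — the six continuous gauge covariates plus
#' the two categoricals `capture_murray` and `spawning` — and `:`-joined
#' interactions. Marginality is enforced: every lower-order constituent of
#' an interaction must itself be present.
#'
#' @param terms character vector of term names (may be `character(0)` for
#'   the intercept-only model).
#' @return a `model_spec` (character vector, canonically ordered).
#' @examples
#' model_spec(c("capture_murray", "spawning", "mean_temp",
#'              "mean_temp:spawning"))
#' @export
model_spec <- function(terms = character()) {
  terms <- unique(canonical_term(terms))
  for (t in terms) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(parts) > 1) {
      need <- unlist(lapply(seq_len(length(parts) - 1), function(k)
        utils::combn(parts, k, paste, collapse = ":", simplify = TRUE)))
      need <- canonical_term(need)
      miss <- setdiff(need, terms)
      if (length(miss)) {
        abort(paste0("marginality violated: '", t, "' requires ",
                     paste(miss, collapse = ", ")))
      }
    }
  }
  structure(terms[order(match(
    vapply(strsplit(terms, ":"), `[`, character(1), 1), .vocabulary),
    nchar(terms))], class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  paste(c("intercept", unclass(x)), collapse = " + ")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

# design matrix for a spec: intercept column plus one product column per term
spec_model_matrix <- function(design, spec) {
  X <- matrix(1, nrow(design), 1, dimnames = list(NULL, "intercept"))
  for (t in unclass(spec)) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    missing <- setdiff(parts, names(design))
    if (length(missing)) {
      abort(paste0("unknown term component(s): ",
                   paste(missing, collapse = ", ")))
    }
    col <- Reduce(`*`, lapply(parts, function(p) as.numeric(design[[p]])))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- t
  }
  X
}

# ---- fitting -------------------------------------------------------------

#' Fit one diagonal persistence model
#'
#' Maximum-likelihood fit of a binomial GLM with logit link for the weekly
#' persistence response of one conditional dataset (one diagonal of the
#' transition matrix). Standard errors come from the observed information.
#' Quasi-separation — any |coefficient| > `separation_threshold` on the logit
#' scale — marks the fit non-converged, since all-subsets enumeration will
#' visit pathological models whose likelihoods are unbounded artifacts.
#'
#' @param design a design tibble (one diagonal's rows; see
#'   [split_diagonals()]).
#' @param spec a [model_spec()].
#' @param separation_threshold logit-scale cutoff flagging separation.
#' @return a `persistence_fit` with coefficients, SEs, log-likelihood, `k`,
#'   `n`, AICc and a convergence flag.
#' @export
fit_persistence <- function(design, spec = model_spec(),
                            separation_threshold = 15) {
  if (nrow(design) == 0) abort("no data: empty design")
  y <- design$response
  if (!all(y %in% c(0L, 1L))) abort("response must be 0/1")
  X <- spec_model_matrix(design, spec)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[fit$qr$pivot[seq(fit$rank + 1L, ncol(X))]]
    abort(paste0("rank-deficient design: aliased term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  beta <- fit$coefficients
  # observed information from the weighted QR of the final IRLS step
  cov_un <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  se <- setNames(sqrt(diag(cov_un)), colnames(X)[fit$qr$pivot[seq_len(fit$rank)]])
  se <- se[colnames(X)]
  ll <- -fit$deviance / 2
  k <- ncol(X)
  n <- nrow(X)
  converged <- isTRUE(fit$converged) && all(abs(beta) <= separation_threshold)
  structure(list(
    spec = spec, coefficients = beta, standard_errors = se,
    log_likelihood = ll, k = k, n = n,
    aicc = if (n > k + 1) aicc(ll, k, n) else NA_real_,
    converged = converged,
    diagnostic = if (converged) NULL else "separation or non-convergence"
  ), class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat("<persistence_fit> ", format(x$spec), "\n",
      "  n = ", x$n, ", k = ", x$k,
      ", logLik = ", format(x$log_likelihood, digits = 6),
      ", AICc = ", format(x$aicc, digits = 6),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' @export
coef.persistence_fit <- function(object, ...) object$coefficients

#' Tidy a fitted persistence model
#'
#' @param x a `persistence_fit`.
#' @param ... unused.
#' @return a tibble with `term`, `estimate`, `std.error`, `statistic`.
#' @method tidy persistence_fit
#' @export
tidy.persistence_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$standard_errors),
                 statistic = unname(x$coefficients / x$standard_errors))
}

#' @rdname tidy.persistence_fit
#' @return `glance()`: a one-row tibble with `logLik`, `k`, `n`, `AICc`,
#'   `converged`.
#' @method glance persistence_fit
#' @export
glance.persistence_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, k = x$k, n = x$n,
                 AICc = x$aicc, converged = x$converged)
}

# ---- probabilities and the transition matrix -----------------------------

#' Persistence probability under a coefficient set
#'
#' Inverse-logit of the linear predictor of a fitted or averaged model at
#' given covariate values. Interaction terms are evaluated as products of
#' their constituents; covariates not named in `values` default to 0, which
#' under mean-centred covariates means "average conditions".
#'
#' @param object a `persistence_fit`, an `averaged_model`, or a named
#'   coefficient vector (using `intercept` for the intercept).
#' @param values named list/vector of covariate values.
#' @param default value used for covariates absent from `values` (`NA` to
#'   require every constituent explicitly).
#' @return a probability.
#' @examples
#' persistence_probability(c(intercept = 1.8232, capture_murray = 2.9833),
#'                         list(capture_murray = 1))
#' @export
persistence_probability <- function(object, values = list(), default = 0) {
  coefs <- if (is.numeric(object)) object else coef(object)
  parts <- unique(unlist(strsplit(names(coefs), ":", fixed = TRUE)))
  parts <- setdiff(parts, c("intercept", "(Intercept)", "1"))
  values <- as.list(values)
  if (is.na(default)) {
    miss <- setdiff(parts, names(values))
    if (length(miss)) {
      abort(paste0("missing covariate value(s): ", paste(miss, collapse = ", ")))
    }
  } else {
    for (p in setdiff(parts, names(values))) values[[p]] <- default
  }
  plogis(eval_linear_predictor(coefs, values))
}

#' Weekly transition matrix from the two diagonal persistence probabilities
#'
#' Rows index the current river (Goulburn, Murray), columns the next; each
#' row is a probability distribution: a fish in the Goulburn persists with
#' `p_G` and moves with `1 - p_G`, and symmetrically for the Murray.
#'
#' @param p_G,p_M diagonal persistence probabilities in \[0, 1\].
#' @return a 2 x 2 row-stochastic matrix with dimnames.
#' @examples
#' transition_matrix(0.7, 0.9)
#' @export
transition_matrix <- function(p_G, p_M) {
  if (!is.finite(p_G) || !is.finite(p_M) ||
      p_G < 0 || p_G > 1 || p_M < 0 || p_M > 1) {
    abort("invalid argument: persistence probabilities must be in [0, 1]")
  }
  matrix(c(p_G, 1 - p_G, 1 - p_M, p_M), 2, 2, byrow = TRUE,
         dimnames = list(from = c("Goulburn", "Murray"),
                         to = c("Goulburn", "Murray")))
}

#' @rdname transition_matrix
#' @return `stationary_occupancy()`: the long-run probability of occupying
#'   the Goulburn under constant persistence probabilities,
#'   `(1 - p_M) / ((1 - p_G) + (1 - p_M))`.
#' @export
stationary_occupancy <- function(p_G, p_M) {
  (1 - p_M) / ((1 - p_G) + (1 - p_M))
}
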