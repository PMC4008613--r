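test_that("AICc follows the small-sample corrected formula", {
  expect_equal(aicc(-10, 2, 100), 24 + 12 / 97)
  # the correction vanishes at large n, recovering AIC
  expect_equal(aicc(-10, 2, 1e9), 24, tolerance = 1e-6)
  # equal likelihoods: the smaller model always scores better
  expect_lt(aicc(-10, 2, 100), aicc(-10, 3, 100))
  expect_error(aicc(-10, 99, 100), "small-sample")
})

test_that("Akaike weights normalise exponential AICc differences", {
  expect_equal(akaike_weights(50), 1)
  expect_equal(akaike_weights(c(12, 12)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(0.7310586, 0.2689414), tolerance = 1e-6)
  expect_equal(sum(w), 1)
  # invariant to a constant shift
  expect_equal(akaike_weights(c(100, 102) + 57), w)
})

test_that("single-covariate enumeration yields the 10 marginality-valid subsets", {
  specs <- enumerate_models("pct_change_flow", interactions = "spawning")
  expect_length(specs, 10)
  # marginality: any spec with the interaction carries both main effects
  for (s in specs) {
    if ("pct_change_flow:spawning" %in% s) {
      expect_true(all(c("pct_change_flow", "spawning") %in% s))
    }
  }
  expect_error(enumerate_models(c("cv_flow", "cv_flow")), "duplicate")
})

test_that("no continuous covariates leaves the categorical powerset", {
  specs <- enumerate_models(character(0))
  expect_length(specs, 4)
  expect_setequal(vapply(specs, format, character(1)),
                  c("intercept", "intercept + spawning",
                    "intercept + capture_murray",
                    "intercept + capture_murray + spawning"))
})

test_that("two-covariate enumeration equals a powerset filtered by marginality", {
  specs <- enumerate_models(c("mean_temp", "cv_flow"),
                            interactions = c("spawning", "capture"))
  universe <- c("spawning", "capture_murray",
                "mean_temp", "cv_flow",
                "mean_temp:spawning", "mean_temp:capture_murray",
                "cv_flow:spawning", "cv_flow:capture_murray")
  keep <- list()
  for (mask in 0:(2^length(universe) - 1)) {
    terms <- universe[bitwAnd(mask, 2^(seq_along(universe) - 1)) > 0]
    ok <- all(vapply(terms, function(t) {
      parts <- strsplit(t, ":", fixed = TRUE)[[1]]
      length(parts) == 1 || all(parts %in% terms)
    }, logical(1)))
    if (ok) keep[[length(keep) + 1L]] <- sort(terms)
  }
  got <- lapply(specs, function(s) sort(unclass(s)))
  expect_equal(length(got), length(keep))
  expect_true(all(vapply(keep, function(k)
    any(vapply(got, identical, logical(1), k)), logical(1))))
})

test_that("the covariate cap limits model size without breaking marginality", {
  specs <- enumerate_models(c("mean_temp", "cv_flow"),
                            interactions = "spawning", max_covariates = 1)
  conts <- vapply(specs, function(s)
    sum(c("mean_temp", "cv_flow") %in% s), integer(1))
  expect_true(all(conts <= 1))
})

# a hand-built candidate set with known weights: delta chosen so the
# renormalised weights are exactly 0.6 / 0.4
fake_fit <- function(spec, coefs, ses, ll, n) {
  structure(list(spec = spec, coefficients = coefs,
                 standard_errors = ses, log_likelihood = ll,
                 k = length(coefs), n = n,
                 aicc = aicc(ll, length(coefs), n), converged = TRUE),
            class = "persistence_fit")
}

fake_candidates <- function(b1, b2, se1 = 0.5, se2 = 0.5) {
  delta <- 2 * log(0.6 / 0.4)
  f1 <- fake_fit(model_spec("mean_temp"),
                 c(intercept = 0.1, mean_temp = b1),
                 c(intercept = 0.2, mean_temp = se1), -50, 500)
  ll2 <- f1$log_likelihood - delta / 2  # same k -> AICc gap = delta
  f2 <- fake_fit(model_spec("cv_flow"),
                 c(intercept = 0.3, cv_flow = b2),
                 c(intercept = 0.2, cv_flow = se2), ll2, 500)
  aiccs <- c(f1$aicc, f2$aicc)
  structure(list(diagonal = "A", specs = list(f1$spec, f2$spec),
                 fits = list(f1, f2), aicc = aiccs,
                 delta_aicc = aiccs - min(aiccs),
                 weights = akaike_weights(aiccs), n_excluded = 0L),
            class = "candidate_set")
}

test_that("relative importance sums the weights of containing models", {
  cs <- fake_candidates(1, 2)
  ri <- relative_importance(cs)
  # the intercept is implicit, never ranked
  expect_false("intercept" %in% ri$term)
  expect_equal(ri$relative_importance[ri$term == "mean_temp"], 60,
               tolerance = 1e-9)
  expect_equal(ri$relative_importance[ri$term == "cv_flow"], 40,
               tolerance = 1e-9)
})

test_that("conditional averaging weights coefficients over containing models", {
  # shared term (the intercept) with betas 0.1/0.3 under weights 0.6/0.4;
  # a term private to one model keeps its own estimate
  cs <- fake_candidates(1, 2)
  avg <- model_average(cs, delta_threshold = 4)
  t <- tidy(avg)
  expect_equal(t$estimate[t$term == "intercept"], 0.6 * 0.1 + 0.4 * 0.3)
  expect_equal(t$estimate[t$term == "mean_temp"], 1)
  expect_equal(t$estimate[t$term == "cv_flow"], 2)
  expect_equal(t$conf.low, t$estimate - 1.96 * t$std.error)
  # identical coefficient and SE across models -> unconditional SE = common SE
  cs2 <- fake_candidates(1, 2)
  cs2$fits[[2]]$coefficients["intercept"] <- 0.1
  expect_equal(tidy(model_average(cs2))$std.error[1], 0.2)
})

test_that("a two-model average with a shared slope gives the 0.6/0.4 weighted mean", {
  cs <- fake_candidates(1, 2)
  cs$fits[[2]]$coefficients <- c(intercept = 0.3, mean_temp = 2)
  names(cs$fits[[2]]$standard_errors) <- c("intercept", "mean_temp")
  avg <- tidy(model_average(cs))
  expect_equal(avg$estimate[avg$term == "mean_temp"], 0.6 * 1 + 0.4 * 2)
})

test_that("averaging respects the delta threshold and excludes absent terms", {
  cs <- fake_candidates(1, 2)
  cs$delta_aicc <- c(0, 6)  # second model now outside the window
  avg <- model_average(cs, delta_threshold = 4)
  t <- tidy(avg)
  expect_false("cv_flow" %in% t$term)
  expect_equal(t$estimate[t$term == "mean_temp"], 1)
  expect_equal(avg$n_included, 1)
})

test_that("candidate fitting on real data orders models sensibly and weights sum to 1", {
  beta <- c(intercept = 1, spawning = 1.5)
  design <- random_design(600, beta, seed = 77)
  specs <- enumerate_models("mean_temp", interactions = "spawning")
  cs <- fit_candidates(design, specs, diagonal = "B")
  expect_equal(sum(cs$weights), 1)
  expect_equal(min(cs$delta_aicc, na.rm = TRUE), 0)
  tt <- tidy(cs)
  expect_true(all(diff(tt$AICc[is.finite(tt$AICc)]) >= 0))
  # the spawning main effect should dominate importance
  ri <- relative_importance(cs)
  expect_gt(ri$relative_importance[ri$term == "spawning"], 50)
})
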