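# tribmove

Movement of river fish across a mainstem–tributary junction, modelled from
acoustic telemetry as a weekly two-state Markov chain.

## What it does, and for whom

Fisheries ecologists tracking tagged fish with moored acoustic receivers at
a river junction (here: adult golden perch at the Murray–Goulburn
confluence, south-eastern Australia) face three chained problems:

1. turn a patchy detection log into a complete weekly river-occupancy state
   series per fish, censored at transmitter battery expiry or angler
   removal;
2. relate weekly persistence — the probability a fish stays in its current
   river next week — to hydrology and season;
3. rank and combine many plausible covariate structures honestly.

`tribmove` implements the whole chain as tidyverse-style, pipe-friendly
functions. The core model is a Markov transition matrix with logistic
regressions on the diagonals,

```
        | p_G,t      1 - p_G,t |
  P_t = |                      |
        | 1 - p_M,t  p_M,t     |
```

where `logit(p_G,t)` and `logit(p_M,t)` are binomial GLMs fitted on
disjoint conditional datasets (currently-Goulburn and currently-Murray
fish-weeks). Candidate covariate sets — capture river, spawning season
(September–February), mean weekly flow and temperature, fortnight
percentage change and CV of each, with two- and three-way interactions
under a marginality constraint — are enumerated exhaustively, scored by
AICc, weighted, and averaged over the ΔAICc < 4 subset with unconditional
standard errors and per-term relative importance. Discrimination is
reported as the rank-sum AUC, and prediction curves sweep any covariate
under capture-river × spawning scenarios.

Because the original telemetry data are unpublished, the package includes a
first-class synthetic-data generator (`simulate_environment()`,
`simulate_cohort()`, `simulate_movement()`, `simulate_detections()`) that
emulates the study design — three April tagging cohorts, paired listening
stations, seasonal flow with freshes, battery expiry at 611/660/880 days,
imperfect detection — so the estimation machinery is validated end to end
by parameter recovery. See the methods vignette
(`vignettes/tributary-movement.Rmd`) for the model, the design decisions
and their rationale.

## Worked example

The published tag table and Murray-diagonal model-average coefficients ship
with the package:

```r
library(tribmove)

cohort_summary(golden_perch_tags())[, 1:6]
#>      group  n mean_length se_length min_length max_length
#> 1 Goulburn 37       413.5    10.200        315        520
#> 2   Murray 42       437.9     9.289        320        580
#> 3  Overall 79       426.5     6.965        315        580

coefs <- with(murray_model_average(), setNames(estimate, term))
persistence_probability(coefs, list(capture_murray = 1, spawning = 0))
#> [1] 0.9918899
exp(coefs[["spawning"]])
#> [1] 17.54905
```

A Murray-tagged fish in the Murray under average conditions persists with
probability 0.992 — 99% to the nearest percent — and being in the spawning
season multiplies the persistence odds more than 17-fold.

A full synthetic study, simulated from a known truth and re-analysed:

```r
tm <- truth_model(c(intercept = 1.8, capture_murray = 3, spawning = 2.9,
                    pct_change_flow = -1.7))
b <- run_scenario(env_config(seed = 1), cohort_config(), truth = tm,
                  seed = 42, vocabulary = c("mean_temp", "pct_change_flow"),
                  interactions = c("spawning", "capture"))
round(b$auc, 3)
#>     A     B
#> 0.905 0.876
as.data.frame(tidy(b$average$B))[, c(1, 2, 3, 6)]
#>                             term estimate std.error relative_importance
#> 1                      intercept  1.80572    0.0909                  NA
#> 2                pct_change_flow -1.53836    0.1389               100.0
#> 3                 capture_murray  2.49047    0.3172               100.0
#> 4                       spawning  2.64041    0.3403               100.0
#> 5                      mean_temp  0.00231    0.0188                43.4
#> 6             mean_temp:spawning  0.00555    0.0652                11.7
#> 7       mean_temp:capture_murray -0.04935    0.0592                14.8
#> 8       pct_change_flow:spawning -0.43763    0.7594                30.1
#> 9 pct_change_flow:capture_murray -0.06459    0.2520                27.8
```

The averaged Goulburn-persistence model puts all its weight on the three
generating terms (relative importance 100) and recovers their coefficients;
the mild shrinkage of `capture_murray` and `pct_change_flow` towards zero
is the expected attenuation from rebuilding states under 90% weekly
detection with carry-forward imputation. `autoplot()` methods draw the
prediction curves and coefficient plots; `plot_occupancy()` draws the
per-fish weekly occupancy timeline.

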