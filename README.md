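# habitdtw

Objective habit detection from minute-level app-session logs.

Frequency counts cannot tell a reflexive daily routine apart from the
same amount of use scattered unpredictably across the day. `habitdtw`
implements a temporal-similarity statistic that can: each user-day
becomes a 1440-minute binary vector, consecutive days are compared with
a dynamic time warping (DTW) distance

```
DTW(a, b) = min over monotone warping paths π of Σ_{(i,j)∈π} |a_i − b_j|
```

(steps {(1,0), (0,1), (1,1)}, boundary-anchored, unconstrained), a
penalty substitutes for pairs of empty days, and the distance is
normalised by the user's mean daily minutes of use and averaged within
nonoverlapping 14-day intervals. DTW forgives a routine that merely
shifts a few minutes — two days with the same single interior block of
use have distance 0 at any shift, where the Euclidean distance already
counts every shifted minute — so low values isolate temporally
*consistent* use, the behavioural signature of a cue-driven habit.

Around the statistic the package provides the full evaluation pipeline
for mobile-health engagement analyses:

* session-log / survey ingest and validation (CSV), minute binarisation,
  Morning/Evening/Night and weekday/weekend stratification;
* the start-date rule (first Monday after 5 use-days within 14 days),
  ten 14-day intervals per user with post-survey padding, and per-stratum
  objective use measures (days of use, sessions, duration, unique titles,
  temporal similarity);
* dichotomous future-use outcomes (any use 28 days and 6 months after a
  survey; above-median 28-day duration) and survey-based physical/mental
  improvement outcomes;
* logistic odds-ratio tables (Wald CIs, separation flagging), paired
  in-sample ROC AUC comparison via the DeLong test, and seeded
  random-forest variable importance;
* a fully seeded synthetic cohort generator in which a latent habit
  strength drives use frequency, streakiness, cue-time concentration,
  post-survey persistence and reported mental-health improvement — so
  every stage is testable without proprietary data.

## Worked example

```r
library(habitdtw)

# the canonical two-day contrast: equal use, shifted in time
fx <- figure1_fixture()
euclidean_distance(fx$day_a, fx$day_b)
#> [1] 2
dtw_distance(fx$day_a, fx$day_b)
#> [1] 0

# a synthetic cohort end to end
co <- generate_cohort(cohort_config(n_users = 300), seed = 7)
iv <- user_intervals(co$sessions, co$survey)
ft <- aggregate_features(co$sessions, iv, strata = "all")
fut <- future_use_outcomes(co$sessions, co$survey)
demo <- co$survey[, c("user_id", "age_band", "sex", "race", "income",
                      "employment", "education")]
ps <- run_prediction_suite(ft, fut, demo, tiers = 1, seed = 7)
ps
#> Future-use prediction suite (with vs without DTW features)
#>             outcome tier   n auc_without auc_with difference  chi2 p_value
#> 1       any_use_28d  all 300      0.7635   0.8046    0.04107 6.370 0.01161
#> 2       any_use_6mo  all 300      0.7794   0.8091    0.02967 4.431 0.03530
#> 3 high_duration_28d  all 300      0.7635   0.8046    0.04107 6.370 0.01161
```

The comparison rows read: adding the ten per-interval DTW columns to a
logistic model that already contains demographics and all count/duration
measures raises the in-sample AUC, and the DeLong chi-square test says
the paired improvement is real rather than noise. (In this small cohort
the third outcome coincides with the first: half the users never return,
so the median 28-day duration is zero and "above median" reduces to "any
use".) In this simulated cohort the habit signal genuinely lives partly
in timing regularity, so the statistic earns its keep;
`run_benefit_suite()` does the analogous job for the survey outcomes,
where stronger habits (lower temporal dissimilarity) carry higher odds
of reported mental-health improvement.

A thin command-line wrapper drives the same pipeline from a YAML config:

```
exec/habitdtw run -c config.yaml --seed 1 -o out/
```

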