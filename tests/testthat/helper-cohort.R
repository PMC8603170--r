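# Small deterministic fixtures built in code.

mk_sessions <- function(...) {
  rows <- list(...)
  out <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      user_id = r$user %||% "u1",
      start = as.POSIXct(paste(r$date, r$time %||% "10:00:00"), tz = "UTC"),
      duration_min = r$dur %||% 10,
      session_type = r$type %||% "meditation",
      title = r$title %||% paste0(r$type %||% "meditation", "_1"),
      completed = r$completed %||% TRUE)
  }))
  habitdtw::validate_sessions(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# one session per day over a date span, fixed clock time
daily_sessions <- function(user, from, n_days, time = "10:00:00", dur = 10,
                           type = "meditation") {
  dates <- as.Date(from) + seq_len(n_days) - 1
  habitdtw::validate_sessions(tibble::tibble(
    user_id = user,
    start = as.POSIXct(paste(dates, time), tz = "UTC"),
    duration_min = dur, session_type = type,
    title = paste0(type, "_1"), completed = TRUE))
}

# a minimal single-row survey for constructed cohorts
mk_survey <- function(user_ids, survey_date = "2019-12-01") {
  n <- length(user_ids)
  out <- tibble::tibble(
    user_id = user_ids, survey_date = as.Date(survey_date),
    age_band = "30-44", sex = "female", race = "white",
    income = "over_60k", employment = "full_time", education = "college")
  for (col in habitdtw:::.survey_flag_cols()) out[[col]] <- FALSE
  out
}

demo_of <- function(survey) {
  survey[, c("user_id", "age_band", "sex", "race", "income", "employment",
             "education")]
}

# Simulate a cohort and run the tier-1 (all-sessions) prediction
# comparison; returns the AUC comparison tibble.
run_tier1_suite <- function(n_users, seed, suite_args = list(), ...) {
  co <- habitdtw::generate_cohort(
    habitdtw::cohort_config(n_users = n_users, ...), seed = seed)
  iv <- habitdtw::user_intervals(co$sessions, co$survey)
  ft <- habitdtw::aggregate_features(co$sessions, iv, strata = "all")
  fut <- habitdtw::future_use_outcomes(co$sessions, co$survey)
  ps <- do.call(habitdtw::run_prediction_suite,
                c(list(ft, fut, demo_of(co$survey), tiers = 1, seed = seed,
                       n_trees = 100), suite_args))
  ps$comparisons
}

# Simulate a cohort and return the Model-1 odds-ratio table for improved
# mental health from the benefit suite (last 3 pre-survey intervals).
run_benefit_model1 <- function(n_users, seed, ...) {
  co <- habitdtw::generate_cohort(
    habitdtw::cohort_config(n_users = n_users, days_post = 5, ...),
    seed = seed)
  iv <- habitdtw::user_intervals(co$sessions, co$survey)
  iv <- iv[iv$interval_index >= 8, ]   # the suite only uses the last 3
  ft <- habitdtw::aggregate_features(co$sessions, iv,
                                     strata = c("all", "session_type"))
  ben <- habitdtw::dichotomize_survey(co$survey)
  bs <- habitdtw::run_benefit_suite(ft, ben, demo_of(co$survey))
  bs$or_tables[["model1.improved_mental"]]
}
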