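#' Outcome window definitions
#'
#' The three dichotomous future-use outcomes are measured in fixed windows
#' after the survey date: any use in the 28 days following the survey;
#' any use in the 28-day window ending 182 days (6 months) after the
#' survey; and whether total duration in the first 28-day window exceeds
#' the cohort median. The 6-month window width mirrors the 28-day
#' outcome because a single-day reading of "use 6 months later" would be
#' degenerate.
#'
#' @param use_28d Integer vector `c(from, to)`, days after survey
#'   (half-open on the left: day `from` excluded, day `to` included).
#' @param use_6mo Same for the 6-month window.
#' @return A list of class `outcome_windows`.
#' @export
outcome_windows <- function(use_28d = c(0L, 28L), use_6mo = c(154L, 182L)) {
  structure(list(use_28d = as.integer(use_28d),
                 use_6mo = as.integer(use_6mo)),
            class = "outcome_windows")
}

#' Dichotomous future-use outcomes
#'
#' For each user: `any_use_28d` (any session in the 28 days after the
#' survey), `any_use_6mo` (any session in the 28-day window ending 6
#' months after the survey), and `high_duration_28d` (total session
#' duration in the 28-day window strictly above the cohort median of that
#' quantity; ties go to the low group). An outcome whose window is not
#' fully observed is `NA` (unavailable), never `FALSE`.
#'
#' @param sessions Validated session tibble.
#' @param survey Survey tibble (`user_id`, `survey_date`); defines the
#'   cohort, including users with no post-survey sessions.
#' @param observation_end Last observed date (defaults to the latest
#'   session date).
#' @param windows An [outcome_windows()] object.
#' @return A tibble with `user_id`, `any_use_28d`, `any_use_6mo`,
#'   `duration_28d`, `high_duration_28d`.
#' @export
future_use_outcomes <- function(sessions, survey, observation_end = NULL,
                                windows = outcome_windows()) {
  observation_end <- as.Date(observation_end %||%
                               max(.session_date(sessions$start)))
  sess <- sessions |>
    mutate(date = .session_date(.data$start)) |>
    inner_join(select(survey, all_of(c("user_id", "survey_date"))),
               by = "user_id") |>
    mutate(offset = as.integer(.data$date - .data$survey_date))

  in_window <- function(off, w) off > w[1] & off <= w[2]
  per_user <- sess |>
    group_by(.data$user_id) |>
    summarise(
      any_28 = any(in_window(.data$offset, windows$use_28d)),
      any_6mo = any(in_window(.data$offset, windows$use_6mo)),
      dur_28 = sum(.data$duration_min[in_window(.data$offset,
                                                windows$use_28d)]),
      .groups = "drop")

  out <- survey |>
    select(all_of(c("user_id", "survey_date"))) |>
    left_join(per_user, by = "user_id") |>
    mutate(
      any_28 = replace_na(.data$any_28, FALSE),
      any_6mo = replace_na(.data$any_6mo, FALSE),
      dur_28 = replace_na(.data$dur_28, 0),
      obs_28 = as.integer(observation_end - .data$survey_date) >=
        windows$use_28d[2],
      obs_6mo = as.integer(observation_end - .data$survey_date) >=
        windows$use_6mo[2],
      any_use_28d = ifelse(.data$obs_28, .data$any_28, NA),
      any_use_6mo = ifelse(.data$obs_6mo, .data$any_6mo, NA),
      duration_28d = ifelse(.data$obs_28, .data$dur_28, NA))
  med <- median(out$duration_28d, na.rm = TRUE)
  out$high_duration_28d <- ifelse(is.na(out$duration_28d), NA,
                                  out$duration_28d > med)
  out[, c("user_id", "any_use_28d", "any_use_6mo", "duration_28d",
          "high_duration_28d")]
}

#' Dichotomise the survey's health-benefit responses
#'
#' `improved_mental` is 1 if the respondent reported improvement on any
#' of the three mental health conditions; `improved_physical` is the same
#' OR over the physical conditions; likewise for `very_improved_*` (the
#' very-improved answers come from separate questions and do not imply,
#' nor are implied by, the improved answers). The `*_mental_only` flags
#' are mental AND NOT physical at the corresponding severity.
#'
#' @param survey Survey tibble from [read_survey()].
#' @return A tibble keyed by `user_id` with the seven benefit booleans.
#' @export
dichotomize_survey <- function(survey) {
  cond <- survey_conditions()
  or_over <- function(prefix, slots) {
    cols <- paste0(prefix, slots)
    as.logical(rowSums(as.data.frame(survey[cols])) > 0)
  }
  tibble(
    user_id = survey$user_id,
    improved_mental = or_over("improved_", cond$mental),
    improved_physical = or_over("improved_", cond$physical),
    very_improved_mental = or_over("very_improved_", cond$mental),
    very_improved_physical = or_over("very_improved_", cond$physical)
  ) |>
    mutate(
      improved_mental_only = .data$improved_mental &
        !.data$improved_physical,
      very_improved_mental_only = .data$very_improved_mental &
        !.data$very_improved_physical)
}
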