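#' Recognised session types
#'
#' The seven content categories a session can belong to.
#'
#' @return A character vector of length 7.
#' @export
session_types <- function() {
  c("meditation", "sleep_story", "breathe", "music",
    "soundscape", "masterclass", "body")
}

#' Named condition slots used by the survey table
#'
#' Survey respondents report, condition by condition, whether each listed
#' physical and mental health condition was improved (and separately, very
#' improved) since starting to use the app. These are the fixed slot names;
#' the survey CSV carries one `improved_<slot>` and one
#' `very_improved_<slot>` 0/1 column per slot.
#'
#' @return A list with elements `physical` and `mental`.
#' @export
survey_conditions <- function() {
  list(
    physical = c("hypertension", "high_cholesterol", "asthma", "emphysema",
                 "lung_disease", "heart_disease", "cancer", "pain",
                 "arthritis"),
    mental = c("anxiety", "ptsd", "depression")
  )
}

.survey_flag_cols <- function() {
  cond <- survey_conditions()
  all <- c(cond$physical, cond$mental)
  c(paste0("improved_", all), paste0("very_improved_", all))
}

.demographic_cols <- function() {
  c("age_band", "sex", "race", "income", "employment", "education")
}

.session_cols <- c("user_id", "start", "duration_min", "session_type",
                   "title", "completed")

#' Read a session log
#'
#' Reads a delimited session log into the canonical in-memory event table:
#' one row per app session with the user id, minute-precision start time,
#' duration in minutes, session type, content title and completion flag.
#' Seconds in the start timestamp are truncated to the minute on ingest,
#' and rows are sorted by user and start time, so ingest is insensitive to
#' the input row order.
#'
#' @param path Path to a delimited text file with a header row.
#' @param col_map Optional named character vector mapping canonical column
#'   names (`user_id`, `start`, `duration_min`, `session_type`, `title`,
#'   `completed`) to the names used in the file, for other dialects.
#' @param delim Field delimiter, `","` by default.
#' @return A tibble of validated sessions sorted by `(user_id, start)`.
#' @export
read_sessions <- function(path, col_map = NULL, delim = ",") {
  if (!file.exists(path)) stop("session log not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  missing <- setdiff(.session_cols, names(raw))
  if (length(missing) > 0) {
    stop("session log is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sessions <- tibble(
    user_id = as.character(raw$user_id),
    start = readr::parse_datetime(raw$start, locale = readr::locale(tz = .habit_tz)),
    duration_min = suppressWarnings(as.numeric(raw$duration_min)),
    session_type = as.character(raw$session_type),
    title = as.character(raw$title),
    completed = .parse_flag(raw$completed)
  )
  validate_sessions(sessions)
}

.parse_flag <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true", "T", "yes")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "F", "no")] <- FALSE
  out[is.na(x)] <- NA
  as.logical(out)
}

#' Validate (and canonicalise) a session table
#'
#' Enforces the event-model invariants: positive durations, one of the
#' seven recognised session types, parseable minute-resolution start
#' times. Seconds are discarded and rows are sorted by `(user_id, start)`.
#'
#' @param sessions A data frame with the canonical session columns.
#' @return The validated, sorted session tibble.
#' @export
validate_sessions <- function(sessions) {
  missing <- setdiff(.session_cols, names(sessions))
  if (length(missing) > 0) {
    stop("session table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(sessions$start))
  if (length(bad) > 0) {
    stop("unparseable start timestamp in row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(sessions$duration_min) | sessions$duration_min <= 0)
  if (length(bad) > 0) {
    stop("nonpositive or missing duration_min in row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!sessions$session_type %in% session_types())
  if (length(bad) > 0) {
    stop("unknown session_type in row(s): ",
         paste(head(bad, 5), collapse = ", "),
         " (values: ", paste(unique(sessions$session_type[head(bad, 5)]),
                             collapse = ", "), ")", call. = FALSE)
  }
  sessions$start <- .truncate_minute(sessions$start)
  sessions |>
    as_tibble() |>
    select(all_of(.session_cols)) |>
    arrange(.data$user_id, .data$start)
}

.truncate_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60,
             origin = "1970-01-01", tz = .habit_tz)
}

#' Write a session log
#'
#' Writes the canonical CSV dialect; [read_sessions()] on the result
#' returns an identical table (round-trip property).
#'
#' @param sessions A validated session tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  out <- sessions
  out$start <- format(out$start, "%Y-%m-%dT%H:%M:%S", tz = .habit_tz)
  out$completed <- as.integer(out$completed)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a survey table
#'
#' One row per user: survey completion date, demographic categories, and
#' per-condition improved / very-improved 0/1 flags (see
#' [survey_conditions()] for the slot names). The improved and
#' very-improved answers come from separate questions; no implication
#' between them is imposed.
#'
#' @param path Path to the survey CSV.
#' @return A tibble with one row per user; flags as logicals.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey table not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  required <- c("user_id", "survey_date", .demographic_cols(),
                .survey_flag_cols())
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("survey table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- unique(raw$user_id[duplicated(raw$user_id)])
  if (length(dup) > 0) {
    stop("duplicate user_id in survey table: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  date <- suppressWarnings(as.Date(raw$survey_date, format = "%Y-%m-%d"))
  if (anyNA(date)) {
    stop("unparseable survey_date in row(s): ",
         paste(head(which(is.na(date)), 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble(user_id = as.character(raw$user_id), survey_date = date)
  for (col in .demographic_cols()) out[[col]] <- as.character(raw[[col]])
  for (col in .survey_flag_cols()) {
    flag <- .parse_flag(raw[[col]])
    if (anyNA(flag)) {
      stop("survey flag column ", col, " must be coded 0/1", call. = FALSE)
    }
    out[[col]] <- flag
  }
  out
}

#' Write a survey table
#'
#' @param survey A survey tibble as returned by [read_survey()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  out <- survey
  for (col in .survey_flag_cols()) out[[col]] <- as.integer(out[[col]])
  out$survey_date <- format(out$survey_date, "%Y-%m-%d")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
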