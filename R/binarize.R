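#' Minute-level coverage table for a session log
#'
#' Expands sessions onto the minute grid. A session starting at clock
#' minute `s` with duration `d` covers the half-open minute interval
#' `[s, s + ceiling(d))`; sessions crossing midnight cover trailing
#' minutes of their start day and leading minutes of the next calendar
#' day. Overlapping sessions cover each minute once (binary semantics).
#'
#' @param sessions A validated session tibble.
#' @param type_filter Optional session type; only sessions of that type
#'   contribute.
#' @param by_type If `TRUE`, keep one row per `(user, minute, type)` so the
#'   result can be filtered by type later; minutes covered by two types
#'   appear once per type.
#' @return A tibble with columns `user_id`, `date`, `minute` (0-1439) and,
#'   if `by_type`, `session_type`.
#' @export
minute_coverage <- function(sessions, type_filter = NULL, by_type = FALSE) {
  s <- sessions
  if (!is.null(type_filter)) {
    if (!all(type_filter %in% session_types())) {
      stop("unknown session type: ",
           paste(setdiff(type_filter, session_types()), collapse = ", "),
           call. = FALSE)
    }
    s <- s[s$session_type %in% type_filter, , drop = FALSE]
  }
  n <- nrow(s)
  if (n == 0) {
    out <- tibble(user_id = character(), date = as.Date(character()),
                  minute = integer())
    if (by_type) out$session_type <- character()
    return(out)
  }
  n_min <- as.integer(ceiling(s$duration_min))
  start_abs <- floor(as.numeric(s$start) / 60)  # absolute minute index
  abs_min <- rep(start_abs, n_min) + sequence(n_min) - 1
  out <- tibble(
    user_id = rep(s$user_id, n_min),
    abs_min = abs_min
  )
  if (by_type) {
    out$session_type <- rep(s$session_type, n_min)
    out <- distinct(out, .data$user_id, .data$abs_min, .data$session_type)
  } else {
    out <- distinct(out, .data$user_id, .data$abs_min)
  }
  out$date <- as.Date(out$abs_min %/% 1440, origin = "1970-01-01")
  out$minute <- as.integer(out$abs_min %% 1440)
  out$abs_min <- NULL
  cols <- c("user_id", "date", "minute", if (by_type) "session_type")
  out[, cols]
}

#' Build a 1440-minute binary day vector
#'
#' Minute `m` (0-based clock minute; index 1 of the vector is 00:00,
#' index 1440 is 23:59) is 1 iff some session - optionally restricted to
#' one session type - covers that minute of the given calendar date.
#'
#' @param sessions A validated session tibble.
#' @param user_id The user.
#' @param date The calendar date (`Date` or string).
#' @param type_filter Optional session type restriction.
#' @return An integer vector of length 1440 with attributes `user_id`,
#'   `date` and `stratum`.
#' @export
build_day_vector <- function(sessions, user_id, date, type_filter = NULL) {
  date <- as.Date(date)
  cov <- minute_coverage(sessions[sessions$user_id == user_id, , drop = FALSE],
                         type_filter = type_filter)
  v <- integer(1440)
  v[cov$minute[cov$date == date] + 1L] <- 1L
  structure(v, user_id = user_id, date = date,
            stratum = type_filter %||% "all")
}

#' Number of used minutes in a day vector
#'
#' @param day_vector An integer/logical vector on the 1440-minute grid.
#' @return The number of minutes with use.
#' @export
used_minutes <- function(day_vector) sum(day_vector > 0)

#' Assign a session start time to a timing stratum
#'
#' Morning is 4 AM to 12 PM, Evening 12 PM to 8 PM, and Night 8 PM to
#' 4 AM the next day; the three windows partition the clock. Sessions
#' starting between midnight and 4 AM belong to the previous calendar
#' day's Night window for counting purposes (see [timing_stratum_date()]);
#' the minutes they cover stay on their own calendar day in the day
#' vectors used for DTW.
#'
#' @param start POSIXct vector of session start times.
#' @return Character vector: `"Morning"`, `"Evening"` or `"Night"`.
#' @export
assign_timing_stratum <- function(start) {
  minute <- floor(as.numeric(start) / 60) %% 1440
  out <- rep("Night", length(minute))
  out[minute >= 240 & minute < 720] <- "Morning"
  out[minute >= 720 & minute < 1200] <- "Evening"
  out
}

#' Calendar day a session is attributed to for timing-stratified counts
#'
#' Identity except for starts in `[00:00, 04:00)`, which are attributed to
#' the previous day (the tail of that day's Night window).
#'
#' @param start POSIXct vector of session start times.
#' @return A `Date` vector.
#' @export
timing_stratum_date <- function(start) {
  abs_min <- floor(as.numeric(start) / 60)
  day <- abs_min %/% 1440
  early <- (abs_min %% 1440) < 240
  as.Date(day - as.integer(early), origin = "1970-01-01")
}

#' Weekday/weekend label for a date
#'
#' @param date A `Date` vector.
#' @return `"weekend"` for Saturday and Sunday, `"weekday"` otherwise.
#' @export
weekday_weekend_label <- function(date) {
  ifelse(format(as.Date(date), "%u") %in% c("6", "7"), "weekend", "weekday")
}

#' Render a day vector as a 0/1 string (debug aid)
#'
#' @param day_vector An integer vector on the 1440-minute grid.
#' @return A single 1440-character string of 0s and 1s.
#' @export
format_day_vector <- function(day_vector) {
  paste(as.integer(day_vector > 0), collapse = "")
}
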