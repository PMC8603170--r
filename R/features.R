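#' Per-user observation start date
#'
#' A user's analysis clock starts on the first Monday strictly after the
#' earliest date at which some trailing 14-day window contains at least 5
#' distinct days with any use. Users who never accumulate 5 use-days
#' within a 14-day span are excluded (the function returns `NA`).
#'
#' @param sessions Either a validated session tibble for one user, or a
#'   `Date` vector of use days.
#' @return A `Date` (always a Monday), or `NA` if the user never
#'   qualifies.
#' @export
compute_start_date <- function(sessions) {
  if (inherits(sessions, "Date")) {
    dates <- sessions
  } else {
    if (nrow(sessions) == 0) stop("user has no sessions", call. = FALSE)
    if (length(unique(sessions$user_id)) > 1) {
      stop("compute_start_date expects sessions for a single user",
           call. = FALSE)
    }
    dates <- .session_date(sessions$start)
  }
  if (length(dates) == 0) stop("user has no sessions", call. = FALSE)
  d <- sort(unique(dates))
  if (length(d) >= 5) {
    # d[i] qualifies if the window [d[i]-13, d[i]] holds 5 distinct use days
    span <- as.integer(d[-(1:4)] - d[seq_len(length(d) - 4)])
    ok <- which(span <= 13L)
    if (length(ok) > 0) {
      q <- d[ok[1] + 4L]
      u <- as.integer(format(q, "%u"))   # Monday = 1
      return(q + (8L - u))               # first Monday strictly after q
    }
  }
  as.Date(NA)
}

.session_date <- function(start) {
  as.Date(floor(as.numeric(start) / 60) %/% 1440, origin = "1970-01-01")
}

#' Build the 10 analysis intervals for one user
#'
#' Consecutive, nonoverlapping 14-day intervals aligned to the user's
#' Monday start date. The pre-survey intervals are the maximal whole
#' 14-day blocks ending on or before the survey date; when more than
#' `n_intervals` fit, the `n_intervals` closest to the survey are kept
#' (so interval 10 is always the one closest to the outcomes), and when
#' fewer fit, padding intervals continue immediately after and are
#' flagged `is_post_survey`.
#'
#' @param start_date The user's Monday start date.
#' @param survey_date Survey completion date (must be after `start_date`).
#' @param sessions_end Last observed date; the final interval must end on
#'   or before it.
#' @param n_intervals Number of intervals (default 10, i.e. 140 days).
#' @return A tibble with `interval_index` (1..n, n = closest to survey),
#'   `start`, `end`, `is_post_survey`.
#' @export
build_intervals <- function(start_date, survey_date, sessions_end,
                            n_intervals = 10) {
  start_date <- as.Date(start_date)
  survey_date <- as.Date(survey_date)
  sessions_end <- as.Date(sessions_end)
  if (format(start_date, "%u") != "1") {
    stop("start_date must be a Monday", call. = FALSE)
  }
  if (survey_date <= start_date) {
    stop("survey_date must be after start_date", call. = FALSE)
  }
  k_pre <- (as.integer(survey_date - start_date) + 1L) %/% 14L
  offset <- max(0L, k_pre - as.integer(n_intervals))
  starts <- start_date + 14L * (offset + seq_len(n_intervals) - 1L)
  ends <- starts + 13L
  if (ends[n_intervals] > sessions_end) {
    stop("observation ends ",
         as.integer(ends[n_intervals] - sessions_end),
         " day(s) too early to fit ", n_intervals, " intervals",
         call. = FALSE)
  }
  tibble(interval_index = seq_len(n_intervals), start = starts, end = ends,
         is_post_survey = ends > survey_date)
}

#' Intervals for every user in a cohort
#'
#' Applies the start-date rule and [build_intervals()] per user. Users
#' who never qualify under the start-date rule, or whose observation span
#' cannot hold the required intervals, are excluded and reported in the
#' `exclusions` attribute of the result.
#'
#' @param sessions Validated session tibble (all users).
#' @param survey Survey tibble with `user_id` and `survey_date`.
#' @param sessions_end Last observed date; defaults to the latest session
#'   date in the log.
#' @param n_intervals Number of intervals per user.
#' @return A tibble of per-user intervals (`user_id`, `interval_index`,
#'   `start`, `end`, `is_post_survey`) with attribute `exclusions`, a
#'   tibble of `user_id` and `reason`.
#' @export
user_intervals <- function(sessions, survey, sessions_end = NULL,
                           n_intervals = 10) {
  sessions_end <- as.Date(sessions_end %||% max(.session_date(sessions$start)))
  users <- survey$user_id
  out <- vector("list", length(users))
  excl <- list()
  sess_split <- split(.session_date(sessions$start), sessions$user_id)
  for (k in seq_along(users)) {
    u <- users[k]
    dates <- sess_split[[u]]
    if (is.null(dates)) {
      excl[[length(excl) + 1]] <- tibble(user_id = u, reason = "no_sessions")
      next
    }
    sd <- compute_start_date(dates)
    if (is.na(sd)) {
      excl[[length(excl) + 1]] <- tibble(user_id = u,
                                         reason = "insufficient_use")
      next
    }
    iv <- tryCatch(
      build_intervals(sd, survey$survey_date[k], sessions_end, n_intervals),
      error = function(e) NULL)
    if (is.null(iv)) {
      excl[[length(excl) + 1]] <- tibble(user_id = u,
                                         reason = "observation_too_short")
      next
    }
    iv$user_id <- u
    out[[k]] <- iv
  }
  res <- bind_rows(out)
  if (nrow(res) > 0) {
    res <- res[, c("user_id", "interval_index", "start", "end",
                   "is_post_survey")]
  }
  attr(res, "exclusions") <- bind_rows(excl) %||%
    tibble(user_id = character(), reason = character())
  if (length(excl) == 0) {
    attr(res, "exclusions") <- tibble(user_id = character(),
                                      reason = character())
  }
  res
}

.stratum_types <- function() {
  c("all", "session_type", "timing", "weekpart", "session_type_weekpart")
}

#' Objective app-use measures per user, interval and stratum
#'
#' For every user x 14-day interval x stratum, computes the number of
#' days with any use, the total number of sessions, the number of unique
#' titles, the total duration (minutes, summed session durations), and the
#' mean normalised DTW distance of [interval_temporal_similarity()].
#'
#' Strata:
#' * `"all"`: every session; DTW over the 13 consecutive-day pairs.
#' * `"session_type"`: one stratum per session type; DTW on type-filtered
#'   day vectors.
#' * `"timing"`: Morning / Evening / Night by session start time, with
#'   00:00-03:59 starts attributed to the previous day's Night window;
#'   counts and durations only (`dtw_mean` is `NA`).
#' * `"weekpart"`: weekday vs weekend; DTW uses only within-stratum
#'   consecutive calendar-day pairs (Mon-Tue .. Thu-Fri and Sat-Sun), and
#'   the normalising mean daily duration is the stratum total divided by
#'   the number of stratum days.
#' * `"session_type_weekpart"`: the session-type by weekday/weekend cross.
#'
#' @param sessions Validated session tibble.
#' @param intervals Per-user intervals from [user_intervals()].
#' @param strata Which stratum families to compute (see above).
#' @param cfg A [dtw_config()].
#' @return A tidy tibble with columns `user_id`, `interval_index`,
#'   `is_post_survey`, `stratum_type`, `stratum`, `days_any_use`,
#'   `total_sessions`, `unique_titles`, `total_duration`, `dtw_mean`,
#'   `dtw_penalty_pairs`.
#' @export
aggregate_features <- function(sessions, intervals,
                               strata = c("all", "session_type", "timing",
                                          "weekpart"),
                               cfg = dtw_config()) {
  strata <- match.arg(strata, .stratum_types(), several.ok = TRUE)
  if (nrow(intervals) == 0) stop("no intervals supplied", call. = FALSE)

  sess <- sessions |>
    semi_join(distinct(intervals, .data$user_id), by = "user_id") |>
    mutate(date_cal = .session_date(.data$start),
           date_timing = timing_stratum_date(.data$start),
           timing = assign_timing_stratum(.data$start),
           weekpart = weekday_weekend_label(.data$date_cal))

  anchors <- intervals |>
    group_by(.data$user_id) |>
    summarise(first_start = min(.data$start),
              first_index = .data$interval_index[which.min(.data$start)],
              last_end = max(.data$end), .groups = "drop")

  assign_iv <- function(df, date_col) {
    df |>
      inner_join(anchors, by = "user_id") |>
      mutate(interval_index = .data$first_index +
               as.integer(as.integer(.data[[date_col]] - .data$first_start) %/% 14L)) |>
      filter(.data[[date_col]] >= .data$first_start,
             .data[[date_col]] <= .data$last_end)
  }

  count_block <- function(df, date_col, extra_groups, stratum_label) {
    grouped <- df |>
      group_by(.data$user_id, .data$interval_index,
               across(all_of(extra_groups))) |>
      summarise(days_any_use = n_distinct(.data[[date_col]]),
                total_sessions = n(),
                unique_titles = n_distinct(.data$title),
                total_duration = sum(.data$duration_min),
                .groups = "drop")
    grouped$stratum <- stratum_label(grouped)
    grouped |> select(-all_of(extra_groups))
  }

  grid_for <- function(stratum_type, stratum_values) {
    intervals |>
      select(all_of(c("user_id", "interval_index", "is_post_survey"))) |>
      tidyr::crossing(stratum = stratum_values) |>
      mutate(stratum_type = stratum_type)
  }

  blocks <- list()
  cal <- assign_iv(sess, "date_cal")
  tim <- if ("timing" %in% strata) assign_iv(sess, "date_timing") else NULL

  if ("all" %in% strata) {
    blocks$all <- grid_for("all", "all") |>
      left_join(count_block(cal, "date_cal", character(),
                            function(g) "all"),
                by = c("user_id", "interval_index", "stratum"))
  }
  if ("session_type" %in% strata) {
    blocks$session_type <- grid_for("session_type", session_types()) |>
      left_join(count_block(cal, "date_cal", "session_type",
                            function(g) g$session_type),
                by = c("user_id", "interval_index", "stratum"))
  }
  if ("timing" %in% strata) {
    blocks$timing <- grid_for("timing", c("Morning", "Evening", "Night")) |>
      left_join(count_block(tim, "date_timing", "timing",
                            function(g) g$timing),
                by = c("user_id", "interval_index", "stratum"))
  }
  if ("weekpart" %in% strata) {
    blocks$weekpart <- grid_for("weekpart", c("weekday", "weekend")) |>
      left_join(count_block(cal, "date_cal", "weekpart",
                            function(g) g$weekpart),
                by = c("user_id", "interval_index", "stratum"))
  }
  if ("session_type_weekpart" %in% strata) {
    grid <- grid_for("session_type_weekpart",
                     paste(rep(session_types(), each = 2),
                           c("weekday", "weekend"), sep = ":"))
    blocks$session_type_weekpart <- grid |>
      left_join(count_block(cal, "date_cal", c("session_type", "weekpart"),
                            function(g) paste(g$session_type, g$weekpart,
                                              sep = ":")),
                by = c("user_id", "interval_index", "stratum"))
  }

  feats <- bind_rows(blocks) |>
    mutate(across(c("days_any_use", "total_sessions", "unique_titles"),
                  ~ as.integer(replace_na(.x, 0L))),
           total_duration = replace_na(.data$total_duration, 0))

  dtw <- .dtw_features(sess, intervals, strata, cfg)
  feats <- feats |>
    left_join(dtw, by = c("user_id", "interval_index", "stratum_type",
                          "stratum")) |>
    arrange(.data$user_id, .data$interval_index, .data$stratum_type,
            .data$stratum)
  feats[, c("user_id", "interval_index", "is_post_survey", "stratum_type",
            "stratum", "days_any_use", "total_sessions", "unique_titles",
            "total_duration", "dtw_mean", "dtw_penalty_pairs")]
}

# DTW features for the stratum families that define them. Timing strata
# get none: their windows cross midnight while the DTW series is a
# per-calendar-day vector.
.dtw_features <- function(sess, intervals, strata, cfg) {
  want_all <- "all" %in% strata
  want_type <- "session_type" %in% strata
  want_wp <- "weekpart" %in% strata
  want_twp <- "session_type_weekpart" %in% strata
  if (!(want_all || want_type || want_wp || want_twp)) {
    return(tibble(user_id = character(), interval_index = integer(),
                  stratum_type = character(), stratum = character(),
                  dtw_mean = numeric(), dtw_penalty_pairs = integer()))
  }
  cov <- minute_coverage(sess, by_type = TRUE)
  cov_split <- split(cov, cov$user_id)
  iv_split <- split(intervals, intervals$user_id)
  res <- vector("list", length(iv_split))
  consec <- cbind(1:13, 2:14)
  for (u_idx in seq_along(iv_split)) {
    iv <- iv_split[[u_idx]]
    u <- iv$user_id[1]
    cu <- cov_split[[u]]
    acc_iv <- integer(0); acc_stype <- character(0)
    acc_stratum <- character(0); acc_mean <- numeric(0)
    acc_pen <- integer(0)
    for (k in seq_len(nrow(iv))) {
      d0 <- iv$start[k]
      dates <- d0 + 0:13
      lab <- weekday_weekend_label(dates)
      sub <- if (is.null(cu)) NULL else
        cu[cu$date >= d0 & cu$date <= iv$end[k], , drop = FALSE]
      emit <- function(stype, stratum, stats) {
        acc_iv[length(acc_iv) + 1L] <<- iv$interval_index[k]
        acc_stype[length(acc_stype) + 1L] <<- stype
        acc_stratum[length(acc_stratum) + 1L] <<- stratum
        acc_mean[length(acc_mean) + 1L] <<- stats$mean
        acc_pen[length(acc_pen) + 1L] <<- stats$n_penalty
      }
      mk_mat <- function(rows_df) {
        mat <- matrix(0L, 14, 1440)
        if (!is.null(rows_df) && nrow(rows_df) > 0) {
          mat[cbind(as.integer(rows_df$date - d0) + 1L,
                    rows_df$minute + 1L)] <- 1L
        }
        mat
      }
      wp_stats <- function(mat, which_lab) {
        idx <- which(lab == which_lab)
        prs <- consec[lab[consec[, 1]] == which_lab &
                      lab[consec[, 2]] == which_lab, , drop = FALSE]
        mdd <- sum(mat[idx, ]) / length(idx)
        .pairs_stats(mat, prs, mdd, cfg)
      }
      if (want_all || want_wp) {
        mat <- mk_mat(sub)
        if (want_all) {
          emit("all", "all", .pairs_stats(mat, consec, sum(mat) / 14, cfg))
        }
        if (want_wp) {
          emit("weekpart", "weekday", wp_stats(mat, "weekday"))
          emit("weekpart", "weekend", wp_stats(mat, "weekend"))
        }
      }
      if (want_type || want_twp) {
        for (tp in session_types()) {
          sub_t <- if (is.null(sub)) NULL else
            sub[sub$session_type == tp, , drop = FALSE]
          mat_t <- mk_mat(sub_t)
          if (want_type) {
            emit("session_type", tp,
                 .pairs_stats(mat_t, consec, sum(mat_t) / 14, cfg))
          }
          if (want_twp) {
            emit("session_type_weekpart", paste(tp, "weekday", sep = ":"),
                 wp_stats(mat_t, "weekday"))
            emit("session_type_weekpart", paste(tp, "weekend", sep = ":"),
                 wp_stats(mat_t, "weekend"))
          }
        }
      }
    }
    res[[u_idx]] <- tibble(user_id = u, interval_index = acc_iv,
                           stratum_type = acc_stype, stratum = acc_stratum,
                           dtw_mean = acc_mean, dtw_penalty_pairs = acc_pen)
  }
  bind_rows(res)
}

# Mean normalised distance plus penalty provenance over given row pairs.
# Semantically identical to looping pair_distance() over the rows
# (asserted by a property test), but hoists the per-day bookkeeping -
# used minutes, 1-run counts, boundary occupancy - out of the pair loop
# so the interval sweep only pays for genuine dynamic-programming calls.
.pairs_stats <- function(mat, pairs, mdd, cfg) {
  if (sum(mat) == 0) {
    # every pair is an empty pair; with zero mean daily duration the
    # normalised value is 0 by the degenerate rule
    return(list(mean = 0, n_penalty = nrow(pairs)))
  }
  if (!is.null(cfg$window)) {
    # windowed DTW has no shortcut structure; take the plain path
    vals <- numeric(nrow(pairs)); pen <- 0L
    for (k in seq_len(nrow(pairs))) {
      pd <- pair_distance(mat[pairs[k, 1], ], mat[pairs[k, 2], ], mdd, cfg)
      vals[k] <- pd$normalized
      if (pd$penalty_applied != "none") pen <- pen + 1L
    }
    return(list(mean = mean(vals), n_penalty = pen))
  }
  storage.mode(pairs) <- "integer"
  interval_pairs_cpp(mat, pairs, mdd, cfg$empty_pair_k)
}

#' Log-transform app-use measures
#'
#' Applies `x -> log(x + offset)` (default offset 1, i.e. `log1p`) to the
#' measure columns, so that logistic-model coefficients read as the
#' association with a relative (percentage) increase in the measure while
#' true zeros remain defined. The offset is recorded in the
#' `log_offset` attribute.
#'
#' @param features A feature tibble (from [aggregate_features()] or any
#'   data frame with the named measure columns).
#' @param measures Columns to transform.
#' @param offset Positive constant added before taking logs.
#' @return The transformed tibble with attribute `log_offset`.
#' @export
log_transform <- function(features,
                          measures = c("days_any_use", "total_sessions",
                                       "total_duration", "dtw_mean"),
                          offset = 1) {
  measures <- intersect(measures, names(features))
  for (col in measures) {
    x <- features[[col]]
    if (any(x < 0, na.rm = TRUE)) {
      stop("negative values in ", col, " cannot be log-transformed",
           call. = FALSE)
    }
    features[[col]] <- log(x + offset)
  }
  attr(features, "log_offset") <- offset
  features
}
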