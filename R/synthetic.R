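#' Synthetic cohort configuration
#'
#' Parameters of the seeded generator that emulates the statistical
#' structure the analysis assumes: a latent habit strength `h` in `[0,1]`
#' per user drives (a) how often the app is used, (b) how temporally
#' concentrated use is around a personal cue time, (c) whether use
#' persists after the survey, and (d) the odds of reporting mental-health
#' improvement.
#'
#' Mechanisms, each linear in `h`:
#' * daily use: a two-state Markov chain with marginal probability
#'   `p(h) = p0 + h (p1 - p0)` and day-to-day autocorrelation
#'   `rho(h) = rho0 + h (rho1 - rho0)`, so habitual users use the app
#'   both more often and in steadier streaks (`rho0 = rho1 = 0` recovers
#'   independent Bernoulli days);
#' * cue timing: one cue session per use day at clock minute
#'   `mu + N(0, sigma(h))` with `sigma(h) = sigma_max - h (sigma_max -
#'   sigma_min)`; the draw may overshoot midnight, in which case the
#'   session simply lands on the adjacent calendar day (late-night cues
#'   with loose timing genuinely scatter use across day boundaries);
#' * scattered extra sessions: `Poisson(lambda(h))` additional sessions
#'   per use day at uniform clock times, with `lambda(h) = scatter0 -
#'   h (scatter0 - scatter1)`, so weak-habit use is more fragmented;
#' * persistence: post-survey use continues with probability
#'   `plogis(persist_a0 + persist_a1 h)`;
#' * benefit: each mental-condition improved flag is Bernoulli
#'   `plogis(benefit_b0 + benefit_b1 h)` (very-improved flags use the
#'   `very_*` intercept/slope); physical flags have constant base rates.
#'
#' @param n_users Number of users.
#' @param survey_date Common survey completion date.
#' @param days_pre,days_post Observation span around the survey, days.
#' @param habit_shape1,habit_shape2 Beta parameters of the habit
#'   distribution (1,1 = uniform).
#' @param cue_mix Named probabilities of the cue falling in the Morning,
#'   Evening or Night clock window.
#' @param sigma_min,sigma_max Cue-time jitter SD range, minutes.
#' @param p0,p1 Daily-use probability at `h = 0` and `h = 1`.
#' @param rho0,rho1 Day-to-day use autocorrelation at `h = 0` and `h = 1`.
#' @param scatter0,scatter1 Mean extra sessions per use day at `h = 0`
#'   and `h = 1`.
#' @param duration_meanlog,duration_sdlog Log-normal session duration
#'   parameters, minutes.
#' @param type_probs Named session-type mixture (the user's habitual cue
#'   type is drawn once from it; extra sessions draw independently).
#' @param persist_a0,persist_a1 Persistence logit intercept and slope.
#' @param benefit_b0,benefit_b1 Mental-improvement logit intercept/slope.
#' @param very_b0,very_b1 Very-improved logit intercept/slope.
#' @param phys_b0,phys_very_b0 Physical-flag logit intercepts (constant).
#' @param completed_prob Probability a session is flagged completed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_users = 500,
                          survey_date = as.Date("2019-12-01"),
                          days_pre = 182, days_post = 182,
                          habit_shape1 = 1, habit_shape2 = 1,
                          cue_mix = c(Morning = 0.35, Evening = 0.35,
                                      Night = 0.30),
                          sigma_min = 10, sigma_max = 150,
                          p0 = 0.5, p1 = 0.8,
                          rho0 = 0, rho1 = 0.85,
                          scatter0 = 0.2, scatter1 = 0,
                          duration_meanlog = log(10),
                          duration_sdlog = 0.6,
                          type_probs = c(meditation = 0.35,
                                         sleep_story = 0.30, breathe = 0.10,
                                         music = 0.08, soundscape = 0.07,
                                         masterclass = 0.05, body = 0.05),
                          persist_a0 = -1.75, persist_a1 = 3.5,
                          benefit_b0 = -2.5, benefit_b1 = 2,
                          very_b0 = -3.5, very_b1 = 2.5,
                          phys_b0 = -3.5, phys_very_b0 = -4.5,
                          completed_prob = 0.8) {
  cfg <- as.list(environment())
  if (!(p0 >= 0 && p0 <= p1 && p1 <= 1)) {
    stop("need 0 <= p0 <= p1 <= 1", call. = FALSE)
  }
  if (sigma_min < 0 || sigma_max < sigma_min) {
    stop("need 0 <= sigma_min <= sigma_max", call. = FALSE)
  }
  if (any(c(rho0, rho1) < 0) || any(c(rho0, rho1) >= 1)) {
    stop("autocorrelations must be in [0, 1)", call. = FALSE)
  }
  if (any(c(scatter0, scatter1) < 0)) {
    stop("scatter rates must be nonnegative", call. = FALSE)
  }
  if (!setequal(names(cfg$cue_mix), c("Morning", "Evening", "Night")) ||
      abs(sum(cfg$cue_mix) - 1) > 1e-8 || any(cfg$cue_mix < 0)) {
    stop("cue_mix must be probabilities over Morning/Evening/Night",
         call. = FALSE)
  }
  if (!setequal(names(cfg$type_probs), session_types()) ||
      abs(sum(cfg$type_probs) - 1) > 1e-8 || any(cfg$type_probs < 0)) {
    stop("type_probs must be probabilities over the 7 session types",
         call. = FALSE)
  }
  if (completed_prob < 0 || completed_prob > 1) {
    stop("completed_prob must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Clock windows the cue time mu is drawn from (minutes). Night cues may
# fall up to 2 AM "next day" (minutes >= 1440), so a loosely timed night
# cue naturally scatters sessions across the midnight boundary.
.cue_windows <- list(Morning = c(240, 719), Evening = c(720, 1199),
                     Night = c(1200, 1559))

#' Generate a synthetic cohort
#'
#' Draws a full cohort under a [cohort_config()]: a session log, a survey
#' table and the latent ground truth. Fully reproducible: the same
#' config and seed give byte-identical outputs.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer RNG seed.
#' @return A list with `sessions` (validated session tibble), `survey`
#'   (survey tibble in the [read_survey()] schema) and `ground_truth`
#'   (per-user latent draws: habit, cue minute and stratum, jitter SD,
#'   daily-use probability, autocorrelation, scatter rate, persistence).
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  n <- cfg$n_users
  user_id <- sprintf("u%05d", seq_len(n))
  h <- rbeta(n, cfg$habit_shape1, cfg$habit_shape2)
  cue_stratum <- sample(names(cfg$cue_mix), n, replace = TRUE,
                        prob = cfg$cue_mix)
  lo <- vapply(.cue_windows[cue_stratum], `[`, 0, 1)
  hi <- vapply(.cue_windows[cue_stratum], `[`, 0, 2)
  mu <- floor(runif(n, lo, hi + 1))
  sigma <- cfg$sigma_max - h * (cfg$sigma_max - cfg$sigma_min)
  p <- cfg$p0 + h * (cfg$p1 - cfg$p0)
  rho <- cfg$rho0 + h * (cfg$rho1 - cfg$rho0)
  lambda <- cfg$scatter0 - h * (cfg$scatter0 - cfg$scatter1)
  persist <- rbinom(n, 1, plogis(cfg$persist_a0 + cfg$persist_a1 * h)) == 1
  cue_type <- sample(names(cfg$type_probs), n, replace = TRUE,
                     prob = cfg$type_probs)

  day0 <- cfg$survey_date - cfg$days_pre + 1
  n_days <- cfg$days_pre + cfg$days_post
  dates <- day0 + seq_len(n_days) - 1
  post_survey <- dates > cfg$survey_date

  # two-state Markov chain per user, started at stationarity
  use <- matrix(FALSE, n, n_days)
  use[, 1] <- runif(n) < p
  for (d in 2:n_days) {
    p_cond <- ifelse(use[, d - 1], p + rho * (1 - p), p * (1 - rho))
    use[, d] <- runif(n) < p_cond
  }
  use[, post_survey] <- use[, post_survey] & persist

  idx <- which(use, arr.ind = TRUE)
  u_i <- idx[, 1]
  day_num <- as.integer(dates[idx[, 2]])
  # cue session, jitter may cross midnight in either direction
  cue_abs <- day_num * 1440 + round(rnorm(length(u_i), mu[u_i], sigma[u_i]))
  cue <- tibble(user = u_i, abs_min = cue_abs, session_type = cue_type[u_i])
  # scattered extra sessions at uniform clock times
  n_extra <- rpois(length(u_i), lambda[u_i])
  ue <- rep(u_i, n_extra)
  extra <- tibble(
    user = ue,
    abs_min = rep(day_num, n_extra) * 1440 +
      floor(runif(length(ue), 0, 1440)),
    session_type = sample(names(cfg$type_probs), length(ue),
                          replace = TRUE, prob = cfg$type_probs))
  ev <- bind_rows(cue, extra)
  ev$duration_min <- round(rlnorm(nrow(ev), cfg$duration_meanlog,
                                  cfg$duration_sdlog), 1)
  ev$duration_min <- pmax(ev$duration_min, 0.5)
  sessions <- tibble(
    user_id = user_id[ev$user],
    start = as.POSIXct(ev$abs_min * 60, origin = "1970-01-01",
                       tz = .habit_tz),
    duration_min = ev$duration_min,
    session_type = ev$session_type,
    title = paste0(ev$session_type, "_",
                   sprintf("%02d", 1 + (ev$abs_min %% 12))),
    completed = runif(nrow(ev)) < cfg$completed_prob)
  sessions <- validate_sessions(sessions)

  survey <- .synthetic_survey(user_id, h, cfg)
  ground_truth <- tibble(user_id = user_id, habit = h,
                         cue_stratum = cue_stratum, cue_minute = mu,
                         sigma = sigma, p_daily = p, rho = rho,
                         scatter = lambda, persist = persist,
                         cue_type = cue_type)
  list(sessions = sessions, survey = survey, ground_truth = ground_truth)
}

.synthetic_survey <- function(user_id, h, cfg) {
  n <- length(user_id)
  cond <- survey_conditions()
  out <- tibble(
    user_id = user_id,
    survey_date = format(cfg$survey_date, "%Y-%m-%d"),
    age_band = sample(c("18-29", "30-44", "45-59", "60+"), n, TRUE,
                      prob = c(0.15, 0.30, 0.30, 0.25)),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.86, 0.14)),
    race = sample(c("white", "other"), n, TRUE, prob = c(0.86, 0.14)),
    income = sample(c("under_60k", "over_60k"), n, TRUE,
                    prob = c(0.39, 0.61)),
    employment = sample(c("full_time", "other"), n, TRUE,
                        prob = c(0.61, 0.39)),
    education = sample(c("college", "no_college"), n, TRUE,
                       prob = c(0.73, 0.27)))
  p_ment <- plogis(cfg$benefit_b0 + cfg$benefit_b1 * h)
  p_very <- plogis(cfg$very_b0 + cfg$very_b1 * h)
  for (cn in cond$mental) {
    out[[paste0("improved_", cn)]] <- rbinom(n, 1, p_ment)
    out[[paste0("very_improved_", cn)]] <- rbinom(n, 1, p_very)
  }
  for (cn in cond$physical) {
    out[[paste0("improved_", cn)]] <- rbinom(n, 1, plogis(cfg$phys_b0))
    out[[paste0("very_improved_", cn)]] <-
      rbinom(n, 1, plogis(cfg$phys_very_b0))
  }
  out$survey_date <- as.Date(out$survey_date)
  for (col in .survey_flag_cols()) out[[col]] <- out[[col]] == 1
  # canonical column order, matching what read_survey() returns
  out[, c("user_id", "survey_date", .demographic_cols(),
          .survey_flag_cols())]
}

#' Two-day worked example: shifted equal blocks
#'
#' Two 1440-minute day vectors, each with one interior contiguous
#' 2-minute block of use, the blocks disjoint in time (day B's use is
#' shifted 100 minutes later). Their Euclidean distance is 2 (four
#' differing minutes) while their DTW distance is 0: warping absorbs the
#' shift completely. This is the canonical illustration of why the
#' temporal-similarity statistic uses DTW rather than a rigid
#' minute-by-minute comparison.
#'
#' @return A list with `day_a` and `day_b`, each a 1440-length binary
#'   integer vector.
#' @export
figure1_fixture <- function() {
  day_a <- integer(1440); day_a[601:602] <- 1L   # 10:00-10:01
  day_b <- integer(1440); day_b[701:702] <- 1L   # 11:40-11:41
  list(day_a = day_a, day_b = day_b)
}
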