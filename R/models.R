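#' Logistic regression odds-ratio table
#'
#' Maximum-likelihood logistic fit of a dichotomous outcome on the given
#' predictors and controls; odds ratios are exponentiated coefficients
#' with Wald 95% confidence intervals `exp(coef +/- 1.96 * SE)`.
#' Predictors are expected on the log scale (see [log_transform()]) so an
#' OR reads as the change in odds per relative increase in the measure.
#' Separation (non-convergence or exploding standard errors) is flagged,
#' never silently reported.
#'
#' @param data A data frame holding the outcome, predictors and controls.
#' @param outcome Name of a logical/0-1 outcome column (both classes must
#'   be present).
#' @param predictors Character vector of predictor column names.
#' @param controls Character vector of control column names (reported but
#'   marked `is_control`).
#' @return A tibble of class `or_table`: `term`, `or`, `conf_low`,
#'   `conf_high`, `p_value`, `is_control`, `flagged`; attributes
#'   `outcome`, `n`, `separation` and `fit` (the trimmed `glm` object).
#' @export
fit_logistic_or <- function(data, outcome, predictors,
                            controls = character()) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2) {
    stop("outcome ", outcome, " has a single class", call. = FALSE)
  }
  vars <- c(predictors, controls)
  if (nrow(data) <= length(vars)) {
    stop("more predictors than observations", call. = FALSE)
  }
  df <- data[, vars, drop = FALSE]
  df$.y <- y
  fml <- as.formula(paste(".y ~", paste(sprintf("`%s`", vars),
                                        collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  sm <- sm[terms, , drop = FALSE]
  est <- sm[, 1]; se <- sm[, 2]; p <- sm[, 4]
  term_flag <- abs(est) > 15 | se > 10
  separation <- !fit$converged || any(term_flag)
  ctrl_terms <- vapply(terms, function(tm) {
    any(vapply(controls, function(cv) startsWith(tm, cv) ||
                 startsWith(tm, paste0("`", cv)), logical(1)))
  }, logical(1))
  out <- tibble(
    term = gsub("`", "", terms),
    or = exp(est),
    conf_low = exp(est - 1.96 * se),
    conf_high = exp(est + 1.96 * se),
    p_value = p,
    is_control = unname(ctrl_terms),
    flagged = unname(term_flag))
  class(out) <- c("or_table", class(out))
  attr(out, "outcome") <- outcome
  attr(out, "n") <- nrow(df)
  attr(out, "separation") <- separation
  attr(out, "fit") <- fit
  out
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a randomly chosen positive
#' case outscores a randomly chosen negative one, ties counted one half.
#' Invariant under strictly monotone transformations of the scores.
#'
#' @param scores Numeric risk scores.
#' @param y Logical/0-1 labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  y <- as.logical(y)
  stopifnot(length(scores) == length(y), !anyNA(y), !anyNA(scores))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values underlying the DeLong covariance estimator.
.delong_placements <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r[seq_len(n1)] - rank(pos, ties.method = "average")) / n0
  v01 <- 1 - (r[n1 + seq_len(n0)] - rank(neg, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Compare two correlated AUCs (DeLong test)
#'
#' Paired nonparametric comparison of the AUCs of two risk scores
#' evaluated on the same subjects: the difference divided by its DeLong
#' (1988) variance gives a 1-df chi-square statistic. Used to test
#' whether adding the temporal-similarity features improves a model's
#' discrimination.
#'
#' @param scores_without,scores_with Paired risk scores on the same
#'   subjects.
#' @param y Logical/0-1 labels.
#' @return A list of class `auc_comparison`: `auc_without`, `auc_with`,
#'   `difference` (`auc_with - auc_without`), `chi2`, `p_value`, `n`.
#' @export
compare_auc <- function(scores_without, scores_with, y) {
  y <- as.logical(y)
  if (length(scores_without) != length(scores_with) ||
      length(y) != length(scores_with)) {
    stop("scores and labels must have matching lengths", call. = FALSE)
  }
  a <- .delong_placements(scores_without, y)
  b <- .delong_placements(scores_with, y)
  n1 <- sum(y); n0 <- sum(!y)
  diff <- b$auc - a$auc
  s10 <- var(a$v10) + var(b$v10) - 2 * .cov(a$v10, b$v10)
  s01 <- var(a$v01) + var(b$v01) - 2 * .cov(a$v01, b$v01)
  v <- s10 / n1 + s01 / n0
  if (diff == 0) {
    chi2 <- 0; p <- 1
  } else if (v <= 0) {
    chi2 <- Inf; p <- 0
  } else {
    chi2 <- diff^2 / v
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(auc_without = a$auc, auc_with = b$auc, difference = diff,
                 chi2 = chi2, p_value = p, n = length(y)),
            class = "auc_comparison")
}

.cov <- function(x, y) {
  if (length(x) < 2) return(0)
  sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "AUC %.4f (without) vs %.4f (with): diff %+0.4f, chi2(1) = %.3f, p = %.4g\n",
    x$auc_without, x$auc_with, x$difference, x$chi2, x$p_value))
  invisible(x)
}

#' Random-forest variable importance
#'
#' Impurity-based (mean decrease in Gini) importance from a
#' classification random forest, normalised to sum to one, with ranks.
#' Deterministic given the seed.
#'
#' @param X Data frame or matrix of features.
#' @param y Logical/0-1 outcome; both classes required.
#' @param n_trees Number of trees.
#' @param seed RNG seed for the forest.
#' @return A tibble `feature`, `importance`, `rank` with attributes
#'   `n_trees` and `seed`.
#' @export
rf_importance <- function(X, y, n_trees = 500, seed = 1) {
  y <- as.logical(y)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class", call. = FALSE)
  }
  X <- as.data.frame(X)
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = factor(as.integer(y)),
                                    ntree = n_trees)
  imp <- randomForest::importance(fit, type = 2)[, 1]
  total <- sum(imp)
  norm <- if (total > 0) imp / total else rep(1 / length(imp), length(imp))
  out <- tibble(feature = names(norm), importance = unname(norm)) |>
    arrange(desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  attr(out, "n_trees") <- n_trees
  attr(out, "seed") <- seed
  out
}

# Widen a tidy feature table for one stratum family into a per-user
# design matrix; columns are measure__stratum__iNN, values log(x + offset).
.wide_features <- function(features, stratum_type,
                           measures = c("days_any_use", "total_sessions",
                                        "total_duration", "dtw_mean"),
                           log_offset = 1, with_dtw = TRUE) {
  if (!with_dtw) measures <- setdiff(measures, "dtw_mean")
  f <- features[features$stratum_type == stratum_type, , drop = FALSE]
  if (nrow(f) == 0) stop("no features for stratum family ", stratum_type,
                         call. = FALSE)
  long <- f |>
    select(all_of(c("user_id", "interval_index", "stratum", measures))) |>
    tidyr::pivot_longer(all_of(measures), names_to = "measure",
                        values_to = "value") |>
    filter(!is.na(.data$value)) |>
    mutate(value = log(.data$value + log_offset),
           col = paste(.data$measure,
                       gsub("[^a-zA-Z0-9]+", "_", .data$stratum),
                       sprintf("i%02d", .data$interval_index), sep = "__"))
  long |>
    select(all_of(c("user_id", "col", "value"))) |>
    pivot_wider(names_from = "col", values_from = "value")
}

.drop_constant <- function(df, cols) {
  keep <- vapply(cols, function(cl) {
    v <- df[[cl]]
    length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  cols[keep]
}

.tier_names <- function(tiers) {
  map <- c("all", "weekpart", "session_type_weekpart")
  if (is.numeric(tiers)) map[tiers] else match.arg(tiers, map,
                                                   several.ok = TRUE)
}

#' Run the future-use prediction suite
#'
#' For each of the three future-use outcomes and each requested
#' granularity tier (1: all sessions; 2: weekday/weekend; 3: session type
#' by weekday/weekend), fits paired logistic models with and without the
#' DTW temporal-similarity features - always including demographics and
#' the measures of every interval, with intervals 1-5 treated as controls
#' in the reported table - and compares the two in-sample ROC AUCs with
#' the DeLong chi-square test. Random-forest importance of the
#' with-DTW feature set corroborates the comparison.
#'
#' @param features Feature tibble from [aggregate_features()] (raw scale;
#'   the suite log-transforms internally).
#' @param outcomes Tibble from [future_use_outcomes()].
#' @param demographics Tibble of `user_id` plus categorical demographic
#'   columns used as controls.
#' @param tiers Tiers to run: integers in 1..3 or family names.
#' @param n_trees,seed Random-forest settings.
#' @param log_offset Offset for the internal log transform.
#' @param control_intervals Interval indices treated as controls in the
#'   reported OR tables.
#' @param outcome_names Which of the three future-use outcomes to fit.
#' @param with_importance Compute random-forest importance (set `FALSE`
#'   to skip the forests, e.g. in replicated calibration runs).
#' @param evaluation `"in_sample"` (default) compares fitted values
#'   directly, the convention in the observational literature; because
#'   the two models are nested this is somewhat anti-conservative in
#'   small cohorts (see the methods vignette). `"cv"` compares
#'   cross-fitted scores - each subject scored by models fit with their
#'   fold held out - which keeps the comparison calibrated at any size,
#'   at some cost in power.
#' @param folds Number of cross-fitting folds.
#' @param cv_repeats Number of independent fold splits; cross-fitted
#'   scores are averaged over them, damping fold-assignment noise
#'   (repeated k-fold).
#' @return A list of class `prediction_suite` with `comparisons` (tibble:
#'   outcome, tier, AUCs, difference, chi2, p), `or_tables`, `importance`
#'   (named lists keyed `outcome.tier`).
#' @export
run_prediction_suite <- function(features, outcomes, demographics,
                                 tiers = 1:3, n_trees = 500, seed = 1,
                                 log_offset = 1, control_intervals = 1:5,
                                 outcome_names = c("any_use_28d",
                                                   "any_use_6mo",
                                                   "high_duration_28d"),
                                 with_importance = TRUE,
                                 evaluation = c("in_sample", "cv"),
                                 folds = 5, cv_repeats = 3) {
  tiers <- .tier_names(tiers)
  evaluation <- match.arg(evaluation)
  # dummy-encode the categorical controls once so every fold sees the
  # same design columns
  demo_cols0 <- setdiff(names(demographics), "user_id")
  if (length(demo_cols0) > 0) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(
      lapply(demographics[demo_cols0], as.factor)))[, -1, drop = FALSE]
    colnames(mm) <- gsub("[^a-zA-Z0-9_]+", "_", colnames(mm))
    demographics <- bind_cols(demographics["user_id"], as_tibble(mm))
  }
  demo_cols <- setdiff(names(demographics), "user_id")
  comparisons <- list()
  or_tables <- list()
  importance <- list()
  for (tier in tiers) {
    wide <- .wide_features(features, tier, log_offset = log_offset)
    use_cols <- setdiff(names(wide), "user_id")
    dtw_cols <- grep("^dtw_mean__", use_cols, value = TRUE)
    base <- wide |>
      inner_join(demographics, by = "user_id") |>
      inner_join(outcomes, by = "user_id")
    for (oc in outcome_names) {
      df <- base[!is.na(base[[oc]]), , drop = FALSE]
      pred_with <- .drop_constant(df, use_cols)
      pred_without <- setdiff(pred_with, dtw_cols)
      ctrl <- .drop_constant(df, demo_cols)
      fit_with <- fit_logistic_or(df, oc, pred_with, ctrl)
      fit_without <- fit_logistic_or(df, oc, pred_without, ctrl)
      if (evaluation == "in_sample") {
        s_with <- predict(attr(fit_with, "fit"), type = "response")
        s_without <- predict(attr(fit_without, "fit"), type = "response")
      } else {
        set.seed(seed)
        s_with <- s_without <- rep(0, nrow(df))
        for (rep_i in seq_len(cv_repeats)) {
          fold <- sample(rep_len(seq_len(folds), nrow(df)))
          for (f in seq_len(folds)) {
            te <- fold == f
            fw <- fit_logistic_or(df[!te, , drop = FALSE], oc, pred_with,
                                  ctrl)
            fo <- fit_logistic_or(df[!te, , drop = FALSE], oc,
                                  pred_without, ctrl)
            s_with[te] <- s_with[te] + suppressWarnings(
              predict(attr(fw, "fit"), newdata = df[te, , drop = FALSE],
                      type = "response")) / cv_repeats
            s_without[te] <- s_without[te] + suppressWarnings(
              predict(attr(fo, "fit"), newdata = df[te, , drop = FALSE],
                      type = "response")) / cv_repeats
          }
        }
      }
      cmp <- compare_auc(s_without, s_with, df[[oc]])
      key <- paste(oc, tier, sep = ".")
      # mark early-interval measures as controls in the reported table
      ctrl_pat <- sprintf("__i%02d$", control_intervals)
      fit_with$is_control <- fit_with$is_control |
        Reduce(`|`, lapply(ctrl_pat, grepl, x = fit_with$term))
      or_tables[[key]] <- fit_with
      if (with_importance) {
        importance[[key]] <- rf_importance(df[, pred_with, drop = FALSE],
                                           df[[oc]], n_trees = n_trees,
                                           seed = seed)
      }
      comparisons[[key]] <- tibble(
        outcome = oc, tier = tier, n = cmp$n,
        auc_without = cmp$auc_without, auc_with = cmp$auc_with,
        difference = cmp$difference, chi2 = cmp$chi2,
        p_value = cmp$p_value)
    }
  }
  structure(list(comparisons = bind_rows(comparisons),
                 or_tables = or_tables, importance = importance,
                 meta = list(tiers = tiers, n_trees = n_trees, seed = seed,
                             log_offset = log_offset,
                             evaluation = evaluation,
                             folds = if (evaluation == "cv") folds else NA)),
            class = "prediction_suite")
}

#' @export
print.prediction_suite <- function(x, ...) {
  cat("Future-use prediction suite (with vs without DTW features)\n")
  print(as.data.frame(x$comparisons), digits = 4)
  invisible(x)
}

#' Run the health-benefit association suite
#'
#' Averages the objective app-use measures over the last pre-survey
#' intervals (default 3, i.e. 6 weeks), log-transforms them, and fits
#' logistic models for the four dichotomous benefit outcomes with
#' demographics as controls. Model 1 uses the all-session measures
#' (total sessions, total duration, days with any use, DTW distance);
#' Model 2 uses the meditation-only and sleep-story-only measures
#' (sessions, duration, DTW each).
#'
#' @param features Feature tibble from [aggregate_features()] including
#'   the `all` and `session_type` stratum families.
#' @param benefit_outcomes Tibble from [dichotomize_survey()].
#' @param demographics Tibble of `user_id` plus demographic columns.
#' @param n_intervals_back Number of pre-survey intervals to average.
#' @param log_offset Offset for the log transform.
#' @param models Which of the two model families to fit.
#' @return A list of class `benefit_suite`: `or_tables` keyed
#'   `model.outcome`, and a `summary` tibble of the app-use terms.
#' @export
run_benefit_suite <- function(features, benefit_outcomes, demographics,
                              n_intervals_back = 3, log_offset = 1,
                              models = c("model1", "model2")) {
  pre <- features[!features$is_post_survey, , drop = FALSE]
  if (nrow(pre) == 0) stop("no pre-survey intervals in features",
                           call. = FALSE)
  last_iv <- pre |>
    distinct(.data$user_id, .data$interval_index) |>
    group_by(.data$user_id) |>
    slice_max(.data$interval_index, n = n_intervals_back) |>
    ungroup()
  avg <- pre |>
    semi_join(last_iv, by = c("user_id", "interval_index")) |>
    group_by(.data$user_id, .data$stratum_type, .data$stratum) |>
    summarise(across(c("days_any_use", "total_sessions", "total_duration",
                       "dtw_mean"), mean), .groups = "drop")

  widen <- function(st, strat, measures) {
    avg |>
      filter(.data$stratum_type == st, .data$stratum %in% strat) |>
      select(all_of(c("user_id", "stratum", measures))) |>
      tidyr::pivot_longer(all_of(measures), names_to = "measure") |>
      mutate(value = log(.data$value + log_offset),
             col = paste(.data$measure,
                         gsub("[^a-zA-Z0-9]+", "_", .data$stratum),
                         sep = "__")) |>
      select(all_of(c("user_id", "col", "value"))) |>
      pivot_wider(names_from = "col", values_from = "value")
  }
  models <- match.arg(models, several.ok = TRUE)
  designs <- list()
  if ("model1" %in% models) {
    designs$model1 <- widen("all", "all",
                            c("total_sessions", "total_duration",
                              "days_any_use", "dtw_mean"))
  }
  if ("model2" %in% models) {
    designs$model2 <- widen("session_type", c("meditation", "sleep_story"),
                            c("total_sessions", "total_duration",
                              "dtw_mean"))
  }

  outcome_names <- c("improved_mental", "improved_physical",
                     "very_improved_mental", "very_improved_physical")
  demo_cols <- setdiff(names(demographics), "user_id")
  or_tables <- list()
  rows <- list()
  for (model in names(designs)) {
    base <- designs[[model]] |>
      inner_join(demographics, by = "user_id") |>
      inner_join(benefit_outcomes, by = "user_id")
    use_cols <- setdiff(names(designs[[model]]), "user_id")
    for (oc in outcome_names) {
      preds <- .drop_constant(base, use_cols)
      ctrl <- .drop_constant(base, demo_cols)
      tab <- fit_logistic_or(base, oc, preds, ctrl)
      key <- paste(model, oc, sep = ".")
      or_tables[[key]] <- tab
      rows[[key]] <- tab |>
        filter(!.data$is_control) |>
        mutate(model = model, outcome = oc, .before = 1)
    }
  }
  structure(list(or_tables = or_tables, summary = bind_rows(rows),
                 meta = list(n_intervals_back = n_intervals_back,
                             log_offset = log_offset)),
            class = "benefit_suite")
}

#' @export
print.benefit_suite <- function(x, ...) {
  cat("Health-benefit association suite (app-use measure ORs)\n")
  print(as.data.frame(x$summary[, c("model", "outcome", "term", "or",
                                    "conf_low", "conf_high", "p_value")]),
        digits = 3)
  invisible(x)
}
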