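#' Default pipeline configuration
#'
#' Returns the default run configuration as a nested list; any YAML
#' config is merged over these defaults. The `simulate` block holds
#' [cohort_config()] overrides; alternatively an `input` block with
#' `sessions` and `survey` paths analyses an existing log.
#'
#' @return A nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    simulate = list(n_users = 200),
    input = NULL,
    dtw = list(window = NULL, empty_pair_k = 2),
    features = list(strata = c("all", "session_type", "timing", "weekpart"),
                    n_intervals = 10, log_offset = 1),
    outcomes = list(use_28d = c(0, 28), use_6mo = c(154, 182)),
    models = list(tiers = c(1, 2), n_trees = 500,
                  n_intervals_back = 3, evaluation = "in_sample"),
    output_dir = "habitdtw-out"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> binarize -> features -> outcomes
#' -> models and writes all artifacts to the output directory: the
#' session/survey inputs (when simulated), the tidy feature matrix,
#' outcome tables, odds-ratio tables, AUC comparisons, random-forest
#' importance rankings and a JSON run manifest with the configuration,
#' seed and exclusion accounting. Artifacts are written with a
#' `.partial` suffix while the run is in flight and renamed on success,
#' so an aborted run leaves its partial outputs identifiable.
#'
#' @param config Path to a YAML configuration file, or a nested list
#'   (merged over [default_run_config()]).
#' @param stages Which model stages to run after feature construction:
#'   subset of `"predict"`, `"benefits"` (data and feature stages always
#'   run). Use `character(0)` for a data-only run.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the in-memory results and the artifact
#'   directory.
#' @export
run_pipeline <- function(config = list(), stages = c("predict", "benefits"),
                         quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_run_config(), config)
  say <- function(...) if (!quiet) message("[habitdtw] ", sprintf(...))
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  partials <- character()
  put <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".partial"))
    readr::write_csv(df, path, progress = FALSE)
    partials <<- c(partials, path)
  }

  set.seed(cfg$seed)
  ground_truth <- NULL
  if (!is.null(cfg$input)) {
    say("ingest: reading %s", cfg$input$sessions)
    sessions <- read_sessions(cfg$input$sessions)
    survey <- read_survey(cfg$input$survey)
  } else {
    sim_cfg <- do.call(cohort_config, cfg$simulate)
    say("simulate: %d users, seed %d", sim_cfg$n_users, cfg$seed)
    cohort <- generate_cohort(sim_cfg, seed = cfg$seed)
    sessions <- cohort$sessions
    survey <- cohort$survey
    ground_truth <- cohort$ground_truth
    put(mutate(sessions,
               start = format(.data$start, "%Y-%m-%dT%H:%M:%S")),
        "sessions.csv")
    put(survey, "survey.csv")
    put(ground_truth, "ground_truth.csv")
  }
  say("ingest: %d sessions from %d users", nrow(sessions),
      length(unique(sessions$user_id)))

  dtw_cfg <- dtw_config(window = cfg$dtw$window,
                        empty_pair_k = cfg$dtw$empty_pair_k)
  intervals <- user_intervals(sessions, survey,
                              n_intervals = cfg$features$n_intervals)
  exclusions <- attr(intervals, "exclusions")
  n_featured <- length(unique(intervals$user_id))
  say("intervals: %d users featured, %d excluded (%s)", n_featured,
      nrow(exclusions),
      paste(names(table(exclusions$reason)), table(exclusions$reason),
            sep = "=", collapse = ", "))
  stopifnot(n_featured + nrow(exclusions) == nrow(survey))

  strata <- cfg$features$strata
  if (any(cfg$models$tiers == 3) && "predict" %in% stages) {
    strata <- union(strata, "session_type_weekpart")
  }
  say("features: strata [%s]", paste(strata, collapse = ", "))
  features <- aggregate_features(sessions, intervals, strata = strata,
                                 cfg = dtw_cfg)
  put(features, "features.csv")

  windows <- outcome_windows(cfg$outcomes$use_28d, cfg$outcomes$use_6mo)
  fut <- future_use_outcomes(sessions, survey, windows = windows)
  ben <- dichotomize_survey(survey)
  put(fut, "future_use_outcomes.csv")
  put(ben, "benefit_outcomes.csv")
  demographics <- survey[, c("user_id", .demographic_cols())]

  prediction <- NULL
  benefits <- NULL
  if ("predict" %in% stages) {
    say("predict: tiers [%s]", paste(cfg$models$tiers, collapse = ", "))
    prediction <- run_prediction_suite(
      features, fut, demographics, tiers = cfg$models$tiers,
      n_trees = cfg$models$n_trees, seed = cfg$seed,
      log_offset = cfg$features$log_offset,
      evaluation = cfg$models$evaluation)
    put(prediction$comparisons, "auc_comparisons.csv")
    put(bind_rows(lapply(names(prediction$or_tables), function(k) {
      mutate(as_tibble(prediction$or_tables[[k]]), model = k, .before = 1)
    })), "prediction_or_tables.csv")
    put(bind_rows(lapply(names(prediction$importance), function(k) {
      mutate(prediction$importance[[k]], model = k, .before = 1)
    })), "importance.csv")
  }
  if ("benefits" %in% stages) {
    say("benefits: %d-interval averages", cfg$models$n_intervals_back)
    benefits <- run_benefit_suite(
      features, ben, demographics,
      n_intervals_back = cfg$models$n_intervals_back,
      log_offset = cfg$features$log_offset)
    put(benefits$summary, "benefit_or_tables.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("habitdtw")),
    seed = cfg$seed,
    config = cfg,
    counts = list(users_ingested = nrow(survey),
                  users_featured = n_featured,
                  users_excluded = nrow(exclusions)))
  manifest_path <- file.path(out_dir, "manifest.json.partial")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  partials <- c(partials, manifest_path)
  for (p in partials) {
    file.rename(p, sub("\\.partial$", "", p))
  }
  say("done: artifacts in %s", out_dir)
  invisible(list(sessions = sessions, survey = survey,
                 ground_truth = ground_truth, intervals = intervals,
                 features = features, future_use = fut, benefits_dichot = ben,
                 prediction = prediction, benefits = benefits,
                 exclusions = exclusions, output_dir = out_dir))
}
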