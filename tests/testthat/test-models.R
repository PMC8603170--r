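test_that("univariate logistic OR equals the contingency-table cross-product", {
  # exposed: 30/100 events; unexposed: 10/100 -> OR = (30*90)/(70*10)
  df <- tibble::tibble(
    x = rep(c(1, 0), each = 100),
    y = c(rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(10, 90))))
  tab <- fit_logistic_or(df, "y", "x")
  expect_equal(tab$or[tab$term == "x"], (30 * 90) / (70 * 10),
               tolerance = 1e-6)
  expect_true(tab$conf_low <= tab$or & tab$or <= tab$conf_high)
  expect_false(attr(tab, "separation"))
  expect_error(fit_logistic_or(tibble::tibble(x = 1:10, y = 1), "y", "x"),
               "single class")
})

test_that("null-model Wald CIs cover 1 at close to nominal rate", {
  set.seed(5)
  cover <- vapply(1:50, function(i) {
    df <- tibble::tibble(x = rnorm(2000), y = rbinom(2000, 1, 0.4))
    tab <- fit_logistic_or(df, "y", "x")
    tab$conf_low[1] <= 1 && 1 <= tab$conf_high[1]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("perfect separation is flagged, not silently reported", {
  df <- tibble::tibble(x = c(rnorm(50, -3), rnorm(50, 3)),
                       y = rep(0:1, each = 50))
  tab <- fit_logistic_or(df, "y", "x")
  expect_true(attr(tab, "separation"))
  expect_true(any(tab$flagged))
})

test_that("label flipping returns reciprocal odds ratios", {
  set.seed(6)
  df <- tibble::tibble(x = rnorm(400))
  df$y <- rbinom(400, 1, plogis(0.5 * df$x))
  t1 <- fit_logistic_or(df, "y", "x")
  df$y2 <- 1 - df$y
  t2 <- fit_logistic_or(df, "y2", "x")
  expect_equal(t1$or, 1 / t2$or, tolerance = 1e-6)
})

test_that("the AUC is the Mann-Whitney probability with midrank ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  # hand count: pairs (.9 > .8), (.9 > .2), (.1 < .8), (.1 < .2) -> 2/4
  expect_equal(roc_auc(c(0.9, 0.1, 0.8, 0.2), c(1, 1, 0, 0)), 0.5)
  expect_equal(roc_auc(c(1, 1, 1, 0), c(1, 1, 0, 0)), 0.75)  # tie = 1/2
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  # invariance under strictly monotone transforms
  set.seed(9)
  s <- rnorm(200); y <- rbinom(200, 1, plogis(s))
  expect_equal(roc_auc(s, y), roc_auc(exp(s), y))
  expect_equal(roc_auc(s, y), roc_auc(rank(s), y))
})

test_that("the AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (k in 1:100) {
    n <- sample(20:80, 1)
    s <- rnorm(n); y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("the DeLong comparison matches its reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (k in 1:25) {
    n <- 120
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(x))
    s1 <- x + rnorm(n)
    s2 <- x + rnorm(n, sd = 0.5)
    cmp <- compare_auc(s1, s2, y)
    ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE, direction = "<"),
                          pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(cmp$chi2, unname(ref$statistic)^2, tolerance = 1e-8)
    expect_equal(cmp$p_value, unname(ref$p.value), tolerance = 1e-8)
    expect_equal(cmp$auc_with - cmp$auc_without,
                 unname(ref$estimate[2] - ref$estimate[1]),
                 tolerance = 1e-10)
  }
})

test_that("DeLong degenerate and strong-signal cases behave as expected", {
  set.seed(12)
  y <- rep(0:1, 20)
  s <- rnorm(40)
  cmp <- compare_auc(s, s, y)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
  # perfect vs coin-flip scorer: difference ~ 0.5, decisively significant
  perfect <- y + 0
  coin <- rep(c(0.4, 0.6), 20)[sample(40)]
  cmp <- compare_auc(coin, perfect, y)
  expect_gt(cmp$difference, 0.3)
  expect_lt(cmp$p_value, 0.01)
  # antisymmetry in the two score arguments
  rev <- compare_auc(perfect, coin, y)
  expect_equal(rev$difference, -cmp$difference)
  expect_error(compare_auc(1:3, 1:4, c(0, 1, 0)), "matching lengths")
})

test_that("random-forest importance is seeded, normalised and signal-finding", {
  set.seed(13)
  n <- 1000
  X <- as.data.frame(matrix(rnorm(n * 5), n,
                            dimnames = list(NULL, paste0("f", 1:5))))
  y <- X$f3 > 0
  imp <- rf_importance(X, y, n_trees = 100, seed = 2)
  expect_equal(sum(imp$importance), 1)
  expect_equal(sort(imp$rank), 1:5)
  expect_equal(imp$feature[imp$rank == 1], "f3")
  imp2 <- rf_importance(X, y, n_trees = 100, seed = 2)
  expect_identical(imp, imp2)
  expect_error(rf_importance(X, rep(TRUE, n)), "single class")
})

test_that("pure-noise features rarely dominate the importance ranking", {
  top_ratio <- vapply(1:20, function(k) {
    set.seed(100 + k)
    X <- as.data.frame(matrix(rnorm(200 * 6), 200,
                              dimnames = list(NULL, paste0("f", 1:6))))
    y <- rbinom(200, 1, 0.5)
    imp <- rf_importance(X, y, n_trees = 100, seed = k)
    max(imp$importance) / mean(imp$importance)
  }, numeric(1))
  expect_gte(mean(top_ratio < 3), 0.9)
})

test_that("the prediction suite emits one comparison per outcome and tier", {
  # the most granular tier carries hundreds of columns, so the
  # structural check needs a reasonably sized cohort; in-sample scoring
  # keeps it cheap
  co <- generate_cohort(cohort_config(n_users = 700, days_pre = 170),
                        seed = 14)
  iv <- user_intervals(co$sessions, co$survey)
  ft <- aggregate_features(co$sessions, iv,
                           strata = c("all", "weekpart",
                                      "session_type_weekpart"))
  fut <- future_use_outcomes(co$sessions, co$survey)
  ps <- run_prediction_suite(ft, fut, demo_of(co$survey), tiers = 1:3,
                             n_trees = 25, seed = 14,
                             evaluation = "in_sample")
  expect_equal(nrow(ps$comparisons), 9)
  expect_setequal(unique(ps$comparisons$outcome),
                  c("any_use_28d", "any_use_6mo", "high_duration_28d"))
  expect_setequal(unique(ps$comparisons$tier),
                  c("all", "weekpart", "session_type_weekpart"))
  expect_true(all(ps$comparisons$auc_with >= 0 &
                    ps$comparisons$auc_with <= 1))
  expect_equal(ps$comparisons$difference,
               ps$comparisons$auc_with - ps$comparisons$auc_without)
  expect_length(ps$or_tables, 9)
  expect_length(ps$importance, 9)
  # early intervals are marked as controls in the reported tables
  tab <- ps$or_tables[["any_use_28d.all"]]
  expect_true(all(tab$is_control[grepl("__i01$", tab$term)]))
  expect_false(any(tab$is_control[grepl("__i10$", tab$term)]))
})

test_that("the benefit suite fits both model families for all four outcomes", {
  co <- generate_cohort(cohort_config(n_users = 150, days_pre = 170,
                                      days_post = 5), seed = 15)
  iv <- user_intervals(co$sessions, co$survey)
  ft <- aggregate_features(co$sessions, iv,
                           strata = c("all", "session_type"))
  ben <- dichotomize_survey(co$survey)
  bs <- run_benefit_suite(ft, ben, demo_of(co$survey))
  expect_length(bs$or_tables, 8)
  expect_setequal(unique(bs$summary$model), c("model1", "model2"))
  expect_setequal(unique(bs$summary$outcome),
                  c("improved_mental", "improved_physical",
                    "very_improved_mental", "very_improved_physical"))
  m1 <- bs$or_tables[["model1.improved_mental"]]
  expect_true("dtw_mean__all" %in% m1$term)
  m2 <- bs$or_tables[["model2.improved_mental"]]
  expect_true(all(c("dtw_mean__meditation", "dtw_mean__sleep_story") %in%
                    m2$term))
})
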