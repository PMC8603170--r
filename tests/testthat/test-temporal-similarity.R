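test_that("DTW identity, shifted-block and unit examples are exact", {
  f <- figure1_fixture()
  expect_identical(dtw_distance(f$day_a, f$day_b), 0)
  expect_identical(euclidean_distance(f$day_a, f$day_b), 2)
  set.seed(1)
  a <- as.integer(runif(100) < 0.3)
  expect_identical(dtw_distance(a, a), 0)
  expect_identical(euclidean_distance(a, a), 0)
  expect_equal(euclidean_distance(c(1L, 0L), c(0L, 0L)), 1)
  expect_error(dtw_distance(c(0L, 1L), c(0L, 1L, 0L)), "equal length")
  expect_error(euclidean_distance(c(0L, 1L), c(0L, 1L, 0L)), "equal length")
})

test_that("dynamic program equals independent oracles on small vectors", {
  # every binary pair of length 4 against exhaustive path enumeration
  grid <- as.matrix(expand.grid(rep(list(0:1), 4)))
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      a <- as.integer(grid[i, ]); b <- as.integer(grid[j, ])
      expect_identical(dtw_distance(a, b), dtw_enum_oracle(a, b))
    }
  }
  # random length-30 pairs against memoised recursion
  set.seed(42)
  for (k in 1:50) {
    a <- as.integer(runif(30) < 0.4)
    b <- as.integer(runif(30) < 0.4)
    expect_identical(dtw_distance(a, b), dtw_memo_oracle(a, b))
  }
})

test_that("fast paths are bit-identical to the reference dynamic program", {
  set.seed(7)
  mismatches <- 0L
  for (k in 1:500) {
    kind <- k %% 5
    if (kind == 0) {          # sparse 1440-minute block days (fast paths)
      a <- random_block_day(sample(1:3, 1))
      b <- random_block_day(sample(1:3, 1))
    } else if (kind == 1) {   # one empty day
      n <- sample(30:120, 1)
      a <- as.integer(runif(n) < 0.3); b <- integer(n)
    } else {                  # dense short vectors
      n <- sample(30:120, 1)
      a <- as.integer(runif(n) < runif(1, 0.1, 0.6))
      b <- as.integer(runif(n) < runif(1, 0.1, 0.6))
    }
    if (!identical(dtw_distance(a, b), dtw_distance_ref(a, b))) {
      mismatches <- mismatches + 1L
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("DTW is symmetric, diagonal-bounded and forgives interior shifts", {
  set.seed(11)
  for (k in 1:40) {
    n <- sample(20:80, 1)
    a <- as.integer(runif(n) < 0.4)
    b <- as.integer(runif(n) < 0.4)
    d <- dtw_distance(a, b)
    expect_identical(d, dtw_distance(b, a))
    expect_lte(d, sum(abs(a - b)))                # diagonal path bound
    expect_lte(d, euclidean_distance(a, b)^2)     # binary: L2^2 = L1
  }
  # a single interior block shifted by any interior amount costs nothing
  # under DTW but always costs under the rigid comparison
  set.seed(12)
  for (k in 1:20) {
    v <- random_block_day(1)
    s <- sample(1:20, 1)
    shifted <- c(integer(s), v[seq_len(1440 - s)])
    expect_identical(dtw_distance(v, shifted), 0)
    expect_gt(euclidean_distance(v, shifted), 0)
  }
})

test_that("a windowing constraint is honoured and reported infeasible lengths error", {
  v <- random_block_day(1)
  s <- 30L
  shifted <- c(integer(s), v[seq_len(1440 - s)])
  unconstrained <- dtw_distance(v, shifted)
  expect_identical(unconstrained, 0)
  narrow <- dtw_distance(v, shifted, dtw_config(window = 5))
  expect_gt(narrow, 0)
  # the band must match the reference dynamic program too
  set.seed(21)
  a <- as.integer(runif(60) < 0.4); b <- as.integer(runif(60) < 0.4)
  cfgw <- dtw_config(window = 7)
  expect_identical(dtw_distance(a, b, cfgw), dtw_distance_ref(a, b, cfgw))
  expect_error(dtw_config(window = 0), "window")
})

test_that("pair distances apply the nonuse penalty and normalisation rules", {
  day <- random_block_day(1)
  empty <- integer(1440)
  # identical nonempty days
  pd <- pair_distance(day, day, mean_daily_duration = 10)
  expect_equal(pd$raw_dtw, 0)
  expect_equal(pd$normalized, 0)
  expect_equal(pd$penalty_applied, "none")
  # one empty day: raw equals the nonempty day's used minutes
  seven <- integer(1440); seven[701:707] <- 1L
  pd <- pair_distance(empty, seven, mean_daily_duration = 7)
  expect_equal(pd$raw_dtw, 7)
  expect_equal(pd$normalized, 1)
  expect_equal(pd$penalty_applied, "one_day_empty")
  # both empty: configured penalty k * mean daily duration
  pd <- pair_distance(empty, empty, mean_daily_duration = 10)
  expect_equal(pd$raw_dtw, 20)
  expect_equal(pd$normalized, 2)
  expect_equal(pd$penalty_applied, "both_days_empty")
  # degenerate: both empty and zero mean duration
  pd <- pair_distance(empty, empty, mean_daily_duration = 0)
  expect_equal(pd$normalized, 0)
  expect_equal(pd$penalty_applied, "both_days_empty")
  # dates, when carried, must be consecutive
  a <- structure(day, date = as.Date("2019-12-01"))
  b <- structure(day, date = as.Date("2019-12-03"))
  expect_error(pair_distance(a, b, 10), "calendar day after")
})

test_that("interval temporal similarity averages the 13 consecutive pairs", {
  day <- random_block_day(1)
  mat <- do.call(rbind, rep(list(day), 14))
  expect_equal(interval_temporal_similarity(mat), 0)
  expect_equal(interval_temporal_similarity(matrix(0L, 14, 1440)), 0)
  expect_error(interval_temporal_similarity(mat[1:10, ]), "14")

  # alternating disjoint equal-duration patterns A/B: every pair has the
  # same raw distance DTW(A, B), so the mean normalised value is
  # DTW(A, B) / d with d the common daily duration
  A <- integer(1440); A[401:410] <- 1L                 # one run
  B <- integer(1440); B[1001:1005] <- 1L; B[1101:1105] <- 1L  # two runs
  raw <- dtw_distance_ref(A, B)
  expect_gt(raw, 0)
  alt <- do.call(rbind, rep(list(A, B), 7))
  expect_equal(interval_temporal_similarity(alt), raw / 10)
})

test_that("the batched interval sweep matches per-pair distances on simulated data", {
  co <- generate_cohort(cohort_config(n_users = 6, days_pre = 40,
                                      days_post = 5), seed = 31)
  cov <- minute_coverage(co$sessions)
  cfg <- dtw_config()
  users <- unique(co$sessions$user_id)
  d0 <- min(cov$date)
  for (u in users[1:4]) {
    cu <- cov[cov$user_id == u & cov$date >= d0 & cov$date <= d0 + 13, ]
    mat <- matrix(0L, 14, 1440)
    if (nrow(cu)) mat[cbind(as.integer(cu$date - d0) + 1L, cu$minute + 1L)] <- 1L
    mdd <- sum(mat) / 14
    fast <- habitdtw:::.pairs_stats(mat, cbind(1:13, 2:14), mdd, cfg)
    slow <- vapply(1:13, function(p) {
      pair_distance(mat[p, ], mat[p + 1, ], mdd, cfg)$normalized
    }, numeric(1))
    expect_equal(fast$mean, mean(slow))
    expect_equal(interval_temporal_similarity(mat, cfg), mean(slow))
  }
})
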