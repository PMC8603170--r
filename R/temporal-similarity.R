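#' DTW configuration
#'
#' Settings for the dynamic time warping distance and the nonuse penalty.
#' The defaults reproduce the intended behaviour of the statistic: the
#' symmetric unit-weight step set `{(1,0), (0,1), (1,1)}` with absolute
#' difference as the local cost and no windowing constraint, under which
#' two days with the same single interior block of use have distance 0
#' no matter how far the block is shifted.
#'
#' @param step_pattern Only `"symmetric1"` is supported.
#' @param window Optional Sakoe-Chiba band half-width in minutes
#'   (`NULL` = unconstrained). If set, must be at least 1.
#' @param empty_pair_k Multiplier for the nonuse penalty: a consecutive-day
#'   pair in which both days have zero use is assigned a raw distance of
#'   `empty_pair_k` times the interval's mean daily used minutes. The
#'   default 2 reads "two fully inconsistent days".
#' @return A list of class `dtw_config`.
#' @export
dtw_config <- function(step_pattern = "symmetric1", window = NULL,
                       empty_pair_k = 2) {
  step_pattern <- match.arg(step_pattern)
  if (!is.null(window)) {
    window <- as.integer(window)
    if (is.na(window) || window < 1) stop("window must be >= 1", call. = FALSE)
  }
  if (!is.numeric(empty_pair_k) || empty_pair_k <= 0) {
    stop("empty_pair_k must be positive", call. = FALSE)
  }
  structure(list(step_pattern = step_pattern, window = window,
                 empty_pair_k = empty_pair_k),
            class = "dtw_config")
}

.as_int_vec <- function(x, arg) {
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x)) stop(arg, " must be numeric", call. = FALSE)
  xi <- as.integer(round(x))
  if (any(abs(x - xi) > 1e-9) || any(xi < 0)) {
    stop(arg, " must contain nonnegative integers (binary day vectors)",
         call. = FALSE)
  }
  xi
}

#' Dynamic time warping distance between two day vectors
#'
#' Minimal cumulative `|a_i - b_j|` over monotone warping paths with
#' boundary alignment `(1,1)` to `(n,n)` and steps `{(1,0),(0,1),(1,1)}`,
#' computed by exact dynamic programming. When one vector is all zeros the
#' optimum equals the sum of the other vector (the diagonal path attains
#' the per-row lower bound), and that value is returned directly; this
#' fast path is verified bit-identical to the full dynamic program in the
#' test suite.
#'
#' @param a,b Equal-length nonnegative integer (usually binary) vectors.
#' @param cfg A [dtw_config()].
#' @return The exact DTW distance (nonnegative scalar, minute units for
#'   binary day vectors).
#' @export
dtw_distance <- function(a, b, cfg = dtw_config()) {
  a <- .as_int_vec(a, "a"); b <- .as_int_vec(b, "b")
  if (length(a) != length(b)) {
    stop("vectors must have equal length (got ", length(a), " and ",
         length(b), ")", call. = FALSE)
  }
  w <- cfg$window %||% -1L
  sa <- sum(a); sb <- sum(b)
  # Exact fast paths (bit-identical to the dynamic program, covered by the
  # randomised identity suite in the tests):
  # - against an all-zero day the diagonal path attains the per-row lower
  #   bound sum(x);
  # - two binary vectors that start with the same value, end with the
  #   same value and have the same number of 1-runs share an identical
  #   run-value sequence, so run i maps onto run i (stretched or
  #   compressed freely) at cost 0. A window constraint invalidates the
  #   free stretching, so this only applies unconstrained.
  if (sa == 0L || sb == 0L) return(as.numeric(sa + sb))
  if (w < 0L && all(c(a, b) <= 1L)) {
    if (a[1] == b[1] && a[length(a)] == b[length(b)] &&
        .n_runs(a) == .n_runs(b)) {
      return(0)
    }
    # exact O(runs * n) band-collapse program for binary input
    return(dtw_band_cpp(a, b))
  }
  dtw_dist_cpp(a, b, as.integer(w))
}

.n_runs <- function(x) sum(x == 1L & c(0L, x[-length(x)]) == 0L)

#' Reference DTW dynamic program (anti-diagonal sweep)
#'
#' A pure-R implementation of the same recurrence as [dtw_distance()],
#' vectorised over anti-diagonals and with no shortcuts. It exists as the
#' reference against which the compiled fast path is checked for
#' bit-identical results; costs are small integers, so double arithmetic
#' is exact.
#'
#' @inheritParams dtw_distance
#' @return The exact DTW distance.
#' @export
dtw_distance_ref <- function(a, b, cfg = dtw_config()) {
  a <- .as_int_vec(a, "a"); b <- .as_int_vec(b, "b")
  n <- length(a); m <- length(b)
  if (n != m) stop("vectors must have equal length", call. = FALSE)
  C <- abs(outer(a, b, "-")) * 1.0
  if (!is.null(cfg$window)) {
    band <- abs(outer(seq_len(n), seq_len(m), "-")) > cfg$window
    C[band] <- Inf
  }
  D <- matrix(Inf, n, m)
  D[1, 1] <- C[1, 1]
  if (n == 1) return(D[1, 1])
  for (k in 3:(n + m)) {
    i <- max(1, k - m):min(n, k - 1)
    j <- k - i
    up <- D[cbind(pmax(i - 1, 1), j)]; up[i == 1] <- Inf
    left <- D[cbind(i, pmax(j - 1, 1))]; left[j == 1] <- Inf
    dg <- D[cbind(pmax(i - 1, 1), pmax(j - 1, 1))]
    dg[i == 1 | j == 1] <- Inf
    D[cbind(i, j)] <- C[cbind(i, j)] + pmin(up, left, dg)
  }
  if (!is.finite(D[n, m])) {
    stop("no feasible warping path within the window", call. = FALSE)
  }
  D[n, m]
}

#' Euclidean distance between two day vectors
#'
#' The L2 norm of `a - b`: the rigid minute-by-minute comparison that DTW
#' relaxes. For two binary days with equal total use whose single blocks
#' are shifted in time, this is positive while the DTW distance is 0.
#'
#' @inheritParams dtw_distance
#' @return Nonnegative scalar.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

#' DTW-based dissimilarity for one consecutive-day pair
#'
#' Computes the raw DTW distance between the two days, substituting the
#' nonuse penalty when both days are empty, and normalises by the
#' enclosing interval's mean daily used minutes so the result reads as the
#' fraction of a typical day's use that is inconsistently timed between
#' the two days.
#'
#' Cases:
#' * both days nonempty: raw = DTW distance;
#' * exactly one empty: raw = the dynamic-programming optimum, which
#'   equals the nonempty day's used minutes (asserted at run time);
#' * both empty: raw = `empty_pair_k * mean_daily_duration`.
#'
#' `normalized = raw / mean_daily_duration` when the mean is positive,
#' else 0 (with the penalty provenance still recorded).
#'
#' @param day_a,day_b 1440-minute vectors for calendar days d and d+1
#'   (as from [build_day_vector()]). If both carry `date` attributes, the
#'   dates must be consecutive.
#' @param mean_daily_duration Mean daily used minutes over the enclosing
#'   14-day interval (total used minutes / 14).
#' @param cfg A [dtw_config()].
#' @return A list with `raw_dtw`, `normalized` and `penalty_applied`
#'   (one of `"none"`, `"one_day_empty"`, `"both_days_empty"`).
#' @export
pair_distance <- function(day_a, day_b, mean_daily_duration,
                          cfg = dtw_config()) {
  da <- attr(day_a, "date"); db <- attr(day_b, "date")
  if (!is.null(da) && !is.null(db) && as.integer(as.Date(db) - as.Date(da)) != 1L) {
    stop("day_b must be the calendar day after day_a (got ", da, " and ",
         db, ")", call. = FALSE)
  }
  if (mean_daily_duration < 0) {
    stop("mean_daily_duration must be nonnegative", call. = FALSE)
  }
  sa <- sum(day_a > 0); sb <- sum(day_b > 0)
  if (sa == 0 && sb == 0) {
    raw <- cfg$empty_pair_k * mean_daily_duration
    penalty <- "both_days_empty"
  } else if (sa == 0 || sb == 0) {
    raw <- dtw_distance(day_a, day_b, cfg)
    stopifnot(raw == max(sa, sb))  # DP optimum against an empty day
    penalty <- "one_day_empty"
  } else {
    raw <- dtw_distance(day_a, day_b, cfg)
    penalty <- "none"
  }
  normalized <- if (mean_daily_duration > 0) raw / mean_daily_duration else 0
  list(raw_dtw = raw, normalized = normalized, penalty_applied = penalty)
}

#' Temporal similarity of one 14-day interval
#'
#' The core statistic: the mean, over the 13 consecutive-day pairs of a
#' 14-day interval, of the normalised pair distance of [pair_distance()],
#' with the mean daily duration taken as total used minutes / 14. Lower
#' values mean more temporally consistent daily use; 0 means every day
#' repeats the previous day's pattern up to time warping.
#'
#' @param day_vectors A 14 x 1440 binary matrix (rows = consecutive
#'   calendar days) or a list of 14 day vectors.
#' @param cfg A [dtw_config()].
#' @return The mean normalised distance (nonnegative scalar, dimensionless).
#' @export
interval_temporal_similarity <- function(day_vectors, cfg = dtw_config()) {
  mat <- .as_day_matrix(day_vectors)
  if (nrow(mat) < 14) {
    stop("an interval requires 14 consecutive day vectors (got ",
         nrow(mat), ")", call. = FALSE)
  }
  mdd <- sum(mat) / 14
  pairs <- cbind(1:13, 2:14)
  .pairs_mean_normalized(mat, pairs, mdd, cfg)
}

.as_day_matrix <- function(day_vectors) {
  if (is.list(day_vectors)) {
    stopifnot(all(vapply(day_vectors, length, 1L) == 1440))
    mat <- do.call(rbind, lapply(day_vectors, as.integer))
  } else {
    mat <- day_vectors
    storage.mode(mat) <- "integer"
  }
  mat
}

# Mean normalised pair distance over an arbitrary set of within-stratum
# consecutive-day row pairs (weekday/weekend strata use restricted pairs).
.pairs_mean_normalized <- function(mat, pairs, mdd, cfg) {
  vals <- vapply(seq_len(nrow(pairs)), function(k) {
    pair_distance(mat[pairs[k, 1], ], mat[pairs[k, 2], ], mdd, cfg)$normalized
  }, numeric(1))
  mean(vals)
}
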