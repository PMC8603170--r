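# Independent DTW oracles used to check the dynamic program.

# Top-down memoised recursion over the DTW recurrence; independent of the
# package's bottom-up implementations. Suitable up to length ~50.
dtw_memo_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    cost <- abs(a[i] - b[j])
    v <- if (i == 1 && j == 1) {
      cost
    } else {
      best <- Inf
      if (i > 1) best <- min(best, rec(i - 1, j))
      if (j > 1) best <- min(best, rec(i, j - 1))
      if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
      cost + best
    }
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

# Exhaustive path enumeration (compiled DFS over every monotone warping
# path); exact for short vectors.
dtw_enum_oracle <- function(a, b) {
  habitdtw:::dtw_enum_cpp(as.integer(a), as.integer(b))
}

# A random interior block pattern on the 1440-minute grid: `n_blocks`
# disjoint runs of use, none touching minute 0 or 1439.
random_block_day <- function(n_blocks = 1, min_len = 2, max_len = 20,
                             margin = 60) {
  v <- integer(1440)
  starts <- sort(sample(seq(margin, 1440 - margin - max_len), n_blocks))
  for (s in starts) {
    len <- sample(min_len:max_len, 1)
    v[s:(s + len - 1)] <- 1L
  }
  v
}
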