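# Rank-based tests with exact small-sample distributions.
#
# Both the one-vs-rest marker test (Wilcoxon rank-sum) and the paralog
# vs background comparison (Wilcoxon signed-rank) need exact p-values at
# small n, including under ties where the textbook null tables do not
# apply. The exact conditional distributions given the observed (mid)ranks
# are computed by dynamic programming over subset sums; midranks are
# doubled so every achievable sum is an integer.

# Count, for each achievable (subset size, subset sum), the number of
# subsets of `scaled` (integer vector) realizing it. Returns a
# (n+1) x (S+1) matrix of counts; sizes 0..n in rows, sums 0..S in cols.
subset_sum_counts <- function(scaled) {
  n <- length(scaled)
  S <- sum(scaled)
  f <- matrix(0, nrow = n + 1, ncol = S + 1)
  f[1, 1] <- 1
  for (v in scaled) {
    # update in decreasing size order so each item is used once
    for (k in seq(n, 1)) {
      row <- f[k, ]
      if (any(row != 0))
        f[k + 1, (v + 1):(S + 1)] <- f[k + 1, (v + 1):(S + 1)] +
          row[1:(S + 1 - v)]
    }
  }
  f
}

# Two-sided p from a discrete null distribution: twice the smaller tail
# containing the observed value, capped at 1.
two_sided_from_counts <- function(counts, total, w) {
  # counts: named by achievable sum (0..S index offset 1)
  sums <- seq_along(counts) - 1
  p_lo <- sum(counts[sums <= w]) / total
  p_hi <- sum(counts[sums >= w]) / total
  min(1, 2 * min(p_lo, p_hi))
}

#' Wilcoxon rank-sum test (one group vs the rest)
#'
#' Two-sided rank-sum test used for marker calling. For total sample size
#' `n <= exact_limit` the p-value is exact and conditional on the observed
#' midranks (correct under ties); otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_limit Largest total sample size for which the exact
#'   distribution is enumerated (default 25).
#' @return A list with `statistic` (rank sum `W` of `x`, midranks) and
#'   `p_value`.
#' @export
ranksum_test <- function(x, y, exact_limit = 25) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= exact_limit) {
    scaled <- as.integer(round(2 * r))
    f <- subset_sum_counts(scaled)
    counts <- f[n1 + 1, ]
    p <- two_sided_from_counts(counts, choose(n, n1),
                               as.integer(round(2 * w)))
  } else {
    u <- w - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = w, p_value = 1))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = w, p_value = min(1, p))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided signed-rank test. Zero differences are dropped (standard
#' convention). For `n <= exact_limit` non-zero differences the p-value is
#' exact and conditional on the observed midranks of the absolute
#' differences; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_limit Largest number of non-zero differences for which the
#'   exact distribution is enumerated (default 25).
#' @return A list with `statistic` (`V`, the positive-rank sum), `n_used`
#'   (non-zero differences), and `p_value`. If every difference is zero,
#'   `p_value = 1` with a warning.
#' @export
signed_rank_test <- function(d, exact_limit = 25) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; degenerate comparison")
    return(list(statistic = 0, n_used = 0L, p_value = 1))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    scaled <- as.integer(round(2 * r))
    f <- subset_sum_counts(scaled)
    counts <- colSums(f)          # subsets of any size
    p <- two_sided_from_counts(counts, 2^n, as.integer(round(2 * v)))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) return(list(statistic = v, n_used = n, p_value = 1))
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = v, n_used = as.integer(n), p_value = min(1, p))
}
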