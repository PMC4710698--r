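# Independent oracles, deliberately brute-force.

# Benjamini-Hochberg step-up by direct definition: sort p ascending, compute
# m * p_(i) / i, enforce monotonicity from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in seq(m - 1, 1, length.out = max(m - 1, 0)))
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Two-sided hypergeometric p by exhaustive pmf summation: sum the pmf over
# every achievable count whose probability does not exceed the observed one.
hyper_oracle <- function(a, n, K, N) {
  k_all <- max(0, n - (N - K)):min(n, K)
  pmf <- stats::dhyper(k_all, K, N - K, n)
  sum(pmf[pmf <= stats::dhyper(a, K, N - K, n) * (1 + 1e-7)])
}

# Textbook Pearson correlation from raw sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# 75th percentile with linear interpolation between order statistics,
# written out by hand (h = (n - 1) p + 1).
q75_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * 0.75 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}
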