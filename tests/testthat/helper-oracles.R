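# Independent oracles: deliberately naive implementations (double loops,
# exhaustive enumeration, grid search) used to verify the package's
# vectorized / library-backed routines on small instances.

# O(n^2) concordance-index enumerator (pair-by-pair double loop).
brute_cindex <- function(risk, time, event) {
  num <- 0
  den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (event[i] == 1 && time[i] < time[j]) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Efron-tie-corrected Cox log partial likelihood for one covariate.
efron_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(exp(beta * x[R]))
    sum_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - (l / d) * sum_d)
    }
  }
  ll
}

# Grid-search maximizer of the Efron partial likelihood.
grid_cox_beta <- function(x, time, event, lo = -8, hi = 8, tol = 1e-5) {
  stats::optimize(function(b) efron_loglik(b, x, time, event),
                  c(lo, hi), maximum = TRUE, tol = tol)$maximum
}

# Exhaustive two-sided Wilcoxon signed-rank p-value over all 2^n sign
# assignments of the absolute differences (valid under ties).
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- sum(r)
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[signs == 1])
  }, numeric(1))
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Friedman chi-squared and Kendall's W from first principles
# (average within-block ranks, plain chi-squared formula).
brute_friedman <- function(scores) {
  K <- nrow(scores)
  N <- ncol(scores)
  Rnk <- apply(scores, 2, function(col) rank(col))
  Rsum <- rowSums(Rnk)
  chi2 <- 12 / (N * K * (K + 1)) * sum(Rsum^2) - 3 * N * (K + 1)
  list(statistic = chi2, kendall_w = chi2 / (N * (K - 1)))
}

# Direct evaluation of the chance-corrected overlap formula.
brute_kuncheva <- function(a, b, n) {
  r <- sum(!is.na(match(a, b)))
  k <- length(a)
  (r * n - k^2) / (k * (n - k))
}
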