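# Statistical comparison layer: Friedman test with Kendall's W,
# Wilcoxon signed-rank (exact null for small samples, ties included),
# Benjamini-Hochberg correction, Spearman and partial Spearman
# correlation, and percentile bootstrap intervals. All tests two-sided.

#' Friedman test across blocked method scores, with Kendall's W
#'
#' Rows are methods (treatments), columns are blocks (cohorts or CV
#' replicates). Within-block average ranks feed the plain chi-squared
#' Friedman statistic (no tie correction) on K - 1 degrees of freedom;
#' the effect size is Kendall's `W = chi2 / (N (K - 1))` for N blocks
#' and K methods, so W is 0 when every block ranks the methods
#' identically flat and 1 for a perfectly consistent complete ordering.
#'
#' @param scores numeric matrix, methods x blocks, no missing cells.
#' @return list with `statistic`, `df`, `p_value`, `kendall_w`.
#' @export
friedman_test <- function(scores) {
  if (!is.matrix(scores) || nrow(scores) < 2 || ncol(scores) < 2) {
    stop("degenerate dimensions: need >= 2 methods and >= 2 blocks")
  }
  if (anyNA(scores)) stop("degenerate input: missing cells")
  K <- nrow(scores)
  N <- ncol(scores)
  Rnk <- apply(scores, 2, rank)       # average ranks on ties
  Rsum <- rowSums(Rnk)
  chi2 <- 12 / (N * K * (K + 1)) * sum(Rsum^2) - 3 * N * (K + 1)
  chi2 <- max(chi2, 0)
  list(statistic = chi2, df = K - 1L,
       p_value = max(stats::pchisq(chi2, K - 1, lower.tail = FALSE),
                     .Machine$double.xmin),
       kendall_w = chi2 / (N * (K - 1)))
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped (Wilcoxon's rule). When at most 25
#' non-zero differences remain, the p-value is exact, computed by
#' dynamic-programming enumeration of the signed-rank null (valid under
#' tied absolute differences, where average ranks are used); otherwise a
#' normal approximation with continuity and tie corrections is used.
#'
#' @param a,b paired numeric vectors (>= 5 non-zero differences).
#' @return list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `exact`, `n` (non-zero differences).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("undefined test: all differences are zero")
  if (n < 5) stop("undefined test: fewer than 5 non-zero differences")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact null: enumerate the distribution of the positive-rank sum by
    # convolution over doubled ranks (integers even under .5 ties)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), f[seq_len(total + 1 - ri)])
      f <- f + shifted
    }
    f <- f / sum(f)
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[seq_len(v2 + 1)])
    p_ge <- sum(f[(v2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = v, p_value = max(p, .Machine$double.xmin),
         exact = TRUE, n = n)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = v, p_value = max(p, .Machine$double.xmin),
         exact = FALSE, n = n)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity, clipped at 1.
#'
#' @param p_values vector of raw p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1 | !is.finite(p_values))) {
    stop("out-of-range input: p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman rank correlation with t-approximate p-value
#'
#' Pearson correlation of average ranks; the two-sided p-value uses the
#' t approximation `t = rho sqrt((n-2)/(1-rho^2))` on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of length >= 3, neither constant.
#' @return list with `rho`, `statistic` (t), `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need equal-length vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    tval <- sign(rho) * Inf
    p <- .Machine$double.xmin
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * stats::pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  }
  list(rho = rho, statistic = tval, p_value = p, n = n)
}

#' Partial Spearman correlation of x and y adjusting for z
#'
#' Rank-transforms all three variables, linearly residualizes rank-x and
#' rank-y on rank-z, and correlates the residuals; the two-sided p-value
#' uses a t approximation on n - 3 degrees of freedom.
#'
#' @param x,y,z numeric vectors of length >= 4.
#' @return list with `rho`, `statistic`, `p_value`, `n`.
#' @export
partial_spearman <- function(x, y, z) {
  n <- length(x)
  if (n < 4 || length(y) != n || length(z) != n) {
    stop("need equal-length vectors of length >= 4")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
    stop("undefined correlation: constant input")
  }
  rz <- cbind(1, rank(z))
  ex <- stats::lm.fit(rz, rank(x))$residuals
  ey <- stats::lm.fit(rz, rank(y))$residuals
  if (stats::sd(ex) == 0 || stats::sd(ey) == 0) {
    stop("undefined correlation: degenerate residuals")
  }
  rho <- stats::cor(ex, ey)
  if (abs(rho) >= 1) {
    tval <- sign(rho) * Inf
    p <- .Machine$double.xmin
  } else {
    tval <- rho * sqrt((n - 3) / (1 - rho^2))
    p <- max(2 * stats::pt(-abs(tval), df = n - 3), .Machine$double.xmin)
  }
  list(rho = rho, statistic = tval, p_value = p, n = n)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (or elements) of `data` with replacement `n_boot`
#' times and returns the percentile interval of the statistic.
#'
#' @param statistic_fn function of one resampled data argument returning
#'   a scalar.
#' @param data vector, matrix or data.frame.
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return numeric vector `c(low, high)`. Resamples on which the
#'   statistic is undefined (`NA`) are dropped from the percentile
#'   computation.
#' @export
bootstrap_ci <- function(statistic_fn, data, n_boot = 100, seed = 1,
                         conf = 0.95) {
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n == 0) stop("empty data")
  if (n_boot < 2) stop("configuration error: n_boot must be >= 2")
  stats_v <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample(n, replace = TRUE)
      resampled <- if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
      statistic_fn(resampled)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  if (all(is.na(stats_v))) stop("statistic undefined on every resample")
  unname(stats::quantile(stats_v, c(alpha, 1 - alpha), type = 7,
                         na.rm = TRUE))
}

#' Write a tidy table of test results as TSV
#'
#' @param results data.frame with columns `comparison`, `statistic`,
#'   `p`, `q`, `effect_size` (others allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_test_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
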