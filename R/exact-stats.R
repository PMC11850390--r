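#' Exact statistical machinery
#'
#' Self-contained implementations of the three tests used throughout the
#' staging and regional analyses: the two-sided Fisher exact test on a 2x2
#' table, the two-sided exact binomial test, and the two-tailed Welch t-test.
#' All combinatorics are accumulated in log space so tables with totals up to
#' about 1e6 remain overflow-safe; the Student t tail is evaluated through
#' the regularized incomplete beta function.
#'
#' @name exact_stats
NULL

new_test_result <- function(test_name, statistic, df, p_value, table_or_n,
                            degenerate = FALSE, note = NULL) {
  structure(
    list(test_name = test_name, statistic = statistic, df = df,
         p_value = p_value, tails = "two_sided", table_or_n = table_or_n,
         degenerate = degenerate, note = note),
    class = "ps_test")
}

#' @export
print.ps_test <- function(x, ...) {
  cat(x$test_name, " (two-sided)\n", sep = "")
  if (!is.null(x$statistic) && !is.na(x$statistic))
    cat("  statistic: ", format(x$statistic, digits = 6), "\n", sep = "")
  if (!is.null(x$df) && !is.na(x$df))
    cat("  df:        ", format(x$df, digits = 6), "\n", sep = "")
  cat("  p-value:   ", stats::format.pval(x$p_value, digits = 6), "\n", sep = "")
  if (isTRUE(x$degenerate))
    cat("  [degenerate: ", x$note, "]\n", sep = "")
  invisible(x)
}

# Relative guard used when summing probabilities "no larger than" an observed
# one; absorbs floating-point ties in the enumeration rules below.
.pmf_tie_guard <- 1e-7

#' Hypergeometric probability mass
#'
#' Exact probability of drawing `k` successes in `n` draws without
#' replacement from a population of size `N` containing `K` successes,
#' computed by log-binomial-coefficient accumulation. This is the kernel of
#' the Fisher exact test. Values of `k` outside the support return 0.
#'
#' @param k observed successes in the sample (vectorised).
#' @param N population size.
#' @param K successes in the population.
#' @param n sample size (draws).
#' @return numeric vector of probabilities.
#' @examples
#' hypergeometric_pmf(5, N = 10, K = 5, n = 5)  # 1/252
#' @export
hypergeometric_pmf <- function(k, N, K, n) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1)
  if (K < 0 || K > N || n < 0 || n > N)
    stop("invalid hypergeometric parameters: need 0 <= K <= N and 0 <= n <= N")
  lo <- max(0L, n + K - N); hi <- min(n, K)
  out <- numeric(length(k))
  ok <- k >= lo & k <= hi & k == round(k)
  if (any(ok)) {
    kk <- k[ok]
    out[ok] <- exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n))
  }
  out
}

#' Two-sided Fisher exact test
#'
#' Exact test of association in a 2x2 contingency table. The two-sided
#' p-value follows the point-probability convention of mainstream
#' statistical software: the sum of hypergeometric probabilities over all
#' tables with the same margins whose probability does not exceed that of
#' the observed table (up to a 1e-7 relative tie guard). The statistic is
#' the sample odds ratio `a*d / (b*c)`; tables with a zero margin are
#' degenerate and return p = 1.
#'
#' @param table a 2x2 matrix of non-negative counts
#'   `rbind(c(a, b), c(c, d))`.
#' @return a `ps_test` result with fields `statistic` (odds ratio), `p_value`
#'   and a `degenerate` flag.
#' @examples
#' fisher_exact_two_sided(rbind(c(30, 0), c(21, 13)))
#' @export
fisher_exact_two_sided <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2, 2))) stop("`table` must be 2x2")
  if (any(tb < 0) || any(tb != round(tb))) stop("counts must be non-negative integers")
  a <- tb[1, 1]; b <- tb[1, 2]; cc <- tb[2, 1]; d <- tb[2, 2]
  N <- a + b + cc + d
  K <- a + b          # row 1 margin
  n <- a + cc         # column 1 margin
  or <- (a * d) / (b * cc)   # may be Inf or NaN with zero cells
  if (N == 0 || K == 0 || K == N || n == 0 || n == N) {
    return(new_test_result("Fisher exact test", or, NA_real_, 1,
                           table_or_n = tb, degenerate = TRUE,
                           note = "zero margin"))
  }
  lo <- max(0L, n + K - N); hi <- min(n, K)
  support <- lo:hi
  pmf <- hypergeometric_pmf(support, N, K, n)
  p_obs <- pmf[support == a]
  p <- sum(pmf[pmf <= p_obs * (1 + .pmf_tie_guard)])
  new_test_result("Fisher exact test", or, NA_real_, min(p, 1), table_or_n = tb)
}

#' Two-sided exact binomial test
#'
#' Exact test of `k` successes in `n` Bernoulli trials against success
#' probability `p0`. The two-sided p-value sums the binomial pmf over all
#' outcomes no more probable than the observed one (1e-7 relative tie
#' guard), capped at 1.
#'
#' @param k observed successes.
#' @param n number of trials.
#' @param p0 null success probability (default 0.5).
#' @return a `ps_test` result; `statistic` is the observed count `k`.
#' @examples
#' binomial_test_two_sided(6, 6)  # 2 * 0.5^6
#' @export
binomial_test_two_sided <- function(k, n, p0 = 0.5) {
  if (n < 0 || k < 0 || k > n) stop("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("`p0` must lie in (0, 1)")
  if (n == 0) {
    return(new_test_result("Exact binomial test", NA_real_, NA_real_, 1,
                           table_or_n = c(k = k, n = n), degenerate = TRUE,
                           note = "no trials"))
  }
  support <- 0:n
  logpmf <- lchoose(n, support) + support * log(p0) + (n - support) * log1p(-p0)
  pmf <- exp(logpmf)
  p <- sum(pmf[pmf <= pmf[k + 1] * (1 + .pmf_tie_guard)])
  new_test_result("Exact binomial test", k, NA_real_, min(p, 1),
                  table_or_n = c(k = k, n = n))
}

#' Two-tailed Welch t-test
#'
#' Two-sample t-test that assumes neither equal variances nor pairing.
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch-Satterthwaite degrees of freedom; the two-sided p-value is the
#' Student t tail probability evaluated via the regularized incomplete beta
#' function, exact at the small group sizes (3-8 sections) typical of
#' regional comparisons.
#'
#' @param xs,ys numeric samples, each with at least 2 finite values.
#' @return a `ps_test` result with `statistic` (t), `df` and `p_value`.
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welch_t_test <- function(xs, ys) {
  xs <- xs[is.finite(xs)]; ys <- ys[is.finite(ys)]
  nx <- length(xs); ny <- length(ys)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 finite values")
  vx <- var(xs); vy <- var(ys)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    # all values identical within each sample
    degen <- mean(xs) == mean(ys)
    return(new_test_result("Welch t-test", if (degen) 0 else Inf, NA_real_,
                           if (degen) 1 else 0,
                           table_or_n = c(nx = nx, ny = ny),
                           degenerate = TRUE, note = "zero variance"))
  }
  t <- (mean(xs) - mean(ys)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  # P(|T_df| > |t|) = I_{df/(df+t^2)}(df/2, 1/2)
  p <- pbeta(df / (df + t^2), df / 2, 0.5)
  new_test_result("Welch t-test", t, df, min(max(p, .Machine$double.xmin), 1),
                  table_or_n = c(nx = nx, ny = ny))
}
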