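#' @rdname wilcoxon_rank_sum_exact
#' @param statistic,p_value,method,n_per_group fields of the outcome.
#' @param note optional diagnostic note (e.g. degenerate-variance flag).
#' @export
test_outcome <- function(statistic, p_value, method, n_per_group,
                         note = NULL) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         method = method, n_per_group = unname(n_per_group), note = note),
    class = "test_outcome"
  )
}

#' @export
print.test_outcome <- function(x, digits = 4, ...) {
  cat(x$method, "\n")
  cat(sprintf("statistic = %s, p = %s (n = %s)\n",
              format(x$statistic, digits = digits),
              format.pval(x$p_value, digits = digits),
              paste(x$n_per_group, collapse = ", ")))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# two-sided p by the symmetric-deviation rule: sum the probabilities of all
# outcomes whose statistic deviates from the null mean by at least as much
# as the observed one (with a small tolerance for floating-point mid-ranks)
two_sided_from_distribution <- function(values, probs, observed, null_mean) {
  dev <- abs(values - null_mean)
  obs <- abs(observed - null_mean)
  sum(probs[dev >= obs - 1e-9])
}

#' Exact Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided exact test for a location difference between two unpaired
#' samples.  For `n1 + n2 <= max_exact` (default 20) the null distribution
#' of the rank-sum statistic is obtained by full enumeration of all
#' `choose(n1 + n2, n1)` group labelings of the pooled values; ties are
#' handled with mid-ranks.  The two-sided p-value is the total probability
#' of labelings whose rank sum deviates from its null mean by at least the
#' observed deviation.  Larger samples fall back to the normal
#' approximation with tie-corrected variance.
#'
#' @param x,y numeric samples (each non-empty).
#' @param max_exact largest pooled size for which full enumeration is used.
#' @return A `test_outcome` with the rank sum of `x` as statistic.
#' @examples
#' # complete separation at n = 5 per group: the minimal attainable p
#' wilcoxon_rank_sum_exact(1:5, 6:10)  # p = 2/252 = 0.0079
#' @export
wilcoxon_rank_sum_exact <- function(x, y, max_exact = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || anyNA(x) || anyNA(y))
    stop_devdelay("both samples must be non-empty and free of NA",
                  class = "devdelay_value_error")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))  # mid-ranks
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (N <= max_exact) {
    combos <- utils::combn(N, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    p <- two_sided_from_distribution(w_all, rep(1 / ncol(combos), ncol(combos)),
                                     w_obs, mu)
    method <- "Exact Wilcoxon rank-sum test (full enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (w_obs - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon rank-sum test (normal approximation, tie-corrected)"
  }
  test_outcome(c(W = w_obs), p, method, c(n1 = n1, n2 = n2))
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided exact test for symmetry of paired differences about zero.
#' Zero differences are dropped (the conventional reduction); the absolute
#' values of the remaining differences are mid-ranked and the exact null
#' distribution of the positive-rank sum is built over all `2^n` sign
#' assignments (by convolution, so ties and n up to `max_exact` are exact).
#' The two-sided p-value uses the symmetric-deviation rule about the null
#' mean `T/2` where `T` is the total rank sum.
#'
#' @param differences numeric vector of paired differences; at least one
#'   must be nonzero.
#' @param max_exact largest number of nonzero differences for which the
#'   exact distribution is used; beyond it the tie-corrected normal
#'   approximation applies.
#' @return A `test_outcome` with the positive-rank sum as statistic.
#' @export
wilcoxon_signed_rank_exact <- function(differences, max_exact = 20L) {
  d <- as.numeric(differences)
  if (length(d) < 1L || anyNA(d))
    stop_devdelay("differences must be non-empty and free of NA",
                  class = "devdelay_value_error")
  d <- d[d != 0]
  if (length(d) == 0L)
    stop_devdelay("all differences are zero", class = "devdelay_value_error")
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  tot <- sum(r)
  if (n <= max_exact) {
    # exact distribution of the positive-rank sum by convolution over signs;
    # doubling makes mid-ranks (multiples of 0.5) integral
    r2 <- as.integer(round(2 * r))
    probs <- 1
    for (rk in r2) {
      shifted <- c(rep(0, rk), probs)
      probs <- c(probs, rep(0, rk)) + shifted
    }
    probs <- probs / 2^n
    values <- (seq_along(probs) - 1L) / 2
    p <- two_sided_from_distribution(values, probs, v_obs, tot / 2)
    method <- "Exact Wilcoxon signed-rank test (full enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v_obs - tot / 2) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed-rank test (normal approximation, tie-corrected)"
  }
  test_outcome(c(V = v_obs), p, method, c(n = n))
}

#' Kruskal-Wallis rank test for several groups
#'
#' H statistic with mid-rank tie correction and the chi-square
#' approximation on `k - 1` degrees of freedom, via [stats::kruskal.test()].
#'
#' @param groups a list of two or more non-empty numeric samples.
#' @return A `test_outcome` with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_devdelay("need a list of at least two groups",
                  class = "devdelay_value_error")
  if (any(lengths(groups) == 0L))
    stop_devdelay("every group must be non-empty",
                  class = "devdelay_value_error")
  kt <- stats::kruskal.test(groups)
  test_outcome(c(H = unname(kt$statistic)), kt$p.value,
               "Kruskal-Wallis rank sum test", lengths(groups))
}

#' Welch's two-sample t-test
#'
#' Two-sided t-test with the Welch-Satterthwaite degrees of freedom, via
#' [stats::t.test()].  Degenerate inputs are resolved by convention: if both
#' groups have zero variance and equal means, `t = 0, p = 1`; zero variance
#' in both groups with unequal means gives the limiting `p = 0`, flagged in
#' the outcome's `note`.
#'
#' @param x,y numeric samples of at least 2 observations each.
#' @return A `test_outcome` with the t statistic.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L || anyNA(x) || anyNA(y))
    stop_devdelay("need >= 2 observations per group, no NA",
                  class = "devdelay_value_error")
  n <- c(n1 = length(x), n2 = length(y))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(test_outcome(c(t = 0), 1, "Welch two-sample t-test", n,
                          note = "zero variance in both groups; equal means"))
    return(test_outcome(c(t = sign(mean(x) - mean(y)) * Inf), 0,
                        "Welch two-sample t-test", n,
                        note = "degenerate: zero variance in both groups, unequal means"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  test_outcome(c(t = unname(tt$statistic)), tt$p.value,
               "Welch two-sample t-test", n)
}
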