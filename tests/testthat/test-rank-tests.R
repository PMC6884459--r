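# independent enumeration oracles, deliberately written in the most naive
# way possible (loop over explicit labelings / sign vectors)

oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  labelings <- utils::combn(N, n1, simplify = FALSE)
  hits <- sum(vapply(labelings, function(idx)
    abs(sum(r[idx]) - mu) >= obs - 1e-9, TRUE))
  hits / length(labelings)
}

oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  tot <- sum(r)
  obs <- abs(sum(r[d > 0]) - tot / 2)
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v <- apply(signs, 1, function(s) sum(r[s]))
  mean(abs(v - tot / 2) >= obs - 1e-9)
}

test_that("exact rank-sum test reproduces the published complete-separation p at n = 5 + 5", {
  out <- wilcoxon_rank_sum_exact(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
  expect_equal(out$p_value, 2 / 252)
  expect_equal(round(out$p_value, 4), 0.0079)
  expect_identical(unname(out$n_per_group), c(5L, 5L))
})

test_that("rank-sum edge cases: identical samples give p = 1; 3-vs-3 separation gives 2/20", {
  expect_equal(wilcoxon_rank_sum_exact(c(3, 1, 2), c(1, 2, 3))$p_value, 1)
  expect_equal(wilcoxon_rank_sum_exact(c(1, 2, 3), c(4, 5, 6))$p_value, 2 / 20)
  expect_error(wilcoxon_rank_sum_exact(numeric(0), 1),
               class = "devdelay_value_error")
})

test_that("exact rank-sum agrees with full enumeration for all pooled sizes <= 12", {
  set.seed(30)
  for (i in 1:40) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    # integer draws produce frequent ties, exercising mid-ranks
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(wilcoxon_rank_sum_exact(x, y)$p_value,
                 oracle_rank_sum_p(x, y),
                 info = sprintf("x=%s y=%s", toString(x), toString(y)))
  }
})

test_that("exact rank-sum matches stats::wilcox.test on tie-free samples", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    expect_equal(wilcoxon_rank_sum_exact(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("signed-rank edge cases match closed forms", {
  # one nonzero difference: both sign assignments equally extreme
  expect_equal(wilcoxon_signed_rank_exact(c(0, 2))$p_value, 1)
  # all 20 differences of one sign: only the two extreme tails qualify
  expect_equal(wilcoxon_signed_rank_exact(rep(1.5, 20) + (1:20) / 100)$p_value,
               2 / 2^20)
  # a symmetric multiset is maximally unsurprising
  expect_equal(wilcoxon_signed_rank_exact(c(-3, 3))$p_value, 1)
  expect_error(wilcoxon_signed_rank_exact(c(0, 0)),
               class = "devdelay_value_error")
})

test_that("exact signed-rank agrees with full sign enumeration for n <= 10", {
  set.seed(32)
  for (i in 1:30) {
    d <- sample(c(-4:-1, 1:4), sample(2:10, 1), replace = TRUE)
    expect_equal(wilcoxon_signed_rank_exact(d)$p_value,
                 oracle_signed_rank_p(d),
                 info = toString(d))
  }
})

test_that("Kruskal-Wallis matches hand rank arithmetic and the two-group rank-sum statistic", {
  # identical groups: no rank separation at all
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  out <- kruskal_wallis(g)
  expect_equal(unname(out$statistic), 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1)

  # complete separation of 3/3/3: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  rbar <- c(2, 5, 8); H_hand <- 12 / (9 * 10) * sum(3 * (rbar - 5)^2)
  expect_equal(unname(kruskal_wallis(groups)$statistic), H_hand)

  # two groups: H equals the squared standardized rank-sum statistic
  set.seed(33)
  x <- rnorm(5); y <- rnorm(4)
  H <- unname(kruskal_wallis(list(x, y))$statistic)
  W <- unname(wilcoxon_rank_sum_exact(x, y)$statistic)
  N <- 9; mu <- 5 * (N + 1) / 2; v <- 5 * 4 * (N + 1) / 12
  expect_equal(H, (W - mu)^2 / v)

  expect_error(kruskal_wallis(list(1:3)), class = "devdelay_value_error")
})

test_that("Welch's t handles null, antisymmetry and degenerate variances", {
  x <- c(1, 2, 3)
  out <- welch_t(x, x)
  expect_equal(unname(out$statistic), 0)
  expect_equal(out$p_value, 1)

  set.seed(34)
  a <- rnorm(4); b <- rnorm(6, 1)
  expect_equal(welch_t(a, b)$p_value, welch_t(b, a)$p_value)
  expect_equal(unname(welch_t(a, b)$statistic), -unname(welch_t(b, a)$statistic))

  expect_equal(welch_t(c(2, 2), c(2, 2))$p_value, 1)
  degen <- welch_t(c(2, 2), c(3, 3))
  expect_equal(degen$p_value, 0)
  expect_match(degen$note, "degenerate")
})

test_that("Welch's t p-value matches direct integration of the t density at Welch df", {
  x <- c(1.2, 3.4, 2.2); y <- c(4.1, 5.9, 5.2)
  out <- welch_t(x, y)
  v1 <- var(x) / 3; v2 <- var(y) / 3
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / 2 + v2^2 / 2)
  p_quad <- 2 * stats::integrate(function(u) stats::dt(u, df),
                                 abs(tstat), Inf)$value
  expect_equal(unname(out$statistic), tstat)
  expect_equal(out$p_value, p_quad, tolerance = 1e-6)
})
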