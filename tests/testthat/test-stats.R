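test_that("percentile bootstrap degenerates correctly and reproduces per seed", {
  const <- rep(3.7, 20)
  ci <- bootstrap_ci(const, "median", seed = 1)
  expect_equal(ci$lo, 3.7)
  expect_equal(ci$hi, 3.7)
  expect_equal(ci$point, 3.7)
  expect_equal(ci$n_boot, 1000L)  # study default: 1000 iterations
  x <- stats::rnorm(40)
  a <- bootstrap_ci(x, "mean", seed = 42)
  b <- bootstrap_ci(x, "mean", seed = 42)
  expect_identical(a[c("point", "lo", "hi")], b[c("point", "lo", "hi")])
  c2 <- bootstrap_ci(x, "mean", seed = 43)
  expect_false(identical(a$lo, c2$lo))
  expect_error(bootstrap_ci(numeric(0)), "empty")
  # point always inside the percentile interval for the median
  expect_true(a$lo <= a$point && a$point <= a$hi)
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(9)
  pop <- stats::rnorm(5000)
  w <- vapply(c(20, 100, 500), function(n) {
    ci <- bootstrap_ci(pop[seq_len(n)], "mean", n_boot = 500, seed = 2)
    ci$hi - ci$lo
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("signed-rank test takes the exact path and drops zeros", {
  # all differences positive, n = 6, no ties: p = 2/2^6
  a <- c(5, 6, 7, 8, 9, 10); b <- a - c(1, 2, 3, 4, 5, 6)
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$p_value, 2 / 64)
  expect_match(res$notes, "exact")
  # symmetry under swapping the arms
  expect_equal(wilcoxon_signed_rank(b, a)$p_value, res$p_value)
  # identical arms: p = 1 with a degeneracy flag
  res2 <- wilcoxon_signed_rank(a, a)
  expect_equal(res2$p_value, 1)
  expect_equal(res2$flag, "degenerate")
  # zero differences are dropped before ranking
  res3 <- wilcoxon_signed_rank(c(a, 4), c(b, 4))
  expect_equal(res3$n, 6L)
  expect_equal(res3$p_value, res$p_value)
})

test_that("exact signed-rank p equals full sign enumeration for n <= 8", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    d <- round(stats::runif(n, -5, 5), 3)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    res <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_equal(res$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles exact, tied and swapped inputs", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)  # 2 / choose(6, 3)
  # identical multisets: U = n_a*n_b/2
  res2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(res2$statistic), 9 / 2)
  # label swap flips U to n_a*n_b - U, same p
  r1 <- mann_whitney_u(c(1, 2, 7), c(3, 5, 6))
  r2 <- mann_whitney_u(c(3, 5, 6), c(1, 2, 7))
  expect_equal(r2$statistic, 9 - r1$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("exact Mann-Whitney p equals full label enumeration for n <= 8", {
  set.seed(19)
  for (rep in 1:8) {
    na <- sample(3:4, 1); nb <- sample(3:4, 1)
    x <- sample(seq(0.1, 9.9, 0.1), na + nb)  # distinct, no ties
    res <- mann_whitney_u(x[seq_len(na)], x[-seq_len(na)])
    expect_equal(res$p_value, oracle_mwu_p(x[seq_len(na)], x[-seq_len(na)]),
                 tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis follows the rank formula and is rank invariant", {
  # identical groups: H = 0, p = 1
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- kruskal_wallis(g)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1)
  # three singleton groups with distinct values: H = 2
  res2 <- kruskal_wallis(list(1, 5, 9))
  expect_equal(unname(res2$statistic), 2)
  # invariance under a monotone transform
  g2 <- list(stats::runif(5), stats::runif(6), stats::runif(4))
  expect_equal(kruskal_wallis(g2)$statistic,
               kruskal_wallis(lapply(g2, function(v) exp(3 * v)))$statistic)
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("Spearman correlation matches the rank-difference formula", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  expect_equal(spearman(1:4, c(2, 1, 4, 3))$rho, 0.6)
  res <- spearman(1:5, rep(2, 5))
  expect_equal(res$flag, "degenerate")
  expect_true(is.na(res$rho))
  # rank-based: invariant under monotone rescale
  x <- stats::runif(20); y <- stats::runif(20)
  expect_equal(spearman(x, y)$rho, spearman(x, y * 60)$rho)
})

test_that("Bland-Altman bias and limits follow the 1.96 SD convention", {
  a <- c(1, 2, 3, 4)
  ba <- bland_altman(a, a)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)
  ba2 <- bland_altman(a, a + 2)
  expect_equal(ba2$bias, -2)
  expect_equal(ba2$loa_low, -2)
  expect_equal(ba2$loa_high, -2)
  # diffs {1,-1,1,-1}: sd = 2/sqrt(3)
  ba3 <- bland_altman(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$loa_high, 1.96 * 2 / sqrt(3))
  expect_equal(ba3$loa_low, -1.96 * 2 / sqrt(3))
  p <- autoplot(ba3)
  expect_s3_class(p, "ggplot")
})

test_that("all reported p-values stay in [0, 1] on random inputs", {
  set.seed(31)
  for (rep in 1:20) {
    a <- stats::rnorm(sample(3:12, 1))
    b <- stats::rnorm(sample(3:12, 1))
    expect_true(dplyr::between(mann_whitney_u(a, b)$p_value, 0, 1))
    n <- sample(3:12, 1)
    x <- stats::rnorm(n)
    expect_true(dplyr::between(
      wilcoxon_signed_rank(x, stats::rnorm(n))$p_value, 0, 1))
  }
})
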