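test_that("Friedman: no rank variation gives statistic 0, perfect ordering the maximum 2n", {
  x <- matrix(rep(rnorm(6), 3), 6)         # three identical columns
  f <- friedman_test(x)
  expect_equal(f$statistic, 0)
  expect_equal(f$p.value, 1)

  set.seed(1)
  y <- cbind(rnorm(10, 3), rnorm(10, 2), rnorm(10, 1))
  y <- t(apply(y, 1, sort, decreasing = TRUE))  # every row Conv > BVS90 > BVS80
  fy <- friedman_test(y)
  expect_equal(fy$statistic, 20)           # 2n for k = 3, n = 10
  expect_equal(fy$df, 2)
  expect_error(friedman_test(y[, 1:2]), "at least 3")
  expect_error(friedman_test(cbind(c(1, NA), c(1, 2), c(3, 4))), "missing")
})

test_that("Friedman chi-square agrees with stats::friedman.test on tie-free data", {
  set.seed(4)
  for (i in 1:5) {
    x <- matrix(rnorm(36), 12, 3)
    f <- friedman_test(x)
    ref <- stats::friedman.test(x)
    expect_equal(f$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(f$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Friedman permutation p equals exhaustive within-row enumeration", {
  set.seed(9)
  for (i in 1:2) {
    x <- matrix(rnorm(12), 4, 3)           # (3!)^4 = 1296 arrangements
    f <- friedman_test(x, method = "permutation")
    expect_match(f$method, "exact")
    expect_equal(f$p.value, oracle_friedman_perm(x), tolerance = 1e-12)
  }
  # Monte Carlo fallback stays close to the chi-square reference at n = 20
  set.seed(10)
  big <- matrix(rnorm(60), 20, 3)
  fmc <- friedman_test(big, method = "permutation", n_perm = 4000)
  expect_match(fmc$method, "Monte Carlo")
  expect_lt(abs(fmc$p.value - friedman_test(big)$p.value), 0.08)
})

test_that("Friedman statistic is invariant to monotone within-row transformations", {
  set.seed(12)
  x <- matrix(rlnorm(30), 10, 3)
  f0 <- friedman_test(x)$statistic
  expect_equal(friedman_test(log(x))$statistic, f0)
  expect_equal(friedman_test(x^3)$statistic, f0)
  expect_equal(friedman_test(exp(x / max(x)))$statistic, f0)
})

test_that("Wilcoxon signed-rank: zero handling, exact small-sample p, enumeration oracle", {
  w0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(w0$all_zero)
  expect_equal(w0$p.value, 1)
  expect_equal(w0$zeros_dropped, 3)

  # five all-positive differences: two-sided exact p = 2/2^5
  w <- wilcoxon_signed_rank(c(1.2, 2.3, 0.7, 1.9, 3.1), rep(0, 5))
  expect_true(w$exact)
  expect_equal(w$p.value, 0.0625)

  set.seed(14)
  for (n in c(6, 8, 10)) {
    a <- rnorm(n)
    b <- rnorm(n)
    w <- wilcoxon_signed_rank(a, b)
    expect_equal(w$p.value, oracle_wilcoxon_exact(a, b), tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal-length")
})

test_that("both tests hold their type-I error near 5% under an exchangeable null", {
  set.seed(20)
  reps <- 2000
  rej_w <- mean(replicate(reps, {
    d <- matrix(rnorm(40), 20)
    wilcoxon_signed_rank(d[, 1], d[, 2])$p.value < 0.05
  }))
  band <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_gt(rej_w, 0.05 - band - 0.005)
  expect_lt(rej_w, 0.05 + band + 0.005)

  rej_f <- mean(replicate(reps, {
    friedman_test(matrix(rnorm(60), 20, 3))$p.value < 0.05
  }))
  expect_gt(rej_f, 0.05 - band - 0.005)
  expect_lt(rej_f, 0.05 + band + 0.005)
})

test_that("Bonferroni adjustment is the capped multiple, monotone, never below raw", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  p <- c(0.001, 0.02, 0.2, 0.9)
  a <- bonferroni_adjust(p, 4)
  expect_true(all(a >= p))
  expect_true(all(diff(a[order(p)]) >= 0))
  expect_error(bonferroni_adjust(1.2, 3), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "at least")
})

test_that("reduction summary reports medians, ranges, and mean per-patient reductions", {
  x <- cbind(Conv = c(2, 2, 2), BVS = c(1.6, 1.6, 1.6))
  r <- reduction_summary(x, "Conv")
  expect_equal(r$mean_pct_reduction[r$condition == "BVS"], 20)
  expect_equal(r$mean_pct_reduction[r$condition == "Conv"], 0)
  expect_equal(r$median, c(2, 1.6))

  single <- matrix(c(1.198, 1.05), 1, dimnames = list(NULL, c("Conv", "BVS")))
  rs <- reduction_summary(single, "Conv")
  expect_equal(rs$median[1], 1.198)
  expect_equal(rs$min[1], rs$max[1])       # degenerate range

  withzero <- cbind(Conv = c(2, 0), BVS = c(1, 1))
  expect_warning(rz <- reduction_summary(withzero, "Conv"), "zero baseline")
  expect_equal(rz$mean_pct_reduction[2], 50)
  expect_error(reduction_summary(x, "Nope"), "baseline")
})

test_that("compare_levels runs post-hoc tests only on a significant Friedman unless forced", {
  set.seed(30)
  null3 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  while (friedman_test(null3)$p.value < 0.2) null3 <- matrix(rnorm(30), 10, 3,
                                                             dimnames = list(NULL, c("A", "B", "C")))
  cl <- compare_levels(null3)
  expect_null(cl$posthoc)
  cl2 <- compare_levels(null3, always_posthoc = TRUE)
  expect_equal(nrow(cl2$posthoc), 3)
  expect_true(all(cl2$posthoc$p_adj >= cl2$posthoc$p_raw))

  # identical conditions: all post-hoc p-values are 1
  same <- matrix(rep(rnorm(8), 3), 8, dimnames = list(NULL, c("A", "B", "C")))
  cls <- compare_levels(same, always_posthoc = TRUE)
  expect_true(all(cls$posthoc$p_adj == 1))
  expect_true(all(cls$posthoc$p_raw == 1))
})
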