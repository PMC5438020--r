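test_that("percent change follows the baseline-minus-post convention", {
  expect_equal(percent_change(0.014, 0.014), 0)
  expect_equal(percent_change(0.010, 0.005), 50)
  # group means 0.0120 -> 0.0123: change of means is -2.5% (post above
  # baseline is negative under this convention)
  expect_equal(percent_change(0.0120, 0.0123), -2.5)
  expect_error(percent_change(0, 0.01), "positive")
  expect_error(percent_change(-0.01, 0.01), "positive")
})

test_that("percent change inverts exactly: pc(b, b*(1 - q/100)) = q", {
  set.seed(21)
  for (i in 1:50) {
    b <- runif(1, 1e-4, 1)
    q <- runif(1, -150, 99)
    expect_equal(percent_change(b, b * (1 - q / 100)), q)
  }
})

test_that("correlation handles exact, hand-computed and cross-checked cases", {
  expect_equal(correlate(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(correlate(c(1, 2, 3), c(3, 2, 1))$r, -1)
  # hand computation: cov = 1.5, sd_x = 1, sd_y = sqrt(7/3)
  expect_equal(correlate(c(1, 2, 3), c(1, 2, 4))$r, 1.5 / sqrt(7 / 3),
               tolerance = 1e-12)
  expect_equal(correlate(c(1, 2, 3), c(1, 2, 4))$r, 0.98198, tolerance = 1e-5)

  set.seed(31)
  x <- rnorm(25); y <- x + rnorm(25)
  for (m in c("pearson", "spearman")) {
    got <- correlate(x, y, method = m)
    ct <- cor.test(x, y, method = m, exact = FALSE)
    expect_equal(got$r, unname(ct$estimate))
    expect_equal(got$p_two_tailed, ct$p.value, tolerance = 1e-9)
  }
})

test_that("correlation is affine-equivariant and records exclusions", {
  set.seed(32)
  x <- rnorm(12); y <- rnorm(12)
  base <- correlate(x, y)
  expect_equal(correlate(2 * x + 1, y)$r, base$r)
  expect_equal(correlate(-2 * x + 1, y)$r, -base$r)

  ids <- sprintf("s%02d", 1:12)
  ex <- correlate(x, y, ids = ids, exclude = "s03")
  expect_equal(ex$n, 11)
  expect_equal(ex$excluded_ids, "s03")
  expect_equal(ex$r, cor(x[-3], y[-3]))

  expect_error(correlate(1:2, 2:3), "3 pairs")
  expect_error(correlate(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("paired t matches hand arithmetic and flags degenerate differences", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_tailed, 1)
  hand <- paired_t(c(1, 2, 3), c(2, 3, 5))
  expect_equal(hand$t, -4, tolerance = 1e-12)   # mean_d/(sd_d/sqrt(n))
  expect_equal(hand$df, 2)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero difference variance")
  # agreement with t.test
  set.seed(41)
  a <- rnorm(10); b <- a + rnorm(10, 0.2)
  tt <- t.test(a, b, paired = TRUE)
  got <- paired_t(a, b)
  expect_equal(got$t, unname(tt$statistic))
  expect_equal(got$p_two_tailed, tt$p.value)
})

test_that("summary two-sample t reproduces the printed injected-activity test", {
  # printed group summaries: 147.3 (6.6) vs 147.7 (2.7), n = 8 each
  inj <- two_sample_t_summary(147.3, 6.6, 8, 147.7, 2.7, 8)
  expect_equal(round(inj$t, 2), -0.16)
  expect_equal(inj$df, 14)
  expect_equal(round(inj$p_two_tailed, 2), 0.88)

  expect_equal(two_sample_t_summary(10, 2, 5, 10, 2, 5)$t, 0)
  expect_equal(two_sample_t_summary(10, 2, 4, 12, 2, 4)$t, -sqrt(2),
               tolerance = 1e-12)
  # antisymmetry
  a <- two_sample_t_summary(1.2, 0.5, 6, 0.9, 0.8, 9)
  b <- two_sample_t_summary(0.9, 0.8, 9, 1.2, 0.5, 6)
  expect_equal(a$t, -b$t)
  expect_error(two_sample_t_summary(1, 0, 5, 2, 0, 5), "both SDs zero")
  # pooled result matches t.test(var.equal = TRUE) on raw data
  set.seed(51)
  x <- rnorm(8, 10); y <- rnorm(12, 11)
  tt <- t.test(x, y, var.equal = TRUE)
  got <- two_sample_t_summary(mean(x), sd(x), 8, mean(y), sd(y), 12)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(got$p_two_tailed, tt$p.value, tolerance = 1e-9)
})

test_that("reliability: perfect agreement, offset ordering, null calibration", {
  x <- c(0.012, 0.013, 0.015, 0.014, 0.016)
  perf <- reliability(x, x)
  expect_equal(perf$icc, 1)
  expect_equal(perf$trv_percent, 0)

  off_a <- reliability(x, x + 0.005, "agreement")
  off_c <- reliability(x, x + 0.005, "consistency")
  expect_lt(off_a$icc, off_c$icc)          # offsets penalize agreement only
  expect_equal(off_c$icc, 1)

  # consistency ICC is invariant to a common affine transform
  set.seed(61)
  s1 <- rnorm(50, 0.014, 0.0015); s2 <- s1 + rnorm(50, 0, 5e-4)
  expect_equal(reliability(3 * s1 + 1, 3 * s2 + 1, "consistency")$icc,
               reliability(s1, s2, "consistency")$icc, tolerance = 1e-12)

  # independent scans: ICC near zero
  set.seed(62)
  a <- rnorm(1e4, 10); b <- rnorm(1e4, 10)
  expect_lt(abs(reliability(a, b)$icc), 0.05)

  # variance-components oracle: ICC -> sb^2/(sb^2 + sm^2)
  set.seed(63)
  truth <- rnorm(2e4, 0.014, 0.0015)
  m1 <- truth + rnorm(2e4, 0, 1e-3); m2 <- truth + rnorm(2e4, 0, 1e-3)
  expect_lt(abs(reliability(m1, m2)$icc - 0.0015^2 / (0.0015^2 + 1e-6)), 0.02)
  expect_error(reliability(c(1, 1), c(1, 1)), "3 subjects")
})

test_that("Lilliefors normality statistic matches nortest and separates skewed data", {
  set.seed(71)
  x <- rnorm(50)
  got <- ks_normality(x)
  expect_equal(got$statistic, unname(nortest::lillie.test(x)$statistic),
               tolerance = 1e-12)
  expect_gt(got$p, 0.05)                   # a clean normal sample

  # statistic shrinks with n under the null
  set.seed(72)
  d_small <- ks_normality(rnorm(50))$statistic
  d_big <- ks_normality(rnorm(5000))$statistic
  expect_lt(d_big, d_small)

  # a heavily skewed sample is detected
  set.seed(73)
  ex <- ks_normality(rexp(500))
  nm <- ks_normality(rnorm(500))
  expect_gt(ex$statistic, nm$statistic)
  expect_lt(ex$p, 0.001)

  expect_error(ks_normality(c(1, 2)), "3 observations")
  expect_error(ks_normality(rep(1, 10)), "zero variance")
  # deterministic p despite the Monte-Carlo correction
  expect_identical(ks_normality(x), ks_normality(x))
})
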