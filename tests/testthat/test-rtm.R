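random_2x2_cohort <- function(n1, n2) {
  data.frame(
    subject_id = sprintf("s%02d", seq_len(n1 + n2)),
    arm = rep(c("test_retest", "challenge"), c(n1, n2)),
    ki_scan1 = rnorm(n1 + n2, 0.014, 0.0015),
    ki_scan2 = rnorm(n1 + n2, 0.014, 0.0015)
  )
}

test_that("Levene's test: null case, hand example, dispersion monotonicity", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  same <- levene_test(g)
  expect_equal(same$W, 0)
  expect_equal(same$p, 1)

  # hand sums of squares on absolute deviations from the means
  hand <- levene_test(list(c(0, 1, 2), c(0, 2, 4)), center = "mean")
  expect_equal(hand$W, 0.8, tolerance = 1e-12)
  expect_equal(c(hand$df1, hand$df2), c(1, 4))

  wide <- levene_test(list(c(0, 1, 2), 10 * c(0, 2, 4)))
  expect_gt(wide$W, hand$W)
  expect_error(levene_test(list(c(1, 2), c(3))), "n >= 2")
})

test_that("Levene's test agrees with the car implementation", {
  set.seed(81)
  g1 <- rnorm(15); g2 <- rnorm(20, sd = 2); g3 <- rnorm(10, sd = 0.5)
  for (ctr in c("mean", "median")) {
    got <- levene_test(list(g1, g2, g3), center = ctr)
    ref <- car::leveneTest(c(g1, g2, g3),
                           factor(rep(1:3, c(15, 20, 10))),
                           center = get(ctr))
    expect_equal(got$W, ref[1, "F value"], tolerance = 1e-9)
    expect_equal(got$p, ref[1, "Pr(>F)"], tolerance = 1e-9)
  }
})

test_that("ANOVA interaction equals the hand example and nulls out equal changes", {
  d <- data.frame(arm = rep(c("a1", "a2"), each = 3),
                  ki_scan1 = c(1, 2, 3, 0, 0, 0),
                  ki_scan2 = c(1, 3, 5, 2, 3, 4))
  got <- mixed_anova_interaction(d)
  expect_equal(got$f, 6, tolerance = 1e-12)   # change scores (0,1,2) vs (2,3,4)
  expect_equal(c(got$df1, got$df2), c(1, 4))

  null_d <- data.frame(arm = rep(c("a1", "a2"), each = 4),
                       ki_scan1 = c(1, 2, 3, 4, 11, 12, 13, 14),
                       ki_scan2 = c(1, 2, 3, 4, 11, 12, 13, 14) + c(0, 1, 0, 1))
  expect_lt(mixed_anova_interaction(null_d)$f, 1e-20)
  expect_error(mixed_anova_interaction(d[1:3, ]), "2 arms")
  expect_error(mixed_anova_interaction(data.frame(arm = "a")), "columns")
})

test_that("interaction F equals squared change-score t and the aov general path", {
  set.seed(82)
  for (i in 1:100) {
    d <- random_2x2_cohort(sample(3:10, 1), sample(3:10, 1))
    got <- mixed_anova_interaction(d)
    ch <- split(d$ki_scan2 - d$ki_scan1, d$arm)
    tt <- t.test(ch[[1]], ch[[2]], var.equal = TRUE)
    expect_equal(got$f, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(got$p, tt$p.value, tolerance = 1e-10)
  }
  # general repeated-measures sums-of-squares route via aov
  set.seed(83)
  d <- random_2x2_cohort(8, 12)
  long <- data.frame(
    subject = factor(rep(d$subject_id, 2)),
    arm = factor(rep(d$arm, 2)),
    scan = factor(rep(c("s1", "s2"), each = nrow(d))),
    ki = c(d$ki_scan1, d$ki_scan2)
  )
  fit <- stats::aov(ki ~ arm * scan + Error(subject / scan), data = long)
  tab <- summary(fit)[["Error: subject:scan"]][[1]]
  expect_equal(mixed_anova_interaction(d)$f, tab["arm:scan", "F value"],
               tolerance = 1e-8)
})

test_that("interaction regression recovers the generative regulation strength", {
  # exact identity: baseline coefficient 1, everything else 0
  set.seed(84)
  d <- random_2x2_cohort(6, 6)
  d$ki_scan2 <- d$ki_scan1
  ident <- interaction_regression(d)
  expect_equal(unname(ident$coefficients["baseline"]), 1, tolerance = 1e-8)
  expect_equal(unname(ident$coefficients["baseline_x_challenge"]), 0,
               tolerance = 1e-8)
  expect_equal(ident$adjusted_r2, 1, tolerance = 1e-8)

  # noise-free generated cohorts: interaction coefficient is exactly -gamma
  for (g in c(0.25, 0.6, 0.9)) {
    cfg <- cohort_config(n_per_arm = 10, sigma_measure = 0, sigma_drift = 0,
                         gamma = g, seed = round(1000 * g))
    co <- generate_cohort(cfg)
    fit <- interaction_regression(co)
    expect_equal(unname(fit$coefficients["baseline_x_challenge"]), -g,
                 tolerance = 1e-8)
  }

  # pure-noise outcome: adjusted R^2 near zero
  set.seed(85)
  big <- random_2x2_cohort(2500, 2500)
  expect_lt(abs(interaction_regression(big)$adjusted_r2), 0.02)

  single <- random_2x2_cohort(6, 6)
  single$arm <- "test_retest"
  expect_error(interaction_regression(single), "both arms")
  expect_error(interaction_regression(random_2x2_cohort(2, 2)), "N >= 5")
})

test_that("Fisher z is the odd atanh fixed-point transform", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  z <- seq(-5, 5, by = 0.25)
  expect_equal(fisher_z(tanh(z)), z, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("comparing correlations: equality, the two-study values, antisymmetry", {
  eq <- compare_correlations(0.4, 10, 0.4, 20)
  expect_equal(eq$z_diff, 0)
  expect_equal(eq$p_two_tailed, 1)

  # the two printed study correlations under the independent-samples test:
  # |z| ~ 1.45, p ~ 0.15 -- far from significant
  two <- compare_correlations(-0.57, 8, -0.90, 11)
  expect_equal(abs(two$z_diff), 1.45, tolerance = 0.01)
  expect_equal(two$p_two_tailed, 0.148, tolerance = 0.005)

  sw <- compare_correlations(-0.90, 11, -0.57, 8)
  expect_equal(sw$z_diff, -two$z_diff)
  expect_error(compare_correlations(0.5, 3, 0.4, 10), "insufficient")

  # dependent (Steiger) variant: needs the inter-correlation and one sample
  st <- compare_correlations(0.5, 30, 0.5, 30, method = "steiger_dependent",
                             r_inter = 0.3)
  expect_equal(st$z_diff, 0)
  expect_error(compare_correlations(0.5, 30, 0.4, 30,
                                    method = "steiger_dependent"), "r_inter")
  expect_error(compare_correlations(0.5, 30, 0.4, 20,
                                    method = "steiger_dependent",
                                    r_inter = 0.3), "single sample")
})

test_that("the battery reproduces a component-wise formula recomputation", {
  tr_cfg <- cohort_config(n_per_arm = 8, sigma_drift = 5e-4, seed = 101)
  ch_cfg <- cohort_config(n_per_arm = 12, gamma = 0.6, sigma_drift = 5e-4,
                          seed = 102)
  tr <- generate_cohort(tr_cfg, arms = "test_retest")
  ch <- generate_cohort(ch_cfg, arms = "challenge")
  rpt <- rtm_battery(tr, ch)

  d1 <- tr$ki_scan2 - tr$ki_scan1
  d2 <- ch$ki_scan2 - ch$ki_scan1

  # Levene by direct sums of squares
  z <- c(abs(d1 - mean(d1)), abs(d2 - mean(d2)))
  grp <- rep(1:2, c(8, 12))
  ssb <- 8 * (mean(z[grp == 1]) - mean(z))^2 + 12 * (mean(z[grp == 2]) - mean(z))^2
  ssw <- sum((z - ave(z, grp))^2)
  expect_equal(rpt$levene$W, (ssb / 1) / (ssw / 18), tolerance = 1e-10)

  # interaction F from the pooled two-sample t on change scores
  sp2 <- (7 * var(d1) + 11 * var(d2)) / 18
  t_ch <- (mean(d1) - mean(d2)) / sqrt(sp2 * (1 / 8 + 1 / 12))
  expect_equal(rpt$anova$f, t_ch^2, tolerance = 1e-10)

  # regression against a direct lm fit
  pooled <- rbind(tr, ch)
  fit <- lm(ki_scan2 ~ ki_scan1 * I(arm == "challenge"), data = pooled)
  expect_equal(unname(rpt$regression$coefficients), unname(coef(fit)),
               tolerance = 1e-10)
  expect_equal(rpt$regression$adjusted_r2, summary(fit)$adj.r.squared,
               tolerance = 1e-10)

  # correlations (gain convention) and their Fisher comparison
  r1 <- cor(tr$ki_scan1, 100 * (tr$ki_scan2 - tr$ki_scan1) / tr$ki_scan1)
  r2 <- cor(ch$ki_scan1, 100 * (ch$ki_scan2 - ch$ki_scan1) / ch$ki_scan1)
  expect_equal(rpt$correlations$test_retest$r, r1, tolerance = 1e-12)
  expect_equal(rpt$correlations$challenge$r, r2, tolerance = 1e-12)
  expect_lt(r2, 0)   # regulation shows as a negative correlation
  zd <- (atanh(r1) - atanh(r2)) / sqrt(1 / 5 + 1 / 9)
  expect_equal(rpt$correlation_comparison$z_diff, zd, tolerance = 1e-12)
})

test_that("deterministic null cohorts give an all-null, degenerate-flagged report", {
  cfg0 <- function(seed) cohort_config(n_per_arm = 6, sigma_measure = 0,
                                       sigma_drift = 0, gamma = 0, seed = seed)
  tr <- generate_cohort(cfg0(1), arms = "test_retest")
  ch <- generate_cohort(cfg0(2), arms = "challenge")
  rpt <- rtm_battery(tr, ch)
  expect_equal(rpt$anova$f, 0)
  expect_equal(rpt$anova$p, 1)
  expect_true(isTRUE(rpt$correlations$test_retest$degenerate))
  expect_true(isTRUE(rpt$correlations$challenge$degenerate))
  expect_true(isTRUE(rpt$correlation_comparison$degenerate))
})

test_that("exclusions propagate through the battery bookkeeping", {
  tr <- generate_cohort(cohort_config(n_per_arm = 8, seed = 5), arms = "test_retest")
  ch <- generate_cohort(cohort_config(n_per_arm = 12, gamma = 0.5, seed = 6),
                        arms = "challenge")
  full <- rtm_battery(tr, ch)
  drop1 <- rtm_battery(tr, ch, exclude = "ch_01")
  expect_equal(unname(drop1$n), c(8, 11))
  expect_equal(unname(full$n), c(8, 12))
  expect_equal(drop1$correlations$challenge$n, 11)
  expect_equal(drop1$exclusions, "ch_01")
})
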