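#' Type-I error and power of the regression-to-the-mean battery
#'
#' Monte-Carlo calibration of the battery against the cohort generator:
#' for each regulation strength in `gamma_grid`, simulate `n_sim` study
#' pairs (default 8 test-retest + 12 challenge subjects, the sample sizes
#' of the emulated design), run (a) the group-by-change ANOVA interaction
#' and (b) the independent-samples Fisher-z comparison of the two
#' baseline-versus-percent-change correlations, and record the fraction of
#' pairs where each rejects at `alpha`. At `gamma = 0` the rejection rate
#' is the battery's false-positive rate under pure regression to the mean;
#' its growth with `gamma` is the power curve.
#'
#' @param gamma_grid regulation strengths to simulate.
#' @param n_sim simulated study pairs per grid point (>= 100).
#' @param alpha two-tailed significance level.
#' @param seed integer seed for the whole grid.
#' @param n_test_retest,n_challenge per-arm sample sizes.
#' @param base_config a [cohort_config()] supplying all other generator
#'   parameters (its `n_per_arm`, `gamma` and `seed` are overridden).
#' @return Data frame with one row per gamma: `gamma`, `anova_rate`,
#'   `corr_rate`, `n_sim`, `alpha`.
#' @export
calibration_sim <- function(gamma_grid = c(0, 0.3, 0.6, 0.9),
                            n_sim = 2000, alpha = 0.05, seed = 1,
                            n_test_retest = 8, n_challenge = 12,
                            base_config = cohort_config()) {
  if (!is.numeric(n_sim) || n_sim < 100)
    stop("configuration error: n_sim must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop("configuration error: alpha must be in (0, 1)")
  validate_cohort_config(base_config)

  rows <- with_local_seed(seed, {
    lapply(gamma_grid, function(g) {
      anova_rej <- corr_rej <- logical(n_sim)
      for (s in seq_len(n_sim)) {
        tr <- .sim_arm(n_test_retest, base_config, gamma = 0)
        ch <- .sim_arm(n_challenge, base_config, gamma = g)
        # ANOVA interaction = squared pooled t on change scores
        d1 <- tr$ki_scan2 - tr$ki_scan1
        d2 <- ch$ki_scan2 - ch$ki_scan1
        tt <- two_sample_t_summary(mean(d1), stats::sd(d1), length(d1),
                                   mean(d2), stats::sd(d2), length(d2))
        anova_rej[s] <- tt$p_two_tailed < alpha
        r1 <- stats::cor(tr$ki_scan1, percent_change(tr$ki_scan1, tr$ki_scan2))
        r2 <- stats::cor(ch$ki_scan1, percent_change(ch$ki_scan1, ch$ki_scan2))
        corr_rej[s] <- if (abs(r1) < 1 && abs(r2) < 1) {
          compare_correlations(r1, length(d1), r2, length(d2))$p_two_tailed < alpha
        } else FALSE
      }
      data.frame(gamma = g, anova_rate = mean(anova_rej),
                 corr_rate = mean(corr_rej), n_sim = n_sim, alpha = alpha)
    })
  })
  do.call(rbind, rows)
}

# fast inner generator: one arm, ambient RNG, no data.frame bookkeeping
.sim_arm <- function(n, cfg, gamma) {
  true1 <- pmax(stats::rnorm(n, cfg$mu_ki, cfg$sigma_between), cfg$ki_floor)
  true2 <- true1 + gamma * (cfg$setpoint - true1) +
    stats::rnorm(n, 0, cfg$sigma_drift)
  list(
    ki_scan1 = pmax(true1 + stats::rnorm(n, 0, cfg$sigma_measure), cfg$ki_floor),
    ki_scan2 = pmax(true2 + stats::rnorm(n, 0, cfg$sigma_measure), cfg$ki_floor)
  )
}
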