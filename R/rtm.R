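#' Levene's test for equality of group variances
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group centre. `center = "mean"` is the classical Levene test;
#' `center = "median"` is the Brown-Forsythe variant.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @param center `"mean"` or `"median"`.
#' @return List with `W` (the F statistic on absolute deviations), `df1`,
#'   `df2`, `p`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.list(groups) || length(groups) < 2L)
    stop("insufficient data: need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("insufficient data: every group needs n >= 2")
  cfun <- if (center == "mean") mean else stats::median
  z <- unlist(lapply(groups, function(g) abs(g - cfun(g))))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  k <- length(groups); N <- length(z)
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (zg - zbar)^2)
  ssw <- sum((z - zg[g])^2)
  if (ssw == 0 && ssb == 0) return(list(W = 0, df1 = k - 1, df2 = N - k, p = 1))
  W <- (ssb / (k - 1)) / (ssw / (N - k))
  list(W = W, df1 = k - 1, df2 = N - k,
       p = stats::pf(W, k - 1, N - k, lower.tail = FALSE))
}

#' Group-by-change repeated-measures ANOVA interaction
#'
#' The two-arm, two-scan design's group (arm) x change (scan) interaction.
#' With two within-subject levels the interaction F is algebraically the
#' square of the pooled two-sample t on the per-subject change scores
#' (`ki_scan2 - ki_scan1`), with df (1, N - 2); that change-score route is
#' the implementation (numerically robust, sphericity trivially holds with
#' two levels). Identically-zero change scores in both arms return F = 0,
#' p = 1.
#'
#' @param cohort data frame with columns `arm`, `ki_scan1`, `ki_scan2`.
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
mixed_anova_interaction <- function(cohort) {
  need <- c("arm", "ki_scan1", "ki_scan2")
  if (!all(need %in% names(cohort)))
    stop("incomplete design: cohort needs columns ", paste(need, collapse = ", "))
  if (anyNA(cohort[need])) stop("incomplete design: missing scans")
  arms <- unique(cohort$arm)
  if (length(arms) != 2L) stop("incomplete design: need exactly 2 arms")
  ch <- split(cohort$ki_scan2 - cohort$ki_scan1, cohort$arm)
  n1 <- length(ch[[1]]); n2 <- length(ch[[2]])
  if (n1 < 2L || n2 < 2L) stop("incomplete design: each arm needs n >= 2")
  s1 <- stats::sd(ch[[1]]); s2 <- stats::sd(ch[[2]])
  if (s1 == 0 && s2 == 0) {
    # deterministic change scores: F is 0 (equal shifts) or infinite
    same <- mean(ch[[1]]) == mean(ch[[2]])
    return(list(f = if (same) 0 else Inf, df1 = 1, df2 = n1 + n2 - 2,
                p = if (same) 1 else 0))
  }
  tt <- two_sample_t_summary(mean(ch[[1]]), s1, n1, mean(ch[[2]]), s2, n2)
  f <- tt$t^2
  list(f = f, df1 = 1, df2 = n1 + n2 - 2,
       p = stats::pf(f, 1, n1 + n2 - 2, lower.tail = FALSE))
}

#' Baseline-by-group interaction regression
#'
#' OLS of the second-scan Ki on baseline Ki, the arm indicator
#' (challenge = 1), and their interaction:
#' `ki_scan2 ~ ki_scan1 + challenge + ki_scan1:challenge`. Under the
#' set-point regulation model with regulation strength `gamma`, the
#' population interaction coefficient is exactly `-gamma` (the challenge
#' arm's slope on baseline is `1 - gamma` versus 1 in the test-retest arm),
#' so the fitted interaction coefficient is the battery's estimate of the
#' drug's baseline-dependent effect.
#'
#' @param cohort data frame with `arm`, `ki_scan1`, `ki_scan2`; `arm` must
#'   contain `"test_retest"` (reference level) and `"challenge"`.
#' @return List with `coefficients`, `se`, `p_values` (per coefficient),
#'   `f`, `df1`, `df2`, `p`, `adjusted_r2`, and `interaction_ci95`.
#' @export
interaction_regression <- function(cohort) {
  need <- c("arm", "ki_scan1", "ki_scan2")
  if (!all(need %in% names(cohort)))
    stop("incomplete design: cohort needs columns ", paste(need, collapse = ", "))
  if (nrow(cohort) < 5L) stop("insufficient data: need N >= 5")
  challenge <- as.numeric(cohort$arm == "challenge")
  if (length(unique(challenge)) < 2L)
    stop("singular design: need both arms present")
  X <- cbind(1, cohort$ki_scan1, challenge, cohort$ki_scan1 * challenge)
  if (qr(X)$rank < 4L) stop("singular design: rank-deficient design matrix")
  dat <- data.frame(y = cohort$ki_scan2, baseline = cohort$ki_scan1,
                    challenge = challenge)
  fit <- stats::lm(y ~ baseline * challenge, data = dat)
  # noise-free cohorts fit exactly (the parameter-recovery case); silence
  # summary.lm's perfect-fit warning for them
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- stats::coef(sm)
  names_out <- c("intercept", "baseline", "challenge", "baseline_x_challenge")
  coefs <- stats::setNames(co[, 1], names_out)
  se <- stats::setNames(co[, 2], names_out)
  pv <- stats::setNames(co[, 4], names_out)
  fstat <- sm$fstatistic
  overall_p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  list(coefficients = coefs, se = se, p_values = pv,
       f = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
       df1 = if (is.null(fstat)) NA_real_ else unname(fstat[2]),
       df2 = if (is.null(fstat)) NA_real_ else unname(fstat[3]),
       p = unname(overall_p),
       adjusted_r2 = sm$adj.r.squared,
       interaction_ci95 = unname(coefs[4] + c(-1, 1) * tcrit * se[4]))
}

#' Fisher's r-to-z transform
#'
#' `z = atanh(r)`, the variance-stabilising transform for correlation
#' coefficients.
#'
#' @param r correlation(s), strictly inside (-1, 1).
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}

#' Compare two correlation coefficients
#'
#' Default `"independent"` method (the two samples share no subjects):
#' `z_diff = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` with Fisher-transformed
#' correlations and a two-tailed Normal p. `"steiger_dependent"`
#' implements Steiger's test for two correlations measured in the *same*
#' sample and sharing a variable (r_jk vs r_jh), which requires the
#' correlation `r_kh` between the two non-shared variables and a single n.
#'
#' @param r1,n1 first correlation and its sample size.
#' @param r2,n2 second correlation and its sample size (for the dependent
#'   method `n2` must equal `n1`).
#' @param method `"independent"` or `"steiger_dependent"`.
#' @param r_inter for the dependent method, the inter-correlation `r_kh`.
#' @return List with `r1`, `n1`, `r2`, `n2`, `z1`, `z2`, `z_diff`,
#'   `p_two_tailed`, `method`.
#' @export
compare_correlations <- function(r1, n1, r2, n2,
                                 method = c("independent", "steiger_dependent"),
                                 r_inter = NULL) {
  method <- match.arg(method)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("insufficient data: need n > 3 in both samples")
  z1 <- fisher_z(r1); z2 <- fisher_z(r2)
  if (method == "independent") {
    zd <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    if (is.null(r_inter)) stop("steiger_dependent requires r_inter")
    if (n1 != n2) stop("steiger_dependent requires a single sample (n1 == n2)")
    n <- n1
    rbar <- (r1 + r2) / 2
    # Steiger (1980): covariance of the two dependent correlations via the
    # shared-variable formula, pooled with the mean correlation
    psi <- r_inter * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_inter^2)
    s <- psi / (1 - rbar^2)^2
    zd <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  }
  list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z1 = z1, z2 = z2,
       z_diff = zd, p_two_tailed = 2 * stats::pnorm(-abs(zd)), method = method)
}

#' Run the full regression-to-the-mean test battery
#'
#' Orchestrates the four analyses that probe whether a negative
#' baseline-versus-change correlation in the challenge arm reflects true
#' regulation rather than regression to the mean: (1) Levene's test on the
#' change scores of the two arms, (2) the group-by-change ANOVA
#' interaction, (3) the baseline-by-group interaction regression, (4)
#' per-arm baseline-versus-percent-change correlations and their
#' independent-samples Fisher-z comparison. Degenerate components
#' (zero-variance correlations in noise-free data) are flagged rather than
#' erroring the battery.
#'
#' @param test_retest,challenge cohort data frames (as from
#'   [generate_cohort()]), each holding one arm.
#' @param exclude subject_ids to exclude everywhere.
#' @return An `rtm_report` list with elements `levene`, `anova`,
#'   `regression`, `correlations` (per arm), `correlation_comparison`,
#'   `exclusions`, `n` (per arm after exclusion).
#' @export
rtm_battery <- function(test_retest, challenge, exclude = character(0)) {
  tr <- test_retest[!(test_retest$subject_id %in% exclude), , drop = FALSE]
  ch <- challenge[!(challenge$subject_id %in% exclude), , drop = FALSE]
  if (nrow(tr) < 2L || nrow(ch) < 2L)
    stop("insufficient data: each arm needs n >= 2 after exclusions")
  tr$arm <- "test_retest"; ch$arm <- "challenge"
  pooled <- rbind(tr[c("subject_id", "arm", "ki_scan1", "ki_scan2")],
                  ch[c("subject_id", "arm", "ki_scan1", "ki_scan2")])

  change <- list(test_retest = tr$ki_scan2 - tr$ki_scan1,
                 challenge = ch$ki_scan2 - ch$ki_scan1)
  lev <- tryCatch(levene_test(change), error = function(e) list(degenerate = TRUE, message = conditionMessage(e)))
  an <- mixed_anova_interaction(pooled)
  reg <- tryCatch(interaction_regression(pooled),
                  error = function(e) list(degenerate = TRUE, message = conditionMessage(e)))

  # Correlations use the gain convention 100*(scan2 - scan1)/scan1, the
  # negation of percent_change(): under it a stabilising effect (and plain
  # regression to the mean) shows as a *negative* baseline-vs-change
  # correlation, the sign the field plots. The convention is recorded in
  # the result; the printed-formula convention is its exact negation.
  corr_arm <- function(d) {
    out <- tryCatch(
      correlate(d$ki_scan1, -percent_change(d$ki_scan1, d$ki_scan2),
                ids = d$subject_id),
      error = function(e) list(degenerate = TRUE, message = conditionMessage(e))
    )
    out$change_convention <- "gain: 100*(scan2-scan1)/scan1"
    out
  }
  c_tr <- corr_arm(tr); c_ch <- corr_arm(ch)
  cmp <- if (is.null(c_tr$degenerate) && is.null(c_ch$degenerate) &&
             abs(c_tr$r) < 1 && abs(c_ch$r) < 1) {
    compare_correlations(c_tr$r, c_tr$n, c_ch$r, c_ch$n, method = "independent")
  } else {
    list(degenerate = TRUE, message = "a per-arm correlation is degenerate")
  }

  structure(list(
    levene = lev, anova = an, regression = reg,
    correlations = list(test_retest = c_tr, challenge = c_ch),
    correlation_comparison = cmp,
    exclusions = as.character(exclude),
    n = c(test_retest = nrow(tr), challenge = nrow(ch))
  ), class = "rtm_report")
}

#' @export
print.rtm_report <- function(x, ...) {
  cat("<rtm_report>\n")
  cat(sprintf("  n: %d test-retest, %d challenge (excluded: %s)\n",
              x$n[1], x$n[2],
              if (length(x$exclusions)) paste(x$exclusions, collapse = ", ") else "none"))
  if (is.null(x$levene$degenerate))
    cat(sprintf("  Levene on change scores: W = %.3g, p = %.3g\n", x$levene$W, x$levene$p))
  cat(sprintf("  group x change ANOVA: F(%d,%d) = %.3g, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$f, x$anova$p))
  if (is.null(x$regression$degenerate))
    cat(sprintf("  interaction regression: F = %.3g, adj R^2 = %.3g, baseline x challenge = %.3g\n",
                x$regression$f, x$regression$adjusted_r2,
                x$regression$coefficients["baseline_x_challenge"]))
  for (arm in names(x$correlations)) {
    cc <- x$correlations[[arm]]
    if (is.null(cc$degenerate))
      cat(sprintf("  %s baseline vs %%change: r = %.3g, n = %d, p = %.3g\n",
                  arm, cc$r, cc$n, cc$p_two_tailed))
    else cat(sprintf("  %s baseline vs %%change: degenerate\n", arm))
  }
  if (is.null(x$correlation_comparison$degenerate))
    cat(sprintf("  correlation comparison: z = %.3g, p = %.3g\n",
                x$correlation_comparison$z_diff, x$correlation_comparison$p_two_tailed))
  invisible(x)
}
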