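#' Measurement noise implied by a target ICC
#'
#' With between-subject SD `sigma_between` and i.i.d. measurement noise of
#' SD `sigma_measure` on each scan, the two-scan intraclass correlation is
#' `sigma_between^2 / (sigma_between^2 + sigma_measure^2)`. Inverting gives
#' `sigma_measure = sigma_between * sqrt(1/icc - 1)`, the calibration used
#' for the generator's default noise level.
#'
#' @param icc target intraclass correlation in (0, 1].
#' @param sigma_between between-subject SD (min^-1).
#' @return Measurement SD (min^-1).
#' @examples
#' sigma_from_icc(0.834, 0.0015)   # ~0.00067 min^-1
#' @export
sigma_from_icc <- function(icc, sigma_between) {
  stopifnot(icc > 0, icc <= 1, sigma_between >= 0)
  sigma_between * sqrt(1 / icc - 1)
}

#' Cohort generator configuration
#'
#' Defaults reproduce the resting test-retest conditions the simulator is
#' calibrated to: true baseline influx constants Normal(0.014, 0.0015)
#' min^-1 and measurement noise set so the two-scan ICC is 0.834
#' (`sigma_measure = 0.0015 * sqrt(1/0.834 - 1)`).
#'
#' @param n_per_arm subjects per arm (>= 2).
#' @param mu_ki mean true baseline Ki (min^-1).
#' @param sigma_between between-subject SD of true baseline Ki (min^-1).
#' @param sigma_measure per-scan measurement noise SD (min^-1); default
#'   calibrated from `icc_target`.
#' @param sigma_drift SD of true between-scan drift (min^-1).
#' @param gamma regulation strength in \[0, 1\]: in the challenge arm the
#'   true second-scan Ki moves the fraction `gamma` of the way from its
#'   baseline value toward `setpoint` (partial-agonist stabilisation); 0
#'   means no drug effect.
#' @param setpoint regulation set-point (min^-1); defaults to `mu_ki`.
#' @param icc_target ICC used to calibrate the default `sigma_measure`.
#' @param ki_floor positivity floor for all Ki draws (min^-1).
#' @param interval_days nominal days between scans (bookkeeping only).
#' @param seed optional integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_arm = 10,
                          mu_ki = 0.014,
                          sigma_between = 0.0015,
                          sigma_measure = NULL,
                          sigma_drift = 0,
                          gamma = 0,
                          setpoint = mu_ki,
                          icc_target = 0.834,
                          ki_floor = 1e-4,
                          interval_days = 50,
                          seed = NULL) {
  if (is.null(sigma_measure)) sigma_measure <- sigma_from_icc(icc_target, sigma_between)
  cfg <- list(n_per_arm = n_per_arm, mu_ki = mu_ki,
              sigma_between = sigma_between, sigma_measure = sigma_measure,
              sigma_drift = sigma_drift, gamma = gamma, setpoint = setpoint,
              ki_floor = ki_floor, interval_days = interval_days, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(n_per_arm) || n_per_arm < 2 || n_per_arm != round(n_per_arm))
      stop("configuration error: n_per_arm must be an integer >= 2")
    if (mu_ki <= 0) stop("configuration error: mu_ki must be > 0")
    if (sigma_between < 0 || sigma_measure < 0 || sigma_drift < 0)
      stop("configuration error: all sigmas must be >= 0")
    if (gamma < 0 || gamma > 1) stop("configuration error: gamma must lie in [0, 1]")
    if (setpoint <= 0) stop("configuration error: setpoint must be > 0")
    if (ki_floor <= 0) stop("configuration error: ki_floor must be > 0")
  })
  invisible(cfg)
}

#' Generate a two-arm, two-scan cohort
#'
#' Latent model, per subject:
#' \itemize{
#'   \item true baseline `ki_true_scan1 ~ Normal(mu_ki, sigma_between)`,
#'     floored at `ki_floor`;
#'   \item test-retest arm: `ki_true_scan2 = ki_true_scan1 +
#'     Normal(0, sigma_drift)`;
#'   \item challenge arm: `ki_true_scan2 = ki_true_scan1 +
#'     gamma * (setpoint - ki_true_scan1) + Normal(0, sigma_drift)` --
#'     baseline-dependent regulation toward the set-point;
#'   \item observed `ki_scanX = ki_true_scanX + Normal(0, sigma_measure)`,
#'     floored at `ki_floor`.
#' }
#' Measurement noise alone produces a negative baseline-versus-change
#' correlation in *both* arms (regression to the mean); `gamma > 0` adds a
#' true regulation signal only in the challenge arm.
#'
#' @param config a [cohort_config()].
#' @param arms which arms to generate.
#' @param dose_label free-text dose annotation for the challenge arm.
#' @return A data frame of subject records: `subject_id`, `arm`,
#'   `dose_label`, `ki_scan1`, `ki_scan2`, `ki_true_scan1`, `interval_days`.
#' @export
generate_cohort <- function(config, arms = c("test_retest", "challenge"),
                            dose_label = "0.005 mg/kg") {
  if (!inherits(config, "cohort_config")) stop("configuration error: need a cohort_config")
  validate_cohort_config(config)
  arms <- match.arg(arms, several.ok = TRUE)
  with_local_seed(config$seed, {
    recs <- lapply(arms, function(arm) {
      n <- config$n_per_arm
      true1 <- pmax(stats::rnorm(n, config$mu_ki, config$sigma_between),
                    config$ki_floor)
      drift <- stats::rnorm(n, 0, config$sigma_drift)
      reg <- if (arm == "challenge") config$gamma * (config$setpoint - true1) else 0
      true2 <- true1 + reg + drift
      obs1 <- pmax(true1 + stats::rnorm(n, 0, config$sigma_measure), config$ki_floor)
      obs2 <- pmax(true2 + stats::rnorm(n, 0, config$sigma_measure), config$ki_floor)
      data.frame(
        subject_id = sprintf("%s_%02d", substr(arm, 1, 2), seq_len(n)),
        arm = arm,
        dose_label = if (arm == "challenge") dose_label else "none",
        ki_scan1 = obs1, ki_scan2 = obs2, ki_true_scan1 = true1,
        interval_days = config$interval_days,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, recs)
  })
}
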