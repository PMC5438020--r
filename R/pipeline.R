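#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run: acquisition schedule,
#' kinetics of the simulated exemplar regions, the two cohort generator
#' configurations, the Patlak window, and the analysis settings. Can be
#' loaded from YAML (JSON is valid YAML) via `path`.
#'
#' @param schedule preset name (`"study1_26f"`, `"study2_32f"`) or a
#'   `frame_schedule`.
#' @param striatum,reference [region_kinetics()] for the exemplar curves.
#' @param plasma [plasma_params()].
#' @param test_retest,challenge [cohort_config()] for the two arms; the
#'   challenge config's `gamma` carries the simulated drug effect.
#' @param t_star Patlak window start (min).
#' @param noise_scale frame noise for the exemplar curves.
#' @param icc_variant `"agreement"` or `"consistency"`.
#' @param alpha two-tailed significance level in (0, 1).
#' @param exclude subject_ids excluded from the battery.
#' @param seed non-negative integer master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(schedule = "study2_32f",
                       striatum = region_kinetics(0.04, 0.08, 0.02),
                       reference = region_kinetics(0.04, 0.08, 0),
                       plasma = plasma_params(),
                       test_retest = cohort_config(n_per_arm = 8, seed = NULL),
                       challenge = cohort_config(n_per_arm = 12, gamma = 0.6,
                                                 sigma_drift = 0.0005, seed = NULL),
                       t_star = 24, noise_scale = 0.3,
                       icc_variant = "agreement", alpha = 0.05,
                       exclude = character(0), seed = 1) {
  if (!is.numeric(seed) || seed < 0 || seed != round(seed))
    stop("configuration error: seed must be a non-negative integer")
  if (alpha <= 0 || alpha >= 1) stop("configuration error: alpha must be in (0, 1)")
  sched <- if (is.character(schedule)) schedule_preset(schedule) else validate_schedule(schedule)
  validate_cohort_config(test_retest); validate_cohort_config(challenge)
  structure(list(schedule = sched, schedule_name = if (is.character(schedule)) schedule else "inline",
                 striatum = striatum, reference = reference, plasma = plasma,
                 test_retest = test_retest, challenge = challenge,
                 t_star = t_star, noise_scale = noise_scale,
                 icc_variant = icc_variant, alpha = alpha,
                 exclude = exclude, seed = as.integer(seed)),
            class = "run_config")
}

# djb2 string hash of the serialized config, for provenance stamping
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full simulate-fit-analyze pipeline
#'
#' 1. Simulates exemplar striatal and reference time-activity curves on
#'    the configured schedule and fits the reference-tissue Patlak slope.
#' 2. Generates the test-retest and challenge cohorts.
#' 3. Computes per-arm descriptives, percent change, the paired t-test,
#'    reliability (ICC + TRV) of the test-retest arm, and normality of the
#'    challenge-arm percent changes.
#' 4. Runs the regression-to-the-mean battery.
#' 5. Tabulates the analytic k3-to-Ki propagation on the default grid.
#'
#' Fully deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @return An `analysis_report` list with elements `provenance`, `patlak`,
#'   `cohorts`, `descriptives`, `reliability`, `normality`, `rtm`,
#'   `sensitivity`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  exemplar <- with_local_seed(seed, {
    tgt <- simulate_region(config$striatum, config$plasma, config$schedule,
                           noise_scale = config$noise_scale,
                           region_label = "striatum")
    ref <- simulate_region(config$reference, config$plasma, config$schedule,
                           noise_scale = config$noise_scale,
                           region_label = "cerebellum")
    list(target = tgt, reference = ref)
  })
  fit <- patlak_reference(exemplar$target, exemplar$reference,
                          t_star = config$t_star)

  tr_cfg <- config$test_retest; tr_cfg$seed <- seed + 1L
  ch_cfg <- config$challenge;   ch_cfg$seed <- seed + 2L
  tr <- generate_cohort(tr_cfg, arms = "test_retest")
  ch <- generate_cohort(ch_cfg, arms = "challenge")

  pc_tr <- percent_change(tr$ki_scan1, tr$ki_scan2)
  pc_ch <- percent_change(ch$ki_scan1, ch$ki_scan2)
  desc <- function(d, pc) list(
    n = nrow(d),
    mean_scan1 = mean(d$ki_scan1), sd_scan1 = stats::sd(d$ki_scan1),
    mean_scan2 = mean(d$ki_scan2), sd_scan2 = stats::sd(d$ki_scan2),
    mean_percent_change = mean(pc), sd_percent_change = stats::sd(pc)
  )
  rel <- reliability(tr$ki_scan1, tr$ki_scan2, icc_variant = config$icc_variant)
  pt <- paired_t(ch$ki_scan1, ch$ki_scan2)
  norm_ch <- ks_normality(pc_ch)
  rtm <- rtm_battery(tr, ch, exclude = config$exclude)
  sens <- do.call(rbind, lapply(c(0.01, 0.02, 0.04), function(k3)
    propagate_k3_change(0.04, 0.08, k3, frac = 30)))

  structure(list(
    provenance = list(seed = seed, config_hash = config_hash(config),
                      package_version = as.character(utils::packageVersion("kicer")),
                      schedule = config$schedule_name, alpha = config$alpha,
                      icc_variant = config$icc_variant),
    patlak = fit,
    cohorts = list(test_retest = tr, challenge = ch),
    descriptives = list(test_retest = desc(tr, pc_tr), challenge = desc(ch, pc_ch)),
    reliability = rel,
    paired_t_challenge = pt,
    normality_percent_change = norm_ch,
    rtm = rtm,
    sensitivity = sens
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> seed", x$provenance$seed,
      "config", x$provenance$config_hash, "\n")
  print(x$patlak)
  d <- x$descriptives
  cat(sprintf("  test-retest (n=%d): scan1 %.4g (%.2g), scan2 %.4g (%.2g), ICC(%s) = %.3f, TRV = %.2f%%\n",
              d$test_retest$n, d$test_retest$mean_scan1, d$test_retest$sd_scan1,
              d$test_retest$mean_scan2, d$test_retest$sd_scan2,
              x$reliability$icc_variant, x$reliability$icc, x$reliability$trv_percent))
  cat(sprintf("  challenge (n=%d): mean %%change %.2f (%.2f), paired t(%d) = %.2f, p = %.3g\n",
              d$challenge$n, d$challenge$mean_percent_change,
              d$challenge$sd_percent_change, x$paired_t_challenge$df,
              x$paired_t_challenge$t, x$paired_t_challenge$p_two_tailed))
  print(x$rtm)
  invisible(x)
}
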