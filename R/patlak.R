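#' Running integral of a time-activity curve at frame mid-times
#'
#' The x-axis ingredient of the graphical analysis: the integral from 0 to
#' each frame mid-time of the step-function reconstruction of the curve
#' (frame mean held constant over the frame). The step-function rule is
#' exact for constant inputs; for smooth curves it agrees with fine-grid
#' quadrature of the underlying model to well under a percent on realistic
#' schedules.
#'
#' @param tac a [new_tac()] object.
#' @return Numeric vector, kBq ml^-1 min, one value per frame;
#'   non-decreasing for non-negative activity.
#' @export
cumulative_integral <- function(tac) {
  stopifnot(inherits(tac, "tac"))
  dur_min <- tac$schedule$duration_s / 60
  # integral to mid-frame j: all full frames before j plus half of frame j
  cumsum(tac$activity * dur_min) - tac$activity * dur_min / 2
}

#' Reference-tissue Patlak (graphical) fit of the influx constant
#'
#' For an irreversibly trapped tracer the normalized uptake
#' `target(t) / reference(t)` becomes linear, at late times, in the
#' normalized integrated reference input
#' `int_0^t reference / reference(t)`; the slope of that line is the
#' influx constant Ki_cer (min^-1). Points are taken at frame mid-times
#' with mid-time >= `t_star`; the line is fit by ordinary least squares
#' (optionally weighted by frame duration).
#'
#' @param target striatal [new_tac()].
#' @param reference reference-region (cerebellar) [new_tac()] on the same
#'   schedule.
#' @param t_star start of the linear window, minutes. Default 24.
#' @param weighted if `TRUE`, weight each point by its frame duration.
#' @return A `patlak_fit`: list with `ki_cer` (slope, min^-1), `intercept`,
#'   `t_star`, `n_points`, `r_squared`, `residuals`, and the fit points
#'   (`x`, `y`, `mid_min`).
#' @export
patlak_reference <- function(target, reference, t_star = 24, weighted = FALSE) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (nrow(target$schedule) != nrow(reference$schedule) ||
      any(abs(target$schedule$start_s - reference$schedule$start_s) > 1e-9) ||
      any(abs(target$schedule$duration_s - reference$schedule$duration_s) > 1e-9))
    stop("schedule error: target and reference must share a frame schedule")
  mid <- frame_mid_min(target$schedule)
  if (t_star < 0 || t_star > max(frame_end_min(target$schedule)))
    stop("t_star must lie within the scan duration")
  use <- mid >= t_star
  if (sum(use) < 3L)
    stop("insufficient data: need >= 3 frames with mid-time >= t_star, have ",
         sum(use))
  if (any(reference$activity[use] <= 0))
    stop("degenerate reference: non-positive reference activity after t_star")

  xint <- cumulative_integral(reference)
  x <- xint[use] / reference$activity[use]
  y <- target$activity[use] / reference$activity[use]
  w <- if (weighted) target$schedule$duration_s[use] / 60 else rep(1, sum(use))

  fit <- stats::lm(y ~ x, weights = w)
  res <- stats::residuals(fit)
  sst <- sum(w * (y - stats::weighted.mean(y, w))^2)
  ssr <- sum(w * res^2)
  r2 <- if (sst < 1e-300) {
    # constant y: a flat line fits exactly; report 1 rather than 0/0
    1
  } else max(0, min(1, 1 - ssr / sst))

  structure(list(
    ki_cer = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    t_star = t_star, n_points = sum(use), r_squared = r2,
    residuals = unname(res), x = unname(x), y = unname(y),
    mid_min = mid[use], weighted = weighted
  ), class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf(
    "<patlak_fit> Ki_cer = %.5g min^-1, intercept = %.4g (t* = %g min, %d points, R^2 = %.4f)\n",
    x$ki_cer, x$intercept, x$t_star, x$n_points, x$r_squared))
  invisible(x)
}

#' Standardized uptake value at a time point
#'
#' SUV = tissue activity (kBq/ml) divided by injected activity per body
#' weight (kBq/g, taking 1 g ~ 1 ml). Reads the frame containing `t_min`.
#'
#' @param tac a [new_tac()] object.
#' @param t_min time in minutes, within the scan.
#' @param injected_mbq injected activity, MBq (> 0).
#' @param weight_kg body weight, kg (> 0).
#' @return List with `value` (dimensionless) and `at_time` (min).
#' @export
suv_at <- function(tac, t_min, injected_mbq, weight_kg) {
  stopifnot(inherits(tac, "tac"))
  if (injected_mbq <= 0) stop("injected_mbq must be > 0")
  if (weight_kg <= 0) stop("weight_kg must be > 0")
  start_min <- tac$schedule$start_s / 60
  end_min <- frame_end_min(tac$schedule)
  if (t_min < min(start_min) || t_min > max(end_min) + 1e-9)
    stop("t outside the scan")
  # frame containing t; a frame boundary resolves to the frame ending there
  idx <- which(end_min + 1e-9 >= t_min)[1]
  normalizer <- injected_mbq * 1000 / (weight_kg * 1000)   # kBq per g
  list(value = tac$activity[idx] / normalizer, at_time = t_min)
}
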