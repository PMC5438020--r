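#' Arterial plasma input model
#'
#' A linear-rise tri-exponential (Feng-type) arterial concentration model:
#' after an injection delay `d`, with `tau = t - d`,
#' \deqn{C_p(\tau) = (A_1 \tau - A_2 - A_3) e^{-\lambda_1 \tau}
#'       + A_2 e^{-\lambda_2 \tau} + A_3 e^{-\lambda_3 \tau},}
#' which is 0 at the injection time, rises sharply to a peak and washes out
#' with two slower exponentials. Used only to drive the tissue simulator;
#' the Patlak estimator itself never sees the plasma curve (it uses a
#' reference tissue).
#'
#' Defaults give a bolus peak of about 70 kBq/ml near 0.3 min post
#' injection and a slow tail of a few kBq/ml at 90 min, a plausible shape
#' for a ~150 MBq bolus.
#'
#' @param A1 linear-rise amplitude (kBq ml^-1 min^-1).
#' @param A2,A3 exponential amplitudes (kBq ml^-1).
#' @param l1,l2,l3 decay eigenvalues (min^-1), all > 0.
#' @param delay_min injection delay from scan start (min); activity is 0
#'   before it. Default 0.5 min (injection 30 s after scan start).
#' @return A `plasma_params` list.
#' @export
plasma_params <- function(A1 = 600, A2 = 15, A3 = 10,
                          l1 = 4.0, l2 = 0.12, l3 = 0.01,
                          delay_min = 0.5) {
  stopifnot(l1 > 0, l2 > 0, l3 > 0, A1 > 0, A2 >= 0, A3 >= 0, delay_min >= 0)
  structure(list(A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3,
                 delay_min = delay_min),
            class = "plasma_params")
}

#' Evaluate the plasma input
#'
#' @param params a [plasma_params()] object.
#' @param t_min times in minutes, all >= 0.
#' @return Plasma concentration (kBq/ml) at each time; 0 before the
#'   injection delay.
#' @export
plasma_input <- function(params, t_min) {
  stopifnot(inherits(params, "plasma_params"))
  if (any(t_min < 0)) stop("t must be >= 0")
  tau <- t_min - params$delay_min
  out <- numeric(length(t_min))
  pos <- tau > 0
  tp <- tau[pos]
  out[pos] <- with(params,
    (A1 * tp - A2 - A3) * exp(-l1 * tp) + A2 * exp(-l2 * tp) + A3 * exp(-l3 * tp))
  pmax(out, 0)
}
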