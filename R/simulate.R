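#' Compartmental rate constants for one region
#'
#' The irreversible two-tissue model: tracer enters a free/exchangeable
#' compartment at rate `K1` (delivery), leaves it at `k2` (washout) and is
#' irreversibly trapped at `k3` (decarboxylation/trapping). `k3 = 0` gives
#' the one-tissue model used for the reference region (cerebellum).
#'
#' @param K1 delivery, ml min^-1 ml^-1 (> 0).
#' @param k2 washout, min^-1 (>= 0; `k2 = 0` is the fully trapped limit
#'   used in sensitivity analyses and requires `k3 > 0`).
#' @param k3 trapping, min^-1 (>= 0).
#' @return A `region_kinetics` list.
#' @export
region_kinetics <- function(K1, k2, k3 = 0) {
  if (!is.numeric(K1) || K1 <= 0) stop("K1 must be > 0")
  if (!is.numeric(k2) || k2 < 0) stop("k2 must be >= 0")
  if (!is.numeric(k3) || k3 < 0) stop("k3 must be >= 0")
  if (k2 + k3 <= 0) stop("k2 + k3 must be > 0")
  structure(list(K1 = K1, k2 = k2, k3 = k3), class = "region_kinetics")
}

#' A time-activity curve
#'
#' @param schedule a `frame_schedule`.
#' @param activity per-frame mean activity concentration (kBq/ml), one
#'   value per frame.
#' @param region_label free-text region name.
#' @return A `tac` object.
#' @export
new_tac <- function(schedule, activity, region_label = "region") {
  schedule <- validate_schedule(schedule)
  if (length(activity) != nrow(schedule))
    stop("activity length (", length(activity),
         ") must equal frame count (", nrow(schedule), ")")
  structure(list(schedule = schedule, activity = as.numeric(activity),
                 region_label = as.character(region_label)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> '%s': %d frames over %.6g min, peak %.3g kBq/ml\n",
              x$region_label, nrow(x$schedule),
              sum(x$schedule$duration_s) / 60, max(x$activity)))
  invisible(x)
}

# Convolution of one plasma basis term with exp(-beta t), closed form.
# Terms: A * exp(-l t) and A * t * exp(-l t). Near-degenerate beta ~ l
# switches to the analytic limit to avoid catastrophic cancellation.
.conv_exp <- function(A, l, beta, tau) {
  if (abs(beta - l) < 1e-7) return(A * tau * exp(-beta * tau))
  A * (exp(-l * tau) - exp(-beta * tau)) / (beta - l)
}

.conv_texp <- function(A, l, beta, tau) {
  if (abs(beta - l) < 1e-7) return(A * tau^2 / 2 * exp(-beta * tau))
  d <- beta - l
  A * (tau * exp(-l * tau) / d - (exp(-l * tau) - exp(-beta * tau)) / d^2)
}

# Running integrals of the two convolution terms from 0 to tau.
.iconv_exp <- function(A, l, beta, tau) {
  if (abs(beta - l) < 1e-7)
    return(A * (1 - (1 + beta * tau) * exp(-beta * tau)) / beta^2)
  A * ((1 - exp(-l * tau)) / l - (1 - exp(-beta * tau)) / beta) / (beta - l)
}

.iconv_texp <- function(A, l, beta, tau) {
  if (abs(beta - l) < 1e-7) {
    bt <- beta * tau
    return(A * (2 - (bt^2 + 2 * bt + 2) * exp(-bt)) / (2 * beta^3))
  }
  d <- beta - l
  A * ((1 - (1 + l * tau) * exp(-l * tau)) / (l^2 * d) -
         ((1 - exp(-l * tau)) / l - (1 - exp(-beta * tau)) / beta) / d^2)
}

#' Instantaneous tissue concentration of the two-tissue model
#'
#' Closed-form solution of the irreversible two-tissue compartment model
#' driven by the linear-rise tri-exponential plasma input: the free
#' compartment is the plasma curve convolved with `K1 exp(-(k2+k3) t)`,
#' the trapped compartment is `k3` times the running integral of the free
#' compartment.
#'
#' @param kin a [region_kinetics()] object.
#' @param input a [plasma_params()] object.
#' @param t_min times (minutes), >= 0.
#' @param compartment which curve to return.
#' @return Concentration (kBq/ml) at each time.
#' @export
tissue_curve <- function(kin, input, t_min,
                         compartment = c("total", "free", "trapped")) {
  stopifnot(inherits(kin, "region_kinetics"), inherits(input, "plasma_params"))
  compartment <- match.arg(compartment)
  if (any(t_min < 0)) stop("t must be >= 0")
  beta <- kin$k2 + kin$k3
  tau <- pmax(t_min - input$delay_min, 0)

  terms <- list(
    list(fun = .conv_texp, ifun = .iconv_texp, A = input$A1, l = input$l1),
    list(fun = .conv_exp,  ifun = .iconv_exp,  A = -(input$A2 + input$A3), l = input$l1),
    list(fun = .conv_exp,  ifun = .iconv_exp,  A = input$A2, l = input$l2),
    list(fun = .conv_exp,  ifun = .iconv_exp,  A = input$A3, l = input$l3)
  )

  free <- kin$K1 * Reduce(`+`, lapply(terms, function(tm) tm$fun(tm$A, tm$l, beta, tau)))
  if (compartment == "free") return(free)
  if (kin$k3 == 0) {
    trapped <- numeric(length(tau))
  } else {
    trapped <- kin$k3 * kin$K1 *
      Reduce(`+`, lapply(terms, function(tm) tm$ifun(tm$A, tm$l, beta, tau)))
  }
  if (compartment == "trapped") return(trapped)
  free + trapped
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a region time-activity curve
#'
#' Each frame value is the time-average of the instantaneous model curve
#' over the frame (computed by fine sub-frame trapezoidal quadrature of the
#' closed-form solution), plus optional zero-mean Gaussian noise with
#' standard deviation `noise_scale * sqrt(max(C, eps) / duration_min)` --
#' the standard variance-proportional-to-rate, inverse-duration weighting
#' assumption for dynamic PET frames.
#'
#' @param kin a [region_kinetics()] object.
#' @param input a [plasma_params()] object.
#' @param schedule a `frame_schedule`.
#' @param noise_scale noise magnitude (kBq ml^-1 min^(1/2)); 0 disables
#'   noise. Default 0.3.
#' @param seed optional integer; when given, the RNG state is saved,
#'   seeded, and restored, so identical seeds give identical curves without
#'   disturbing the caller's RNG stream.
#' @param region_label region name carried on the output.
#' @param eps_kbq floor inside the noise variance (kBq/ml).
#' @return A [new_tac()] object.
#' @export
simulate_region <- function(kin, input, schedule, noise_scale = 0.3,
                            seed = NULL, region_label = "region",
                            eps_kbq = 0.01) {
  schedule <- validate_schedule(schedule)
  if (!is.numeric(noise_scale) || noise_scale < 0)
    stop("noise_scale must be >= 0")
  start_min <- schedule$start_s / 60
  dur_min <- schedule$duration_s / 60
  means <- vapply(seq_len(nrow(schedule)), function(i) {
    n_sub <- max(9L, ceiling(schedule$duration_s[i]))   # step <= 1 s
    tt <- seq(start_min[i], start_min[i] + dur_min[i], length.out = n_sub + 1L)
    ct <- tissue_curve(kin, input, tt)
    # trapezoid average over the frame
    sum((ct[-1] + ct[-length(ct)]) / 2 * diff(tt)) / dur_min[i]
  }, numeric(1))
  if (noise_scale > 0) {
    sds <- noise_scale * sqrt(pmax(means, eps_kbq) / dur_min)
    means <- means + with_local_seed(seed, stats::rnorm(length(means), 0, sds))
  }
  new_tac(schedule, means, region_label)
}
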