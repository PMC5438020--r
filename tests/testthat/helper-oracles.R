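# Independent numerical oracles used across the suite. These deliberately
# avoid the package's closed-form curve evaluation and frame-based Patlak
# path: tissue curves come from a stiff ODE solver, integrals from
# trapezoidal quadrature on a fine grid, and fits from lm() on that grid.

# Irreversible two-tissue curve by numeric ODE integration.
oracle_tissue_ode <- function(kin, plasma, t_min) {
  rhs <- function(t, y, parms) {
    cp <- kicer::plasma_input(plasma, t)
    list(c(parms[["K1"]] * cp - (parms[["k2"]] + parms[["k3"]]) * y[1],
           parms[["k3"]] * y[1]))
  }
  times <- sort(unique(c(0, t_min)))
  sol <- deSolve::ode(c(Fc = 0, Tc = 0), times, rhs,
                      c(K1 = kin$K1, k2 = kin$k2, k3 = kin$k3),
                      rtol = 1e-10, atol = 1e-12)
  tot <- sol[, "Fc"] + sol[, "Tc"]
  tot[match(t_min, sol[, "time"])]
}

# Asymptotic reference-Patlak slope on a fine 1 s grid over an extended
# (default 180 min) noiseless run of the same generative model.
oracle_patlak_finegrid <- function(target_kin, reference_kin, plasma,
                                   t_star = 24, t_end = 180, step_min = 1 / 60,
                                   use_ode = FALSE) {
  tg <- seq(0, t_end, by = step_min)
  if (use_ode) {
    ct <- oracle_tissue_ode(target_kin, plasma, tg)
    cr <- oracle_tissue_ode(reference_kin, plasma, tg)
  } else {
    ct <- kicer::tissue_curve(target_kin, plasma, tg)
    cr <- kicer::tissue_curve(reference_kin, plasma, tg)
  }
  xint <- as.numeric(pracma::cumtrapz(tg, cr))
  use <- tg >= t_star & cr > 0
  fit <- stats::lm(I(ct[use] / cr[use]) ~ I(xint[use] / cr[use]))
  unname(stats::coef(fit))   # (intercept, slope)
}

# Independent re-implementation of the k3-perturbation experiment: ODE
# curves on a fine grid, trapezoid integral, lm slope, percent change.
oracle_bias_finegrid <- function(K1, k2, k3, frac, plasma,
                                 reference_kin, t_star = 24, t_end = 95) {
  base <- oracle_patlak_finegrid(kicer::region_kinetics(K1, k2, k3),
                                 reference_kin, plasma,
                                 t_star = t_star, t_end = t_end,
                                 step_min = 1 / 60, use_ode = TRUE)[2]
  pert <- oracle_patlak_finegrid(kicer::region_kinetics(K1, k2, k3 * (1 + frac / 100)),
                                 reference_kin, plasma,
                                 t_star = t_star, t_end = t_end,
                                 step_min = 1 / 60, use_ode = TRUE)[2]
  100 * (pert / base - 1)
}

default_plasma <- kicer::plasma_params()
default_striatum <- kicer::region_kinetics(0.04, 0.08, 0.02)
default_reference <- kicer::region_kinetics(0.04, 0.08, 0)
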