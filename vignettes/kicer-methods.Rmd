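---
title: "Simulating and testing dopamine synthesis capacity measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and testing dopamine synthesis capacity measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dopamine synthesis capacity (DSC) in the striatum is indexed in vivo by the
influx constant Ki_cer of an FDOPA PET scan: the rate at which tracer is
irreversibly trapped in striatal terminals, estimated relative to a
cerebellar reference region. A pharmacological challenge design measures
Ki_cer twice per subject — at baseline and under a dopamine partial agonist
— and asks whether the drug-induced change depends on the baseline value,
as expected if the drug stabilises dopaminergic tone (agonism under low
tone, functional antagonism under high tone).

The statistical hazard in that question is regression to the mean (RTM):
with any measurement noise, subjects observed high at baseline tend to be
observed lower on re-scan, producing a spurious negative
baseline-versus-change correlation even without any drug. This package
exists to make that whole chain testable: it simulates the raw data
(time–activity curves and cohorts) from explicit generative models with
separately controllable measurement noise and true regulation, estimates
Ki_cer the way the field does, runs the full inferential battery, and
measures the battery's false-positive rate and power against its own
generator.

## Generative models

### Time–activity curves

Tissue curves come from the irreversible two-tissue compartment model:
free-compartment kinetics $\dot C_f = K_1 C_p - (k_2 + k_3) C_f$ and
trapped compartment $\dot C_t = k_3 C_f$, with defaults
$K_1 = 0.04\ \mathrm{ml\,min^{-1}\,ml^{-1}}$, $k_2 = 0.08\ \mathrm{min^{-1}}$,
$k_3 = 0.02\ \mathrm{min^{-1}}$ for striatum and $k_3 = 0$ (one-tissue
model) for the cerebellar reference. The driving arterial input is a
linear-rise tri-exponential (Feng-type) curve. No real arterial data stand
behind it — the estimation method never sees plasma, so the input only has
to be shaped plausibly: the defaults give a sharp bolus peaking ≈ 0.3 min
after a 0.5 min injection delay and a slow tail, with concentration
identically zero at and before injection. Solutions are evaluated in
closed form (exponential convolution integrals, with series limits when
$k_2+k_3$ collides with a plasma eigenvalue); the test suite checks them
against an independent stiff ODE solution.

Frame values are time-averages of the instantaneous curve over each frame
(sub-frame trapezoidal quadrature at ≤ 1 s steps). Two acquisition
protocols ship as presets: a 26-frame, 94.5 min schedule and a 32-frame,
95 min schedule, both used verbatim by the simulator. Optional frame noise
is zero-mean Gaussian with standard deviation
$\sigma_j = s\sqrt{\max(C_j, \epsilon)/\Delta_j}$ — the standard
count-rate/duration weighting assumption for dynamic PET; the default
scale $s = 0.3\ \mathrm{kBq\,ml^{-1}\,min^{1/2}}$ yields a ≈ 5–7%
coefficient of variation on the fitted slope, in the range of the
test–retest variability the cohort model is calibrated to. All activities
are decay-corrected by assumption; no decay term is simulated.

### Cohorts

Per subject, true baseline $K^{(1)} \sim N(\mu, \sigma_b^2)$ with
$\mu = 0.014\ \mathrm{min^{-1}}$, $\sigma_b = 0.0015\ \mathrm{min^{-1}}$,
floored at $10^{-4}$ to stay positive. The second scan's truth is

* test–retest arm: $K^{(2)} = K^{(1)} + N(0, \sigma_d^2)$ (pure drift);
* challenge arm: $K^{(2)} = K^{(1)} + \gamma(\theta - K^{(1)}) + N(0, \sigma_d^2)$,

a set-point regulation model: the drug moves each subject the fraction
$\gamma \in [0,1]$ of the way toward the set-point $\theta$ (default
$\mu$). Observations add i.i.d. measurement noise $N(0, \sigma_m^2)$ to
each scan. The default $\sigma_m = \sigma_b\sqrt{1/\rho - 1} \approx
0.00067\ \mathrm{min^{-1}}$ is calibrated so the two-scan intraclass
correlation of a noise-only cohort is $\rho = 0.834$; the suite verifies
the identity at large n. This is the minimal model in which true
regulation ($\gamma$) and RTM ($\sigma_m$) are separate dials, which is
exactly what the battery needs to be calibrated against. It does not
emulate dose–response, tolerability dropout, scanner differences between
arms, or non-Gaussian between-subject heterogeneity — passing tests say
nothing about those.

## Estimation: reference-tissue Patlak

With an irreversibly trapped tracer, plotting
$C_T(t)/C_R(t)$ against $\int_0^t C_R / C_R(t)$ becomes linear once the
free compartments equilibrate; the slope is Ki_cer. Choices made here:

* **Fit window.** $t^*$ is not derivable from the protocol descriptions;
  the default is 24 min, recorded in every fit object and configurable.
  On the 32-frame preset this leaves 14 points, and noiseless curves give
  $R^2 > 0.999$.
* **Points and weights.** Points sit at frame mid-times; ordinary least
  squares by default, optional frame-duration weighting.
* **The x-axis integral** uses the step-function (frame-mean)
  reconstruction, which is exact for constant curves and within 1% of
  fine quadrature on realistic ones; this makes the proportional-curves
  degeneracy (slope 0, intercept equal to the ratio) hold to machine
  precision.
* **Truth for oracles.** "True" Ki_cer is defined operationally as the
  slope of the same generative model on a 1 s grid extended to 180 min —
  the reference-tissue slope is *not* $K_1 k_3/(k_2+k_3)$ in general, so
  comparing against the analytic hyperbola would conflate estimator bias
  with model algebra. The frame-based estimate lands within 1% of that
  fine-grid slope on the default kinetics.
* Degenerate inputs error informatively: mismatched schedules, fewer than
  3 usable frames, non-positive reference activity in the window. A
  constant ratio (target proportional to reference) has zero total sum of
  squares; its $R^2$ is reported as 1 (a flat line fits exactly).

The reference-region SUV check (`suv_at`) reads the frame containing the
requested time and normalises by injected activity per body weight.

## The inferential battery

`percent_change` follows the convention (baseline − post)/baseline × 100.
A consequence worth stating loudly: under this convention a stabilising
drug (or RTM) produces a *positive* correlation between baseline and
percent change. The battery's correlation analyses therefore use the gain
convention 100·(scan2 − scan1)/scan1 — the exact negation — so that
regulation and RTM show as the negative correlation the field plots; every
correlation result carries a `change_convention` label.

The battery (`rtm_battery`) bundles:

1. **Levene's test** on the change scores of the two arms (classical
   mean-centred by default, Brown–Forsythe median-centring as an option);
2. **the group × change repeated-measures ANOVA interaction**, computed
   through the exact algebraic identity F = t² of the pooled two-sample t
   on change scores (df 1, N−2; sphericity is trivial with two levels) —
   the general sums-of-squares route via `aov` serves as a test oracle;
3. **the interaction regression** ki_scan2 ~ baseline × arm, whose
   population interaction coefficient is exactly −γ under the generator —
   noise-free cohorts recover it to 10⁻⁸, and across noisy cohorts the
   95% CI covers −γ at its nominal rate *when the noise is in scan 2*.
   With baseline measurement noise the coefficient attenuates toward
   −λγ (errors-in-variables, λ the reliability ratio) — that is a property
   of the regression the study design uses, not of this implementation,
   and is why the parameter-recovery checks put noise in the drift term;
4. **per-arm baseline-versus-change correlations** and their comparison
   via Fisher's r-to-z. The independent-samples form
   $z = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$ is the default because
   the two arms share no subjects; a Steiger-type dependent-correlations
   form (which needs the inter-correlation and a single sample) is
   available for completeness. On the two study-level correlations
   (−0.57 at n = 8 versus −0.90 at n = 11) the independent test gives
   |z| ≈ 1.45, p ≈ 0.15 — a reported P < 0.01 for this comparison is not
   reproducible from any variant we can reconstruct, and the package
   deliberately reports the computation rather than the target.

`ks_normality` is the Lilliefors form of the Kolmogorov–Smirnov test
(Normal with estimated mean/SD) with a Monte-Carlo p-value; the RNG state
is saved and restored around a fixed internal stream so the p-value is a
deterministic function of the data.

Outliers are never removed automatically: exclusions are caller-specified
subject ids, recorded in every report.

## Calibration of the battery

`calibration_sim` simulates study pairs at the emulated design sizes
(8 test–retest + 12 challenge) across a γ grid and records rejection rates
at α = 0.05 (two-tailed throughout). Two findings, both computed by
`analysis/04_rtm.R` and the acceptance checks rather than asserted:

* With γ = 0 (noise only), both the ANOVA interaction and the correlation
  comparison reject at close to the nominal 5% — the battery is not fooled
  by pure RTM at these sample sizes.
* Under the symmetric set-point model (θ = μ), regulation moves individual
  subjects but leaves the challenge-arm *mean* unchanged, so the ANOVA
  interaction has essentially no power in γ; the power against regulation
  lives in the correlation comparison, whose rejection rate climbs
  steadily with γ. A real study whose interaction F is large is therefore
  seeing a mean shift (θ off-centre from the cohort mean, or an additive
  drug effect), not set-point regulation alone — a useful diagnostic the
  simulation makes explicit.

## k3 → Ki sensitivity

The influx constant of the two-tissue model is the rectangular hyperbola
$K_i = K_1 k_3/(k_2+k_3)$. A fractional change f in k3 maps to

$$\%\Delta K_i = 100\left[\frac{(1+f)(k_2+k_3)}{k_2+(1+f)k_3} - 1\right],$$

which is 0 at $k_2 = 0$ (saturated), approaches f from below as
$k_2/k_3 \to \infty$, and lies strictly inside (0, f) for every
$k_2 > 0$: the hyperbola *compresses* trapping-rate changes, and no
parameter choice can amplify a +30% k3 change beyond +30%. Claims that a
+30% k3 change appears as +33% or +40% in Ki are therefore outside what
this formula permits; the package documents the bound and additionally
propagates the change empirically through simulation + Patlak
re-estimation (`patlak_bias_sim`). The empirical route tracks the analytic
values within ≈ 0.2 percentage points at moderate-to-fast washout and
under-propagates by a few points at the slowest washout grid point, where
the 24–95 min window is not yet asymptotic — estimator bias the analytic
formula cannot show, and the reason both modes are reported side by side.

## Problem sizes and determinism

The test suite and acceptance checks use: Monte-Carlo cohort oracles at
10⁵–10⁶ subjects (cheap vectorised draws), 200-replicate noise studies for
the estimator, 2000 simulated study pairs per γ for calibration, and 100
random datasets for the exact F = t² identity — sizes chosen so the full
suite runs in well under a minute while leaving Monte-Carlo error an order
of magnitude below every tolerance it is compared against. Every stochastic
path takes an explicit seed, restores the caller's RNG state, and
reproduces bit-identically under the same seed.

## Known limitations

* Region curves are simulated directly; there is no image, attenuation,
  scatter, motion, or ROI-delineation model, so scanner-level artefacts
  are out of reach.
* The regulation model is linear in the baseline deviation; saturating or
  threshold autoregulation would need a different generator.
* The plasma model and reference-region kinetics are plausible defaults,
  not fitted to any measured input function.
* The dependent-correlations (Steiger) variant is provided for
  completeness but the two-arm design it would apply to does not arise
  here; it is exercised only by unit tests.
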