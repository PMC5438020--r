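# kicer

Simulation and inference for FDOPA PET pharmacological-challenge designs:
estimate striatal dopamine synthesis capacity (the influx constant
**Ki_cer**, min⁻¹) by reference-tissue Patlak graphical analysis, and test
whether a baseline-dependent drug effect on Ki_cer is real regulation or
regression to the mean.

## What it does

A challenge study scans each subject twice (baseline, then under a dopamine
partial agonist) and correlates baseline Ki_cer with its change. Because
Ki_cer is measured with noise, a negative baseline-versus-change
correlation arises even with no drug at all (regression to the mean). This
package makes the whole analysis chain testable end to end:

* **`tacsim`-level simulation** — dynamic time–activity curves from the
  irreversible two-tissue compartment model (free compartment with
  delivery K1 and washout k2 + k3; trapped compartment fed at k3) driven
  by a tri-exponential arterial input, sampled on two realistic frame
  schedules (26 frames / 94.5 min and 32 frames / 95 min), with
  variance ∝ activity/duration frame noise; and two-scan cohorts from a
  latent set-point model in which measurement noise (σ_m) and true
  regulation strength (γ) are separate dials. The default σ_m is
  calibrated so the test–retest intraclass correlation is 0.834.
* **Estimation** — reference-tissue Patlak: the slope of
  C_T(t)/C_R(t) against ∫₀ᵗC_R/C_R(t) over frames past t* (default
  24 min) is Ki_cer; plus a reference-region SUV check.
* **Inference** — percent change, Pearson/Spearman correlations, paired
  and summary-statistics t-tests, ICC (agreement and consistency
  variants) with test–retest variability, Lilliefors normality, and the
  regression-to-the-mean battery: Levene's test on change scores, the
  group × change repeated-measures ANOVA interaction (exactly the squared
  pooled t on change scores), the `ki_scan2 ~ baseline × arm` interaction
  regression (whose interaction coefficient is −γ under the generator),
  and Fisher r-to-z comparison of the two arms' correlations.
* **Calibration** — Monte-Carlo type-I error and power of the battery
  against the generator at the emulated design sizes (8 + 12 subjects).
* **Sensitivity** — propagation of fractional k3 changes to
  Ki = K1·k3/(k2+k3), analytically (a +30% k3 change always maps strictly
  inside (0%, 30%) when k2 > 0) and empirically through Patlak
  re-estimation.

## Worked example

```r
library(kicer)

sched <- schedule_preset("study2_32f")        # 8x15s, 3x60s, 5x120s, 16x300s
plasma <- plasma_params()
striatum <- region_kinetics(K1 = 0.04, k2 = 0.08, k3 = 0.02)
cerebellum <- region_kinetics(K1 = 0.04, k2 = 0.08, k3 = 0)

tgt <- simulate_region(striatum, plasma, sched, noise_scale = 0)
ref <- simulate_region(cerebellum, plasma, sched, noise_scale = 0)
patlak_reference(tgt, ref, t_star = 24)
#> <patlak_fit> Ki_cer = 0.015895 min^-1, intercept = 0.8324 (t* = 24 min, 14 points, R^2 = 0.9999)

tr <- generate_cohort(cohort_config(n_per_arm = 8, sigma_drift = 5e-4, seed = 11),
                      arms = "test_retest")
ch <- generate_cohort(cohort_config(n_per_arm = 12, gamma = 0.6,
                                    sigma_drift = 5e-4, seed = 12),
                      arms = "challenge")
rtm_battery(tr, ch)
#> <rtm_report>
#>   n: 8 test-retest, 12 challenge (excluded: none)
#>   Levene on change scores: W = 6.55, p = 0.0197
#>   group x change ANOVA: F(1,18) = 4.21, p = 0.0551
#>   interaction regression: F = 11.2, adj R^2 = 0.617, baseline x challenge = -0.57
#>   test_retest baseline vs %change: r = -0.555, n = 8, p = 0.153
#>   challenge baseline vs %change: r = -0.812, n = 12, p = 0.00135
#>   correlation comparison: z = 0.908, p = 0.364
```

Reading the battery: the challenge arm shows a strong negative
baseline-versus-change correlation (r = −0.81, p = 0.001), and the fitted
`baseline x challenge` coefficient (−0.57, 95% CI −1.03 to −0.11)
estimates −γ (the generating γ was 0.6). But note the resting arm *also*
shows r = −0.56 from measurement noise alone — regression to the mean at
n = 8 — which is exactly why the single-study correlation is not evidence
by itself and the comparison between arms (here z = 0.91, underpowered at
these sizes) has to carry the inference. The calibration below quantifies
both effects.

The numbered scripts in `analysis/` run the full study workflow and write
tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # TACs on both schedules + 8/12-subject cohort
Rscript analysis/02_patlak.R      # slope recovery vs fine-grid truth; noise CV
Rscript analysis/03_cohort_stats.R # descriptives, ICC/TRV, normality, t-tests
Rscript analysis/04_rtm.R         # the battery + type-I/power calibration
Rscript analysis/05_sensitivity.R # analytic vs Patlak-estimated k3 propagation
```

`analysis/04_rtm.R` prints, for example, rejection rates at
α = 0.05 over γ ∈ {0, 0.3, 0.6, 0.9} (n_sim = 2000 per point): the ANOVA
interaction stays at ~0.04–0.05 everywhere, while the correlation
comparison rises from ~0.07 at γ = 0 to ~0.49 at γ = 0.9.

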