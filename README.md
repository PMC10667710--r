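# exofanova

Functional ANOVA assessment of back-support exoskeletons in manual lifting
tasks.

## The problem

Back-support exoskeletons are usually evaluated by comparing the *peak* of a
biomechanical variable with and without the device. But an exoskeleton that
helps at the peak of a lift may hinder — or do nothing — elsewhere in the
movement. `exofanova` implements a whole-movement assessment: five
biomechanical variables are estimated at every point of the normalized
(0–100 %) lifting cycle and compared between exoskeleton-on and
exoskeleton-off conditions with a pointwise functional analysis of variance
(FANOVA). It is aimed at ergonomics and biomechanics researchers who have
per-trial motion-capture and hand-force recordings (or who want a fully
synthetic test bed).

The five variables:

| symbol | variable | units |
|---|---|---|
| Fc | lumbar compression load at L5/S1 | N |
| θ | trunk flexion angle (∠C7·L5·C, reported as 180° − ∠ so upright ≈ 0°) | deg |
| ω | trunk angular velocity (dθ/dt) | deg/s |
| α | trunk angular acceleration (dω/dt) | deg/s² |
| H | horizontal wrist–lumbar displacement | m |

## The method

1. **Kinematics** — marker trajectories are low-pass filtered (zero-phase
   Butterworth, 4 Hz), θ/ω/α and H are computed on the raw time base, the
   task is segmented into free-flexion, box-lifting and box-laying phases
   (force-event detection or published fixed fractions), and every series is
   resampled onto a 101-point normalized grid.
2. **Exoskeleton torque model** — bench sweeps (0–90° at 10, 30, 45, 60 and
   90 °/s, 10 repeats each) are filtered, averaged, and fitted with a
   thin-plate spline (kernel r² log r), giving assistive torque as a smooth
   function T(θ, ω).
3. **Dynamics** — a nine-segment top-down Newton–Euler chain (forearms,
   upper arms, head, shoulder, thoracic spine, lumbar spine, pelvis; masses
   as Winter-style fractions of body mass, exoskeleton mass at the lumbar
   COM) yields the gross moment at L5/S1. The assistive torque is subtracted
   in the trunk flexion plane. Trunk muscle forces solve

   min Σᵢ (Fᵢ/PCSAᵢ)²  s.t.  Σᵢ (rᵢ × ûᵢ) Fᵢ = M_net,  Fᵢ ≥ 0

   by quadratic programming, and Fc is the muscular plus upper-body force
   along the vertebral axis.
4. **Functional statistics** — per-subject condition-mean curves are
   represented in a B-spline basis by penalized least squares
   (roughness penalty λ∫(D²x)², λ by GCV), aligned by continuous
   registration (monotone warps, MINEIG criterion), and tested with the
   two-group FANOVA model f(t) = μ(t) + α_g(t) + ε(t) under
   α₁(t) + α₂(t) = 0. The pointwise F-ratio

   F(t) = [(SSY(t) − SSE(t)) / df_error] / [SSE(t) / df_regression]

   with df_error = 1 and df_regression = n − 2 is compared with the
   F-criterion qf(0.95; 1, 18) = **4.41** for the canonical 10-subject,
   two-condition (20-curve) design. Maximal runs of F(t) above the criterion
   are the significant intervals; per-phase reports read the effect size at
   the argmax-F time in each phase, and paired t-tests compare peak values.

A synthetic-data module (`cohort_spec`, `generate_trial`, `generate_bench`,
`generate_curveset`) produces phase-structured minimum-jerk lifting trials,
bench sweeps and curve sets with known ground truth, so the whole pipeline
runs and is testable without any recordings.

## Worked example

```r
library(exofanova)

# 1. bench characterization -> thin-plate-spline torque surface
bench   <- generate_bench(seed = 1)                      # 5 speeds x 10 repeats
surface <- fit_tps(average_characterization(bench), regularization = "auto")
goodness_of_fit(surface, average_characterization(bench))
#> TPS torque surface: R2 = 1.000, RMSE = 0.10 N m
evaluate_tps(surface, 45, 30)
#> assistive torque at 45 deg, 30 deg/s: 45.1 N m

# 2. simulated 10-subject cohort through the full pipeline
cfg <- list(cohort     = list(n_subjects = 10, trials_per_condition = 2),
            symmetries = "symmetric",
            analysis   = list(register = TRUE, register_max_iter = 1, lambda = 10))
report <- run_pipeline(cfg, seed = 1)
print(report)
#> <assessment_report>
#>   symmetric tasks:
#>     Fc        max F =  105.1 (crit 4.41), 1 significant interval(s), paired-t p = 3.34e-11
#>     theta     max F =    8.0 (crit 4.41), 1 significant interval(s), paired-t p = 1.72e-14
#>     omega     max F =   51.8 (crit 4.41), 3 significant interval(s), paired-t p = 8.79e-07
#>     alpha_acc max F =   71.8 (crit 4.41), 5 significant interval(s), paired-t p = 0.0529
#>     H         max F = 12627.5 (crit 4.41), 1 significant interval(s), paired-t p = 6.13e-13

fc <- report$conditions$symmetric$variables$Fc
fc$intervals
#> Fc significant from 9% to 100% of normalized time
fc$phase_rows[[1]]
#> peak-F lumbar-load reduction (flexion phase): 432 N at t = 14%
```

Reading the output: the simulated exoskeleton (injected reductions of 5.5°
peak flexion, 20 °/s peak velocity, 0.02 m reach) lowers the lumbar
compression load significantly from 9 % to 100 % of the movement; at the
most significant time of the flexion phase the reduction is 432 N. The
trunk-angle F-curve barely clears the criterion early in the movement —
exactly the pattern this kind of pointwise analysis is designed to expose,
where a peak-only t-test would report a single yes/no.

A thin CLI over the same functions lives at `inst/cli/exofanova.R`
(subcommands `simulate`, `simulate-bench`, `characterize`, `analyze`,
`report`).

## Package layout

- `R/kinematics.R`, `R/motion_trial.R` — trial container, filtering, angles,
  phases, normalization
- `R/tps.R` — thin-plate-spline torque surface (fit / evaluate / CV / JSON)
- `R/dynamics.R` — segment model, inverse dynamics, muscle QP, Fc, ICC(1,1)
- `R/fda.R`, `R/register.R`, `R/fanova.R` — B-spline smoothing, GCV,
  continuous registration, FANOVA, F-criterion, peaks, paired t-tests
- `R/synthgen.R` — synthetic cohort, bench and curve-set generators
- `R/pipeline.R` — end-to-end orchestration and JSON reports
- `vignettes/exoskeleton-assessment.Rmd` — models, assumptions, parameter
  choices and limitations
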