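---
title: "Assessing back-support exoskeletons over the whole lifting cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing back-support exoskeletons over the whole lifting cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exofanova)
```

## Overview

`exofanova` quantifies, at every point of a normalized lifting movement, how
a passive back-support exoskeleton changes five biomechanical variables:
lumbar compression load (Fc), trunk flexion angle (θ), trunk angular
velocity (ω), trunk angular acceleration (α) and the horizontal wrist–lumbar
displacement (H). This vignette documents the models, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Kinematic model

The trunk angle is the interior angle at L5 between the rays to C7 and to
the knee midpoint C; we report the flexion angle 180° − ∠C7·L5·C so an
upright posture reads approximately 0° and the 0–90° bench characterization
range of the torque model is directly interpretable. Whether the bench's
extension angle and the marker-derived flexion angle share a common zero is
an assumption of this convention; the raw interior angle remains available
through `trunk_angle()`.

All marker, COM and force channels are filtered with a 2nd-order Butterworth
low-pass applied forward and backward (zero phase, DC gain 1). Zero phase
matters because ω and α are numerical derivatives: any phase lag in θ would
translate into timing errors in the derivatives and, downstream, in the
F-curves. The filter pads each series by odd reflection about its endpoints
before the forward–backward pass; without padding, the backward pass's
start-up transient corrupts the first and last ~0.5 s, which double
differentiation then amplifies into spurious hundreds of newtons of
"inertial" load. Defaults: 4 Hz cutoff for motion and force at 60 Hz
sampling, 10 Hz for 1 kHz bench torque.

Derivatives use second-order central differences (first-order one-sided at
the two endpoints) **before** time normalization, so ω and α keep physical
units (deg/s, deg/s²); the normalized grid is only a resampling for
comparison, not a time base for differentiation. The normalized grid has 101
points (0–100 % in 1 % steps), the convention in movement analysis.

Phase segmentation offers two methods because published studies report the
task phases both ways: an event method that detects the box-carry interval
from the summed vertical hand force (threshold 20 N, 0.1 s debounce, both
configurable), and fixed published fractions — (30 %, 60 %) for symmetric
and (33 %, 67 %) for asymmetric tasks. The event method falls back to the
fixed fractions with a warning when no sustained crossing exists. Sample
indices are 1-based (R convention); boundary fractions are index-based,
(i − 1)/(n − 1), so the fixed fractions are reproduced exactly.

## Exoskeleton torque model

Assistive torque is a thin-plate spline in (trunk angle, angular velocity):
the classic scattered-data interpolant with kernel r² log r and an affine
part, which reproduces any affine torque surface exactly and interpolates
the bench records exactly at zero regularization. Two design choices the
bench protocol leaves open:

* **Input scaling.** Angle (deg) and speed (deg/s) are incommensurate, so
  both axes are scaled to [0, 1] before kernel evaluation; the scaling
  constants are stored in the fitted surface.
* **Regularization.** A ridge term on the kernel block trades fidelity for
  smoothness. The default (`"auto"`) picks λ by leave-one-speed-out
  cross-validation over a log grid, holding out interior sweep speeds.

Negative-speed queries (trunk extension while lowering) fall outside the
characterized range; by default the speed coordinate is clamped to the
fitted range and the query flagged as extrapolation, rather than assuming
torque symmetry the bench never measured. Angle is never clamped.

## Dynamics

The link chain has nine upper-body segments (forearms, upper arms, head,
shoulder girdle, thoracic spine, lumbar spine, pelvis); lower limbs are not
part of the chain. Segment masses are Winter-style fractions of body mass,
shipped as an editable table; the trunk fraction is apportioned over the
four trunk segments. The exoskeleton's mass (default 3.8 kg, configurable)
is carried at the lumbar COM when worn. Segments are treated as point masses
at their COMs — rotational inertia is neglected because the fraction table
carries no inertia tensors; for slow lifting the translational and
gravitational terms dominate the L5/S1 moment.

The gross moment is the load moment of everything above L5/S1:
M(t) = Σᵢ (rᵢ − r_L5) × mᵢ(g − aᵢ) + Σₕ (rₕ − r_L5) × Fₕ, with accelerations
from double central differencing of filtered COM positions and Fₕ the
measured external forces on the hands. Positive sagittal component = flexion
load. The assistive torque acts only in the trunk flexion plane (through C7,
L5 and C); its magnitude is subtracted from the gross-moment component along
the sign-aligned plane normal, without clamping — over-assistance shows up
as a negative net component and is flagged, not hidden.

Muscle forces minimize summed squared muscle stress Σ(Fᵢ/PCSAᵢ)² under
moment equilibrium and nonnegativity, solved by quadratic programming
(strictly convex, hence unique). The default muscle set is a six-muscle
sagittally symmetric trunk model (erector spinae, rectus abdominis and
oblique pairs) with literature-style moment arms and PCSAs in an editable
table — deliberately *not* a numerical reproduction of any specific
cadaveric dataset, since published geometries differ; results that depend on
this table are therefore validated against closed forms and oracles, not
against recorded values. Equilibrium is 3-D (sagittal + lateral + axial) by
default, with a sagittal-only mode for unit testing. Optional force upper
bounds Fᵢ ≤ σ_max·PCSAᵢ are off by default. The compression load is
Fc = Σᵢ Fᵢ(ûᵢ·n̂) − L·n̂ in the lumbar frame (n̂ cranial vertebral axis, L the
force transmitted from the upper body); all default muscle lines of action
point cranially, so muscle force always compresses.

`icc_1_1()` implements the one-way random-effects single-measure intraclass
correlation with the standard F-based confidence interval, for agreement
studies between model estimates and reference measurements; in this package
it is exercised on synthetic paired data with a known generating ICC.
`pressure_to_force()` is the linear intradiscal-pressure conversion; its
correction factor is configuration with no shipped default value, because
calibration literature, not this package, owns that number.

## Functional statistics

Curves are represented as B-spline expansions fitted by penalized least
squares with roughness penalty λ∫(D²x)². Defaults: order 4 (cubic), K = 20
basis functions over [0, 100] — enough flexibility for three-phase lifting
waveforms without tracking noise — and λ chosen by generalized
cross-validation over a log grid. The curvature penalty matrix is assembled
exactly by Gauss–Legendre quadrature per knot span.

Continuous registration aligns curves to their evolving cross-sectional mean
by minimizing the MINEIG criterion (smallest eigenvalue of the 2×2
cross-product matrix between target and warped curve — zero exactly when the
two are proportional). Warps use the exponentiated-slope construction
h(t) = a + (b − a)·∫ exp W / ∫ exp W with W an order-2 B-spline with 5
interior knots, so h(a) = a, h(b) = b and strict monotonicity hold by
construction, not by constraint. A small ridge penalty (1e-4) on the warp
coefficients keeps warps mild and the identity warp the default answer for
already-aligned curves. If an outer-loop mean update would increase the
total criterion, the previous iterate is returned, so the reported criterion
trace is non-increasing. Registration is applied per condition–variable
stratum (configurable), mirroring how the curves are later compared.

The FANOVA model is f(t) = μ(t) + α_g(t) + ε(t) for the two exoskeleton
conditions, with the identifiability constraint α₁ + α₂ = 0 enforced exactly
by reparameterizing α₂ = −α₁ rather than by penalization. The pointwise
F-ratio is F(t) = [(SSY − SSE)/df_error]/[SSE/df_regression] with
df_error = 1 and df_regression = n − 2 (18 for the canonical 20-curve
design, giving the F-criterion 4.41 at α = 0.05). These df labels follow the
convention of the functional-ANOVA formulation this package implements
(numerator df 1, denominator df n − 2), which is what reproduces the 4.41
criterion; df_regression generalizes to n − 2 so designs other than 10 + 10
work. At any fixed t this F equals the classical two-group ANOVA F computed
on the curve values at that t — the test suite verifies the identity to
1e-9. Peaks of ω and α are taken as maximum absolute value, since both swing
negative during lowering; ties take the first grid point.

No multiplicity correction is applied across time points: the F-criterion is
a pointwise α = 0.05 threshold, and the reported significant intervals
should be read accordingly. Interval-wise error control is out of scope.

## What the synthetic generator emulates — and what it does not

`cohort_spec()` defaults encode the study conditions: 10 subjects
(mass 68.1 ± 8.8 kg, height 1.72 ± 0.08 m), 5 trials per condition,
symmetric and asymmetric (90° box-table angle) layouts, a 10 kg box
(98.1 N), 60 Hz sampling. Trunk flexion follows minimum-jerk segments — the
standard motor-control surrogate — through the three phases; markers and
segment COMs are kinematically consistent with the flexion angle over a
two-link trunk–arm geometry; hand forces carry the box weight during the
lifting phase with smooth cosine ramps. Exoskeleton-on trials apply the
configured ground-truth reductions (defaults: 5.5° peak flexion, 20 °/s peak
velocity, 0.02 m reach — plausible effect magnitudes for a passive
back-support device). Noise defaults are instrument-grade and configurable:
5 mm marker, 1 N force, 2 N·m bench torque. Phase-timing jitter is 5 % of
phase duration. Within-subject kinematic variance values are stated
assumptions, not fitted quantities.

Randomness is structured for both realism and testability: anthropometry is
drawn from a subject-only substream (identical across a subject's
conditions), phase timing from a trial substream shared between the paired
exo-on/off recordings (so zero effect sizes and zero noise give literally
identical paired trials — a generator identity the tests exploit), and
measurement noise from a condition-specific substream. All generators are
pure functions of (spec, seed), with derived sub-seeds kept below 2³¹.

`generate_curveset()` powers the statistical calibration studies: each curve
is a base mean plus a per-curve offset plus stationary squared-exponential
Gaussian-process noise, so the pointwise noise SD is the constant
√(offset_sd² + gp_sd²). Offsets are drawn independently for every curve —
the groups are unpaired — which makes curve values at any fixed time iid
normal under a null effect, so the pointwise null F is exactly F(1, n − 2)
and type-I calibration against the 4.41 criterion is meaningful. The bump
effect used in recovery studies is flat over its stated support with short
cosine shoulders *outside* it, so every grid point inside the support
carries the full effect and "coverage of the support" is well defined.

What the generator does **not** emulate: ground-reaction forces, lower-limb
kinematics, soft-tissue artifact, marker occlusion, inter-marker correlation
structure of real IMU reconstructions, EMG, or fatigue drift across trials.
Passing tests on synthetic cohorts therefore demonstrate the correctness and
calibration of the estimation and testing machinery — not the physiological
accuracy of any specific muscle geometry or anthropometric table on real
recordings.

## Numerical choices and problem sizes

* Filter warm-up requires > 3(2·order + 1) samples; shorter series error out.
* TPS kernel uses 0.5·d²·log d² with the d = 0 limit set to 0; duplicated
  (angle, speed) sites are averaged before fitting so the kernel matrix stays
  nonsingular.
* Smoothing solves the penalized normal equations by Cholesky; a failed
  factorization (K > N at λ = 0) is reported as rank deficiency.
* The QP objective is rescaled by mean PCSA² for conditioning (the argmin is
  unchanged); along a trajectory the equality-constrained closed form
  F = D⁻¹Aᵀ(AD⁻¹Aᵀ)⁻¹M is used wherever it is already nonnegative, with the
  full QP only at samples where nonnegativity binds.
* Degenerate geometry (collinear C7, L5, C) reuses the previous sample's
  flexion plane with a warning; a first-sample degeneracy takes the first
  valid plane.
* Test and acceptance runs use deliberately scaled problem sizes — e.g.
  bench sweeps sampled at 100–200 Hz instead of 1 kHz, 2 trials per
  condition in pipeline determinism runs, and single-pass registration in
  the end-to-end checks — chosen so the full suite exercises every code path
  at the study's design shape (10 subjects, 20 curves, 101 grid points)
  while remaining quick to run.

## Known limitations

* Point-mass segments: no rotational inertia terms in the Newton–Euler
  recursion.
* The default muscle geometry and anthropometric fractions are editable
  stand-ins in the style of the literature, not subject-specific models;
  absolute Fc values depend on them.
* The torque surface is fitted from positive-speed bench sweeps only;
  behavior during trunk extension is extrapolation by clamping.
* Pointwise significance without multiplicity correction (see above).
* Registration minimizes a shape criterion; it cannot distinguish a pure
  time shift from a genuine timing effect — condition-level timing
  differences are absorbed into the warps when registration is applied
  across conditions within a stratum.
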