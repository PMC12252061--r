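---
title: "Insertion-torque modelling and stripping-torque prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insertion-torque modelling and stripping-torque prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screwstrip)
```

## The problem

A self-tapping cancellous screw forms its own threads in bone (or, on the
bench, rigid polyurethane foam). The torque at which those formed threads
shear off — the stripping torque — is the hard ceiling for tightening, and
it varies by more than an order of magnitude across host materials.
`screwstrip` estimates that ceiling *during* the insertion itself, from the
torque, rotation and axial-position signals a sensorized screwdriver can
record, in two model-based steps: identify the host material's ultimate
compressive strength from the insertion segment, then convert that strength
into a predicted stripping torque.

Everything is kept in a single consistent unit system internally —
millimetres, MPa, N·mm, radians, seconds — so that MPa·mm³ = N·mm and no
hidden conversion factors appear in the model equations. Degrees and N·m
exist only at the file boundary (geometry configs, trace CSVs).

## Insertion model and strength identification

Torque during insertion is modelled as

$$\tau(\varphi) = \sigma_{ucs} G_1 +
  \mu_T\,\sigma_{ucs}\,(\varphi - \alpha/2)\, G_2,$$

a constant cutting term (the tapered tip plastically deforming the hole
wall) plus a friction term that grows linearly with rotation, because each
revolution adds one pitch of formed thread pressing on the screw flanks at
roughly the material's yield stress. $G_1$ and $G_2$ collapse the geometry:

* pitch angle $\theta = \arctan(p / \pi D_s)$,
* friction radius $r_f = (D_h + D_s)/4$, cutting radius
  $r_s = (2D_h + 2D_s)/6$,
* thread cross-section intersecting the wall
  $A_c = \tan\beta\,((D_s - D_h)/2)^2$,
* friction factor $K_{f0} = \tfrac12 (D_s-D_h)(1+\tan^2\beta)
  \sqrt{((D_s+D_h)/4)^2 + (p/2\pi)^2}$,
* $G_1 = r_s A_c / \cos\theta$, $G_2 = 2 r_f K_{f0} / \cos\theta$.

The model is *linear in the one unknown* $\sigma_{ucs}$, which is the whole
point: identification is closed-form through-origin least squares,
$\hat\sigma = \sum \tau_i x_i / \sum x_i^2$ with
$x_i = G_1 + \mu_T G_2 (\varphi_i - \alpha/2)$. No iteration, no starting
values, no convergence failures — an important property for an instrument
that must run in real time. We deliberately fit without an intercept: the
physics says torque is proportional to strength, and an intercept would
absorb systematic offsets into a parameter with no physical meaning.

Two numerical conventions matter:

* **Clamping.** For $\varphi < \alpha/2$ the friction term would be
  negative; the forward model clamps it to zero and keeps the cutting term.
  Samples in that regime are *excluded* from the fit (the clamped model is
  a poor description of pure tip-cutting), and the rotation range actually
  used is reported in `fit_range`.
* **The engagement offset $\alpha$.** The rotation consumed by the taper
  before full-profile thread exists is not directly measurable. The default
  policy derives it from the tip geometry,
  $\alpha = 2\pi L_{taper}/p$ with $L_{taper} = (D_s - D_h)/(2\tan\theta_t)$
  — the rotation needed for a taper of angle $\theta_t$ to open the hole
  from $D_h$ to $D_s$ — about 2.18 rad for the default screw. Because this
  derivation is a modelling choice (the taper angle could plausibly be read
  as a half- or full-angle, and the offset could be calibrated instead), it
  sits behind a policy switch: `"from-taper-geometry"` (default) or
  `"explicit-value"`, and the resolved value is recorded in the
  coefficients object. In practice the fit is insensitive to moderate
  $\alpha$ error: the insertion segment starts two revolutions
  (~12.6 rad) in, far above $\alpha/2 \approx 1.1$ rad.

The fit uses the *equivalent rotation* derived from the draw-wire position
($\varphi_{eq} = 2\pi\,\Delta z/p$) rather than the encoder, because the
screw slips rotationally during early engagement: rotation accumulates
without proportional advance, and the encoder signal would stretch the
abscissa of exactly the samples where the model is least valid. A flag
(`use_position = FALSE`) restores the raw encoder for sensitivity checks.

## Stripping model

Failure is modelled as shear of the material cylinder at the thread tips:
envelope area $A_C = \pi D_s L$, shear angle
$\theta_\tau = \operatorname{atan2}(p, \pi D_s) +
\operatorname{atan2}(1, -\mu_T)$, giving

$$\tau_{fail} = \frac{\sigma_{ucs}}{\sqrt3} A_C \left[
  \frac13 \frac{D_{head}^3 - D_{shaft}^3}{D_{head}^2 - D_{shaft}^2}
  \mu_H \sin\theta_\tau - \frac{D_s}{2}\cos\theta_\tau \right].$$

$\theta_\tau$ lies in the second quadrant for any positive thread friction
(it *increases* with $\mu_T$, approaching $\pi$), so $\cos\theta_\tau < 0$
and both bracket terms are positive: head friction and thread shear both
resist rotation. For the default geometry the prediction is
765.18 N·mm per MPa — about 3.06 N·m for a 4 MPa foam.

The stress concentration factor
$k_t = 1 + [1 + 1.5\tanh(0.3\ln\gamma + 0.7)]\,\gamma$, with
$\gamma = (D_{shaft} - D_{minor})/p$, captures how sharp thread tips
locally raise stress; it is applied by *division*. Two design decisions:

* $k_t$ is **undefined** for the default screw: its shank (2.8 mm) is
  narrower than its thread root (3.0 mm), so $\gamma < 0$ and
  $\ln\gamma$ does not exist. This is treated as a reportable state
  (`kt_defined = FALSE`), never a crash: the prediction runs uncorrected,
  and a user can supply an explicit factor (`kt_mode = "value"`). Which
  diameter the ratio *should* use for such screws is genuinely open; we
  prefer surfacing the ambiguity over silently substituting a diameter.
* The default mode is `"none"`. Ductile materials — the polyurethane foams
  the bench uses, and likely most cancellous bone — redistribute local
  tip overloads, so the uncorrected torque is the better central estimate;
  the corrected value is a lower bound for brittle behaviour. Both bounds
  are always present in the output so a cohort can be read against the two
  1:1 scales. An experimental interpolation $\tau_{fail}/k_t^d$,
  $d \in [0,1]$, is available (`ductility_exponent`) but excluded from
  default reports: calibrating $d$ against ductility measurements is
  future work, not something foam data settles.

## Signal processing

The pre-processing mirrors what a strip-to-failure bench needs:

* **Crop**: start = first sample strictly more than 1° of rotation from the
  initial value; end = first sample within 1° of the maximum rotation.
* **Tightening onset**: smooth torque with a 1 s moving average,
  differentiate by central differences, and take the first crossing of
  6× the 90th percentile of that derivative. The percentile is computed
  over the whole cropped trace; since the threshold is *relative*, the
  detection is invariant to torque rescaling and to per-sample vs
  per-second derivative units (both asserted in tests). A blanking period
  of 2 encoder revolutions after the crop start skips engagement spikes.
* **Empirical stripping torque**: maximum of the 0.03 s median-filtered
  torque — the median kills single-sample spikes that a plain max would
  mistake for the peak.

Filter windows are specified in *seconds* and converted with the trace's
actual sample rate, so the defaults (1000-sample smoothing, 30-sample
median at 1 kHz) transfer to rigs with other clocks. Both filters use
shrinking windows at the edges — no padding constants are invented — and
the derivative is one-sided at the endpoints. Degenerate inputs fail
loudly with located errors: no motion, no tightening crossing (a
constant-slope torque can never exceed 6× its own upper percentile),
non-monotone or non-uniform (>1 ppm) time grids, windows longer than the
signal.

## The simulator

`simulate_insertion_trace()` generates the canonical five-phase recording
— settle, engagement, insertion, tightening, stripping — with known ground
truth, emulating a motorized bench: 30 RPM, 1 kHz sampling, 0.25° encoder
and 0.025 mm draw-wire quantization (round-to-nearest, so half-step error
bounds hold exactly), and Gaussian torque noise with SD 25 N·mm (0.5% of a
±5 N·m sensor). Choices the data does not dictate, made once:

* **Lot-to-lot variability**: true strength is drawn mean-preserving
  lognormal around the nominal value with CV 5% — a realistic spread for
  machined PU foam and safely positive. The programmed stripping peak gets
  an independent lognormal factor with the same CV.
* **Engagement slip**: no axial advance for the first 10% of the
  engagement phase (the tip must rotate before it bites — this also makes
  position exactly zero at the crop-start instant, as the bench's zeroing
  procedure does), then the advance fraction ramps linearly to full pitch
  per revolution over two revolutions.
* **Tightening and stripping shape**: the head seats over half a
  revolution with a linear torque ramp to the peak, holds 0.05 s (long
  enough that the median filter sees a plateau), then decays
  exponentially towards a 30% residual plateau over two revolutions.
  With ten insertion revolutions these defaults put the
  final-insertion-to-stripping torque ratio near 0.38, inside the 0.2–0.5
  band observed on real foam benches; because both torques are linear in
  strength the ratio is nearly material-independent in the simulator,
  which is one of several ways it is *simpler* than reality.
* Traces are **not clipped** at the sensor range; peaks beyond 5 N·m
  (the densest foams) only set a `sensor_range_exceeded` flag in the
  ground truth. Clipping would silently corrupt the round-trip contracts
  the simulator exists to provide.

What passing tests therefore show: the identification, segmentation and
prediction chain is *internally correct* — exact round trips on ideal
sensors, sub-percent median strength error and reliable onset detection
under bench-level noise and quantization, near-unity cohort correlations.
What they cannot show: performance on real bone, where friction
coefficients are uncertain and history-dependent, density varies along the
screw axis, ductility differs between cortical and cancellous tissue, and
the engagement micro-mechanics are richer than a slip ramp. The simulated
cohort correlation is accordingly *higher* than what heterogeneous real
materials produce; the simulator validates software, not biology.

## Evaluation statistics

Cohort evaluation reproduces the standard recipe: Pearson correlation with
the Fisher-z interval $\tanh(\operatorname{atanh} r \pm
z_{(1+c)/2}/\sqrt{n-3})$; a two-sided Fisher Z-test for comparing the
strength-identification and torque-prediction correlations (two-sided
because neither direction is privileged a priori); an in-sample OLS
calibration of predictions (mirroring how a deployed instrument would be
calibrated; its residual-mean-zero identity is asserted); and Bland–Altman
bias/limits in absolute and relative (percent of pair mean) form. The
mean absolute relative error uses the *measured* torque as denominator,
since the clinically relevant question is the error as a fraction of the
true ceiling. Exact linear relations ($|r| = 1$) collapse the interval
rather than hitting the atanh singularity.

## Problem sizes

The test suite and acceptance script use: 8 materials × 100 seeds for
noisy strength recovery, 100 traces for onset detection, 8 × 10 for the
end-to-end cohort, 50 random segments × 10⁵-point grids for the
brute-force least-squares oracle, and 1000 replicates for the
unbiasedness check — sizes chosen to make the Monte-Carlo assertions
stable at the tolerances tested while keeping a full run in the
low minutes on one core.
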