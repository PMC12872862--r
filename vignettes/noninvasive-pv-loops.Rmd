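---
title: "Non-invasive pressure-volume loop analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive pressure-volume loop analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvloopr)
```

## The problem

Ejection fraction and global longitudinal strain are load-dependent: a
ventricle facing severe aortic stenosis can keep both "normal" while its
workload and oxygen demand climb. Pressure-volume analysis separates pump
properties from load, but classically requires a micromanometer catheter in
the LV. `pvloopr` implements a single-beat, fully non-invasive surrogate:
an individualized LV pressure waveform is estimated from a brachial cuff,
the Doppler mean transaortic gradient and valvular event times, and paired
with a 3D-echocardiographic volume-time trace.

## The pressure model

### Reference curve

The estimator needs a normalized LV pressure shape over one cycle (phase 0 =
mitral valve closure, phase 1 = the next MVC) with landmark phases for AVO,
AVC and MVO. Averaged multi-patient curves of this kind are built from
catheterization archives and are generally not redistributable, so the
package ships a documented parametric template (`default_reference()`):
raised-cosine segments through anchor points

| phase | pressure (normalized) | meaning |
|---|---|---|
| 0 | 0.08 | end-diastole |
| 0.08 (AVO) | 0.45 | diastolic-pressure crossing |
| 0.224 (peak) | 1.00 | mid-ejection peak |
| 0.40 (AVC) | 0.38 | end-ejection |
| 0.47 (MVO) | 0.05 | early relaxation minimum |
| 1 | 0.08 | next end-diastole |

Raised cosines give zero slope at every anchor, hence a single smooth
maximum between AVO and AVC and no spurious extrema. Any site that owns an
averaged reference curve can substitute it through `read_reference()`
(a `phase,p_norm` CSV with a landmark header); everything downstream only
uses the two-anchor scaling contract.

### Scaling contract

Horizontally, a strictly increasing piecewise-linear warp maps the landmark
phases exactly onto the measured event times (and phase 1 onto
`t_mvc + cycle_length`, wrapped periodically into the R-wave-aligned cycle).
Vertically, a single affine map `a p + b` solves

* `a · 1 + b = SBP + mean gradient` (peak pressure anchor), and
* `a · p_ref(AVO) + b = DBP` (aortic-valve-opening anchor),

after which the diastolic limb is clamped at a floor (default 2 mmHg).
Without outflow obstruction the gradient term is simply zero. The scaled
knots are interpolated with a monotone Fritsch-Carlson cubic
(`splinefun(method = "monoH.FC")`): it passes through every knot and never
overshoots between knots, so the *continuous* waveform attains its maximum
exactly at the peak knot and equals DBP exactly at `t_avo`. The returned
trace is sampled on a uniform grid (default 200 Hz) and carries the warped
knots; `peak_pressure()` and `pressure_at()` evaluate the continuous model,
which is what the anchoring guarantees refer to (a finite sampling grid can
only honor them to sampling error).

The two-anchor design says nothing about diastole: the model is known to be
unreliable in the filling phase, which is why the end-diastolic
pressure-volume relationship is excluded from scope entirely.

## Loop metrics

`pv_loop()` pairs synchronized samples into a closed polygon, normalized to
counter-clockwise traversal. Choices worth stating explicitly:

* **Stroke work** is the absolute shoelace area. (The trapezoid time
  integral of `P dV/dt` is algebraically near-identical; the test suite
  keeps both routes as a cross-check.)
* **End-systolic point**: volume and pressure are min-max normalized to
  `[0,1]`; the center is the *vertex mean* (an area centroid would also be
  defensible; the vertex mean is simpler and grid-density effects are
  negligible at 200 Hz); candidates are vertices strictly left of and above
  the center; the detected vertex maximizes the Euclidean distance to the
  center, ties broken by earliest time.
* **`V0 = 0`**: the ESPVR intercept cannot be identified from one beat, so
  it is pinned at the origin. `Ees = ESP/V_es` is then a deliberate lower
  bound on the true-intercept slope (asserted as a property test against
  the simulator's known `V0`).
* **Potential energy**: with the EDPVR out of scope, the area between the
  ESPVR, the relaxation line and the volume axis reduces to the triangle
  `PE = ESP (V_es - V0)/2`. Published cohort tables computed with a
  different (unstated) diastolic treatment will not match this absolute
  value, and the package does not attempt to; the identities `PVA = SW +
  PE` and `efficiency = 100 SW / PVA` are enforced by construction in
  `pv_energetics()`, which both the per-loop metrics and cohort-level
  summaries share.
* `V_es` (for `Ees`, `PE`) is the volume at the detected end-systolic
  vertex; `ESV` (for `SV`) is the cycle's minimum volume. These differ: the
  detected point normally sits slightly before minimum volume.

## Myocardial work

Segmental power is `P(t) · (-d strain/dt)` (mmHg · %/s), integrated from MVC
to MVO. During systole (MVC-AVC) shortening is constructive and lengthening
wasted; during isovolumic relaxation (AVC-MVO) the roles invert. GWI is the
mean net work across segments, GCW/GWW the means of the components, and
`GWE = 100 GCW/(GCW+GWW)`. Strain is differentiated by centered finite
differences on the shared grid; the phase-boundary sample can smear a
fraction of a percent of work across the systole/IVR boundary, which is far
below the physiological signal. Strain traces are re-referenced to zero at
cycle start on input.

## Agreement statistics

The method-comparison battery mirrors standard echo-validation practice:
Pearson r, OLS slope/intercept, Bland-Altman bias with limits of agreement
fixed at `bias ± 1.96 SD` (the multiplier is exposed but the identity is
never adjusted post hoc), and single-rater ICCs computed from ANOVA mean
squares — ICC(1,1) one-way random for intraobserver, ICC(2,1) two-way
random for interobserver, ICC(3,1) consistency for method comparison, each
labelled in the output to prevent model confusion. Paired t and Wilcoxon
signed-rank comparisons delegate to `stats`; a zero-variance difference
vector is reported as a degenerate-case flag rather than an error.

## The simulator

The validation design needs paired "true" and estimated loops. The
simulator is deliberately kinematic, not a closed-loop circulation model:
the volume waveform is prescribed and pressure follows from a time-varying
elastance, which is exactly enough to exercise and stress the estimator
deterministically.

* **Volume**: flat at EDV through isovolumic contraction, a skewed
  raised-cosine ejection limb `EDV - SV · rc(s^0.8)` (transvalvular flow
  peaks early in ejection, as it physiologically does), flat at `EDV - SV`
  through isovolumic relaxation, and an E-wave-like filling limb
  `rc(u^0.45)` — rapid early filling followed by diastasis near EDV.
  The E-wave shape matters beyond realism: with an (unphysiological)
  symmetric slow filling limb the loop spends half the cycle at mid-range
  volumes, the vertex-mean center shifts, and the geometric end-systole
  detector drifts onto the mid-ejection pressure ridge.
* **Pressure**: `P = E(t)(V - V0_sim)` with a double-Hill normalized
  activation; defaults `tau1 = 0.269 L, n1 = 1.9, tau2 = 0.45 L, n2 = 21.9`
  place peak elastance at ~96% of ejection, i.e. end-systole essentially at
  aortic valve closure, where it physiologically belongs.
* **Stenosis**: instantaneous gradient `c · Q²` with `Q = -dV/dt` during
  ejection; aortic pressure is LV pressure minus the gradient; the cuff is
  equated to the central aortic extremes (systolic = maximal aortic
  pressure, diastolic = aortic pressure at AVO; no peripheral
  amplification). The ejection-time average of the gradient is the "Doppler
  mean gradient" handed to the estimator.
* **Defaults** emulate a severe-AS, preserved-EF patient: EDV 165 mL, SV
  93 mL, RR 0.9 s, `E_max` 2.6 mmHg/mL — which yields a systolic cuff
  pressure near 160 mmHg and a mean gradient near 51 mmHg, the typical
  pre-replacement operating point of such a cohort.
* **Cohorts** (`simulate_cohort()`) draw EDV 140-200 mL, EF 0.50-0.62,
  `E_max` 2.2-3.2, `E_min` 0.05-0.09, RR 0.75-1.05 s and target mean
  gradient 30-80 mmHg, solving the stenosis coefficient per beat
  (`stenosis_for_gradient()`). A draw whose ventricle cannot generate its
  drawn gradient (instantaneous gradient exceeding LV pressure, i.e.
  non-positive aortic pressure) is hemodynamically impossible — the
  low-flow/low-gradient regime — and is rejected and redrawn from the same
  seeded RNG stream, keeping cohorts reproducible.

What the simulator does *not* emulate: measurement noise in the volume
trace, frame-rate limits of 3D echo, RR variability, peripheral pulse
amplification, atrial kick, and heart-rate dependence of the elastance
shape. Passing recovery tests therefore demonstrates internal consistency
of the method chain, not clinical accuracy; the latter requires invasive
validation data that the package cannot ship.

## Numerical choices and problem sizes

Interpolation everywhere is monotone cubic (no overshoot near anchors);
trapezoid quadrature for all integrals; the default grid is 200 Hz, and
cycle-length mismatch up to 5% between pressure and volume is absorbed by
linear time rescaling (beyond that, synchronization refuses). The test
suite and the acceptance script use 50-beat cohorts, 200-configuration
property sweeps and 720-vertex geometric oracles — sizes at which every
check completes in seconds while the statistical assertions (recovery
r > 0.9, end-systolic timing within 20 ms of maximal elastance) are stable
across seeds.

## Known limitations

Single-beat `Ees`, `VAC`, `PE` and efficiency all inherit the `V0 = 0`
convention and are not interchangeable with multi-beat, preload-varying
estimates. The estimated diastolic limb should not be used to derive
filling-phase indices. Absolute work values are load- and size-dependent
and need normalization before between-patient comparison.
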