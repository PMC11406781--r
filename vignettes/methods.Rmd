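---
title: "Markerless sagittal gait analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless sagittal gait analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the measurement model, the angle conventions, the walker simulator that
stands in for clinical recordings, the tunable parameters, the numerical
choices, and the limits of what passing tests demonstrate.

## The measurement scenario

A single camera views a walkway from the side. The scene is engineered so
that plain color filtering is sufficient for feature extraction: a green
screen behind the walkway, a red sock on the right foot, a blue sock on
the left, and dark pen marks on the greater trochanter, the lateral
femoral epicondyle and the lateral malleolus of each leg. Frames are RGB
at 30 frames/s with a known pixel-to-meter scale. From these five
landmarks per side the entire sagittal analysis follows.

Two consequences of the single-camera geometry shape everything else:

* the two hip marks project to (nearly) the same image point, so the
  package models one shared trochanter;
* the far leg is periodically occluded by the near leg. The original
  hardware disambiguated legs with a depth sensor; here the sock colors
  carry the identity instead. This is a stated divergence: color is
  unambiguous for the feet, while the pen marks must be associated to
  sides geometrically (see *Tracking*).

## Angle conventions

All angles are degrees, metric coordinates are x forward / y up:

* **Hip flexion** is the femur inclination measured from the *downward
  vertical*, flexion positive. Raw inclination from the horizontal would
  place typical values near 90°, while clinical sagittal hip curves span
  roughly −25° to +40°; reporting 90° minus the horizontal inclination
  reproduces the clinical value range. The reference is the room, not the
  pelvis, so curves carry a known offset against pelvis-referenced hip
  kinematics from instrumented laboratories. The offset is documented,
  not corrected.
* **Knee flexion** is the signed angle between femur and tibia vectors;
  0° at full extension, hyperextension negative. The feature
  "peak knee extension in stance" is therefore a *minimum* of the flexion
  curve and can be negative — the only reading under which hyperextending
  knees produce the negative values that clinical summary tables print.
* **Ankle dorsiflexion** is the signed angle between the foot axis
  (heel→toe) and the perpendicular to the tibia; 0° when the foot is
  perpendicular to the shank.
* **Foot orientation** is the heel→toe line against the horizontal,
  heel-up positive; it is the room-referenced signal on which toe-walking
  and the foot rockers are judged.

Translation of the whole scene changes no angle; rotation changes only
the two room-referenced angles (hip, foot orientation). Both properties
are asserted as tests.

## The walker simulator

Clinical video cannot ship with a package, so the generator is
first-class, tested code. It emulates the acquisition scenario — and only
that: stick-figure geometry with sock-colored foot polygons and dark
marks, not photorealism.

**Curves.** One cycle of hip, knee and ankle angles is built from
editable keyframes (periodic splines). The normal ankle curve is derived
during stance from a foot-rollover target — heel-down contact rolling
flat over 0–10 % (first rocker), foot flat to 40 % (second rocker), heel
rise to toe-off (third rocker) — and from a near-neutral ankle in swing.
Patterns are additive offset curves on top of the normal template
(e.g. the true-equinus template shifts the ankle 20–30° into
plantarflexion throughout), re-smoothed by truncating the periodic
spectrum to 12 harmonics so that value and slope are continuous across
the 100 %→0 % wrap.

**Ground contact.** The trochanter path is obtained by anchoring the
stance-foot contact point: the heel from initial contact to heel rise
(0–40 % of the cycle), the toe to 50 %; toe-walking patterns anchor the
toe throughout. Anchor constants are chained so the path is continuous,
which makes the anchored heel *exactly* stationary during foot flat — the
property the zero-velocity event detector rests on.

**Calibrations.** Arbitrary curve shapes do not walk on level ground.
Two scalar calibrations, solved jointly by a damped 2×2 Newton iteration,
make them: the hip excursion is scaled until the realized step length
matches the pattern target, and a smooth pre-swing knee(+ankle) bump
zeroes the per-cycle vertical drift of the footfalls. A third, small
calibration steepens the terminal-swing approach of the landing foot if
a template would otherwise "park" it early — a zero-velocity detector
cannot date a contact that arrives at zero velocity. The calibrated
curves are stored as the trajectory's ground truth, so the
simulator/kinematics closure (regenerating the angles from the landmark
positions) is exact by construction; the tests assert it below half a
degree.

**No double support.** A single anchored contact implies the stance
fraction is 50 % and true toe-off coincides with the contralateral
initial contact — not the physiological ~60 %/40 % split. An explicit
double-support model was considered and rejected: holding the trailing
toe through a double-support window requires late-stance corrections of
tens of degrees that distort the clinical features far more than the
missing phase does. Consequences: detected toe-off sits near 50 % of the
cycle, and the pre-swing rollover concentrates ankle dorsiflexion just
before 50 %. For this reason the classifier and the
plantarflexion–knee-extension-couple flag judge ankle posture on the
*midstance window* (10–40 %), where loading actually happens, rather
than on the whole-stance maximum.

**Study conditions.** Defaults emulate a slow, short-stepping school-age
cohort: stature 1.36 m with published segment fractions (thigh 0.245 H,
shank 0.246 H, foot 0.152 H); cycle durations of 1.0–1.2 s and step
targets of 0.27–0.42 m depending on pattern (the normal pattern's
0.42 m at 32 frames per cycle walks at ~0.79 m/s; the cohort means are
0.69 m/s and 0.37 m); landmark jitter SD 5 mm, i.i.d. per frame and
coordinate; frame dropout probability 0 unless a test injects it. Cycle
durations are quantized to an even number of frames so both sides'
contacts fall on frame boundaries and ground-truth events are exact
integers.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real recordings: soft-tissue and clothing appearance,
marker placement error (the pen marks sit exactly on the model joints),
exposure and motion blur, lens distortion, out-of-plane (coronal or
transverse) motion, pelvis obliquity (both hips share one point),
inter-stride variability within a trial, and double support. Accuracy
numbers on synthetic scenes are validation of the *pipeline mechanics*,
not a clinical validation.

## Segmentation and tracking

Segmentation is hue/saturation/value thresholding per color class, with
the red hue range wrapping through 0°, and removal of connected
components below a minimum area (12 px for socks, 4 px for marks).
Defaults match the renderer's palette; real video needs re-tuning via the
run configuration.

Heel and toe are the sock blob's extremes along its *principal axis*
(sign-aligned with the walking direction), with a half-pixel tip
extrapolation and the transverse centroid of the extreme 5-px band. For
an axis-aligned blob this reduces to the extremes along the walking
direction; for a pitched foot it avoids the corner bias a pure
x-extreme would have.

Pen-mark association uses the scene's structure: the shared trochanter
is the topmost dark blob (tracked by proximity); each malleolus anchors
to its own sock; the epicondyle of a side must lie one rigid shank
length from that side's malleolus, with the shank length estimated
online. The assignment is stateless per frame and must beat the swapped
assignment by a clear margin, otherwise (legs superposed) the marks are
declared missing — continuity-based identity was tried first and
discarded because a swap, once made, is self-consistent and persists.
Partial occlusions are caught by two guards: a sock blob whose area
falls below 75 % of the trial median, or whose implied rigid foot length
deviates more than 12 % from the trial median, is flagged missing.

Gaps up to 5 consecutive frames are filled by linear interpolation (and
flagged as such); longer gaps stay missing, and any cycle containing a
missing frame is excluded from normalization. Trajectories are smoothed
with a zero-lag low-pass filter before any differentiation: a 2nd-order
Butterworth run forward and backward (effective 4th order) at 6 Hz for a
30 frames/s signal, with reflective padding against edge transients.

A trial in which fewer than 80 % of frames have both feet *detected at
all* is rejected with a structured condition (reason code
`feet_identification`) rather than an error — mirroring how unusable
recordings are excluded from clinical series. The finer occlusion guards
deliberately do not count against this gate: they refine localization of
feet that were found.

## Event detection

"Zero velocity" is implemented as planar marker speed below
`vThresh = 0.05` m/s sustained for `dwell = 3` frames. Planar — not
horizontal-only — speed matters because toe-walkers land and lift the
forefoot almost vertically. Initial contact takes the earlier qualifying
instant of heel and toe (heel first in heel-strikers, toe first in
toe-walkers); overlapping or nearly adjacent quiet runs of the two
markers merge into one contact episode, and detections of the same foot
closer than 12 frames keep only the earliest (same-foot contacts are at
least a stride apart).

Three refinements handle measurement noise, each inert on clean data:

* *Adaptive event channel*: if a low quantile of the second differences
  indicates frame-to-frame jitter, the (unsmoothed) heel/toe series are
  low-passed at 3.5 Hz before differentiation; the speed threshold is
  raised above the measured noise floor.
* *Plateau snap*: after the threshold rule fires, the contact is snapped
  to the first frame with sustained proximity to the episode's stationary
  plateau, measured on the unsmoothed positions (a zero-lag filter smears
  the stop symmetrically; the raw plateau does not). The proximity
  tolerance adapts to the marker's scatter, capped at 2 cm.
* *Toe-off escape*: toe-off is the first sustained speed rise after the
  toe's quiet episode *that accelerates to at least six times the
  threshold* — separating lift-off, which accelerates into swing, from
  the slow pitching of a foot rolling over its anchored heel.

Detected cycles whose duration deviates more than 20 % from the trial
median are dropped as implausible (a missed or misplaced contact).
On noise-free synthetic trials of every pattern, detection is exact to
±1 frame for initial contact and ±2 for toe-off; the tests assert this.

## Features, normative band and classification

Features are computed per cycle on the 101-point normalized curves and
averaged across the cycles of a side: hip maximum extension and ROM; knee
at initial contact, loading-response peak (maximum over 0–15 %), peak
stance extension (minimum between the loading-response peak and
toe-off), swing maximum and ROM; ankle dorsiflexion maxima in stance, in
swing, and in the 10–40 % midstance window; foot orientation averaged
over 10–30 %; plus gait speed and mean step length.

The normative band is the pointwise mean and sample SD over an ensemble
of normal-pattern trials (each trial contributing its mean curve), used
with a half-width of 1 SD. `defaultNormativeBand()` builds it from
simulated noisy normal trials under fixed seeds; user-supplied reference
curves can replace it.

The source classification is an expert reading; the package makes the
cutoffs explicit and configurable, with defaults: toe-walking if the
10–30 % foot orientation average exceeds +10° heel-up *or* the first
rocker is absent (the foot never drops below −2° in 0–10 %); ankle
regime from the stance maximum (plantarflexion throughout if below 0°)
and the midstance window against the band; knee/hip posture from the
midstance means against the band. The combination maps to types I–IV;
anything else is `unclassified_mild`. Type III requires increased knee
*and* hip flexion (its definition), type II is separated from type I on
the knee (the hip is recorded in the rule trace); this choice is
deliberately conservative about the hip because of the room-referenced
hip convention. Every comparison lands in the rule trace.

The deviation flags for mild patterns follow the same band logic; the
plantarflexion–knee-extension couple requires stance knee hyperextension
together with midstance ankle dorsiflexion at or below +5°, judged on
the 10–40 % window for the reason given above.

## Problem sizes

The package's own evaluations use: 20 rendered trials (960×540 px,
240 px/m, 3 cycles per side, ~110 frames each) for the end-to-end
kinematic accuracy batch; 40 trajectory-level trials for the
spatio-temporal accuracy batch; 6–8 trials for the default normative
band. These sizes keep the full suite in minutes on one CPU while leaving
every pattern represented at least twice in each batch.

## Known limitations

* The hip is thigh-versus-room; comparisons against pelvis-referenced
  kinematics carry a posture-dependent offset.
* No double support (see above): toe-off timing and pre-swing ankle
  values are schedule artifacts; midstance windows are the reliable part
  of the cycle.
* Leg identity rests entirely on sock color; the far leg's pen marks are
  briefly unobservable at every crossing and are bridged by
  interpolation. Scenes without color-coded feet are out of scope.
* Color thresholds are tuned to the synthetic palette; real video
  requires recalibration, and the classifier thresholds are defaults to
  be audited against a laboratory's own normative data.
* The classifier reproduces the *sagittal* rules only; coronal and
  transverse deviations are invisible to a single lateral camera.
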