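---
title: "Modelling adaptive visual-field training: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adaptive visual-field training: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vftrain)
```

## Scope

`vftrain` models the computational core of a VR-goggles device for visual
restitution training (VRT): converting perimetric visual-field maps into
headset coordinates, adaptively relocating training stimuli from user
feedback, and evaluating placement precision with a blind-spot validation
protocol and a suite of detection statistics. It deliberately models *no*
rendering, optics beyond two scalar constants, Bluetooth input, or clinical
workflow, and it is agnostic about whether VRT itself works: the package
evaluates stimulus placement, not therapy.

## Coordinate model

Two displays are involved. The diagnostic perimeter shows stimuli on a
screen 400 mm from the eye; the headset shows a phone screen 44 mm from the
eye through +32.5 dpt lenses. Positions are exchanged in degrees of visual
angle: a millimetre offset $s$ at viewing distance $d$ subtends

$$\theta = 2\,\arctan\!\left(\frac{s}{2d}\right),$$

and one retinal degree spans 1.54 degrees in the headset's coordinate
system (a lens/display property), inside a stereoscopic field of view of
about 90°. `perimeter_to_headset()` therefore computes
$1.54 \cdot 2\arctan(s/800)$ per axis.

Design choices here:

* **Per-axis, isotropic conversion.** The source text for the conversion is
  typographically garbled; it is read as the subtended-angle formula above,
  which is fixed by the two stated viewing distances and the stated 1.54
  scale. Whether the original optics scale x and y identically is unknown;
  isotropy is assumed, and the scale is a profile parameter
  (`device_profile()`) rather than a constant.
* **Flat degree plane.** Distances (`angular_distance()`) are Euclidean in
  $(x,y)$ degrees, the standard static-perimetry convention at the ≤45°
  eccentricities reachable here; no spherical correction.
* **Errors, not clamps.** A conversion landing outside the headset's
  half-field raises a typed condition carrying the clipped coordinate; the
  caller decides whether clamping is meaningful. Silent clamping inside the
  geometry layer would corrupt round-tripping.
* **Eye-referenced coordinates.** Internally, positive x is always temporal.
  Left-eye maps are mirrored on read and un-mirrored on write, so one
  blind-spot model serves both eyes.

## Visual-field maps

A `visual_field` is a square grid (default pitch 0.75°, the sampling density
of the emulated eye-tracking perimeter) of categorical cell statuses:
`intact`, `defect` (absolute scotoma), `untested`. Graded (dB) sensitivity
and relative scotomata are out of scope.

* `classify_point()` is nearest-cell lookup, with half-way ties resolved
  toward the smaller x then y coordinate. Statuses are categories, so
  interpolation would be meaningless.
* `border_zone(width)` returns the transition cells (intact/defect cells
  with a 4-neighbour of the opposite status) dilated to the requested width.
  The suite verifies it against a brute-force neighbour scan on small grids.
* The default blind-spot model is a circle of radius 2.5° centred at
  (14.5°, −1°): anatomy gives a span of roughly 12° to 17° eccentricity,
  about 1° below the horizontal meridian, but a range, not a shape; the
  midpoint circle is the simplest shape consistent with it.
* `blind_spot_stimulus_sites()` defaults to placing all validation stimuli
  at the mapped scotoma's centroid cell, the stricter reading of "centred on
  the assessed blind-spot location"; a jittered mode (uniform within one
  pitch, rejection-sampled to stay inside the defect) is provided because
  the original wording is ambiguous between one coordinate and a scatter.

## The adaptive relocation rule

After every presentation the device learns one bit: clicked or not.
`relocate()` turns that into movement with step δ:

* detected → move δ along the straight line toward the *reference point*, a
  configured point in the central area of the defect (clamping onto it when
  closer than δ);
* missed → move δ along the same line extended away from the reference
  point, clamped radially at the field-of-view edge.

Two open points were resolved as follows:

* **Missed-stimulus direction.** The procedure is described both as "away
  from the reference point" and "toward the centre of the intact field",
  which differ off-axis. The away-from-reference reading is used because it
  makes detect and miss exact inverses, which is what yields a stable
  oscillation around the border. The configured `intact_anchor` is used only
  for the degenerate miss-on-reference-point case, where the away direction
  is undefined.
* **Step size δ.** Never stated for the original device. Default 0.5°:
  comparable to the perimeter's ~0.44° standard error of measurement (a
  finer step would claim precision the input maps do not have) and about one
  stimulus radius at the validation stimulus size. It is a config field and
  is recorded in every session log.
* **Per-presentation movement.** Movement is applied after each presentation
  (the feedback is tied to individual clicks), not per session block.

With a noiseless responder and a half-plane defect the rule converges to an
oscillation straddling the border with amplitude < δ; the acceptance suite
checks recovery of a border at x = 10° to within 0.5° after 200 feedback
cycles. That test drives the trainer with the *analytic* half-plane truth
(detected iff x ≤ 10) rather than a gridded map: grid quantisation at pitch
0.75° puts the effective classification boundary at x = 10.125°, which would
make the criterion measure the pitch, not the relocation rule.

Timing defaults mirror the device's training mode — 3° stimuli of nominally
1000 cd/m² for 750 ms, a fixed 2000 ms response window plus U(0, 1500) ms
extra break, fixation-cross colour changes at U(3000, 7000) ms — and exist
so that schedules and session logs are realistic; no wall-clock claims
depend on them. Sessions support `cumulative` persistence (relocated
coordinates carry into the next session) and `reset` (progress is logged
but initial coordinates are restored), matching the device's two documented
modes. Logs are JSON lines — header, append-only checkpoints, final record —
so a crashed session keeps its last checkpoint; `config_digest()` (canonical
JSON + MD5) is stored to expose silent parameter drift between sessions.

## The simulated observer

`respond()` models a participant with three knobs: isotropic Gaussian
fixation jitter (SD in degrees) added to each presentation, a lapse rate
(missing a visible stimulus), and a guess rate (clicking for an invisible
one). Detection is evaluated at the jittered stimulus *centre*; stimulus
extent is ignored, which is adequate while stimuli (0.33° in validation) are
small against the scotoma (≥5°), and the size stays in the responder
signature for future overlap models. All defaults are 0 — the ideal,
perfectly fixating observer — because the validation cohort was healthy,
instructed, and demonstrably compliant. The real data cannot distinguish
residual fixation error from guessing in the handful of blind-spot clicks,
so the simulator exposes both knobs rather than asserting a mechanism.

`rate_responder()` replays a subject known only through summary rates. Its
quota mode issues deterministic counts (`round(15·sen)` quiet blind-spot
trials, `round(85·spe)` clicked detectable trials), which is what makes
published per-subject tables reproducible bit-exactly; its stochastic mode
draws Bernoulli trials at the same rates. Quota counting is restricted to
the scored block — warm-up and buffer trials are answered (clicked) but
never consume quota — otherwise the 25 warm-up detectable trials would
corrupt the scored counts.

## The validation protocol

`build_trial_sequence()` produces 150 trials: 25 detectable warm-up, a
scored block that uniformly shuffles 15 blind-spot and 85 detectable
stimuli, 25 detectable buffer; warm-up and buffer are always classified
`excluded`. Detectable positions are drawn uniformly *without replacement*
from intact cells at least one pitch away from any intact/defect transition,
so every trial's ground-truth category is unambiguous — the original spec
says only "in the rest of the normal-sighted field", and the margin is this
implementation's way of keeping the simulated ground truth exact. Scored
classification is a pure function of (category, clicked): blind-spot
no-click → TN, blind-spot click → FP, detectable click → TP, detectable
no-click → FN.

## Detection metrics and their convention

The evaluation keeps the study's own — inverted — naming: the "positive"
event for SEN is the correct *non*-reaction to a blind-spot stimulus
(`sen = tn/(tn+fp)`), and SPE is the correct reaction rate
(`spe = tp/(tp+fn)`); PPV/NPV follow the same inversion. Normalising to
epidemiological convention would silently change every reported number, so
the package documents the inversion instead.

The random hit rate has no published formula; it is implemented as marginal
chance agreement,

$$\mathrm{RHR} = q\frac{D}{N} + (1-q)\frac{B}{N}, \qquad q = \frac{TP+FP}{N},$$

with $B$, $D$ the blind-spot and detectable totals. This was fixed by exact
agreement with every distinct published per-subject RHR value (.745, .752,
.738, .731, .703) and is guarded independently by a permutation oracle in
the test suite: RHR equals the mean hit rate over random re-pairings of the
subject's clicks with the trial categories. RATZ is the chance-corrected
gain $(HR - RHR)/(1 - RHR)$; it is negative for below-chance performance
and undefined at RHR = 1.

Two documented inconsistencies in the published table, surfaced by
`reproduce_validation()` rather than patched over:

* the published RATZ column does not follow the formula for 16 of 40
  subjects (rows with a single error type print 1.0 where the formula gives
  ≈ .96; three multi-error rows print values the formula cannot produce
  under any reading); the reproduction report flags these rows, and no test
  or acceptance target asserts the published RATZ column or its mean;
* the published summary-table PPV mean (.955) is not the mean of the
  published PPV column (.959); the column mean is asserted.

Display rounding is half-up to 3 decimals (`round_half_up()`), matching the
published tables; base R's round-half-to-even is never applied to displayed
metrics. Undefined metrics (zero denominators) are `NA` markers, never 0.

Split-half reliability splits each subject's scored trials odd/even within
category, counts blind-spot correct rejections per half, correlates the
halves across subjects, and applies Spearman–Brown $2r/(1+r)$. The odd/even
scheme is this implementation's choice; the original split is unstated. The
suite checks exact cases (identical halves → 1, zero variance → undefined)
and a generator self-consistency property: two independent replicate batches
of a Beta(20,1)-rate cohort must agree on mean corrected reliability within
Monte-Carlo error (scaled to 2 × 120 replicates to keep the suite fast).

## What the synthetic data do and do not establish

The generator states an idealised world: scotomata with exact parametric
boundaries, a perfectly regular grid, observers whose only failings are the
three knobs above, and blind-spot stimuli placed exactly at the mapped
centroid. Green tests therefore establish that the *algorithms* — geometry,
relocation, protocol bookkeeping, statistics — are correct in that world.
They do not establish anything about real retinae (blind spots are neither
circular nor sharp-edged), real fixation behaviour (saccades are not
isotropic Gaussian jitter; there is no reaction-time model and no learning
across sessions), or real optics (lens distortion is not modelled). The
reproduction of the published cohort results is exact *given* the published
per-subject rates; it re-derives the evaluation arithmetic, not the
behavioural data.

## Numerical notes

* Geometry round-trips are exact to 1e-9 over the in-field domain (pure
  `atan`/`tan` inverses).
* Confusion-matrix reconstruction uses `round()` on `15·sen` / `85·spe`;
  none of the published rates lands on a .5 tie, so half-to-even vs half-up
  is immaterial there.
* Schedules, sequences and simulated cohorts are deterministic per seed; a
  single seeded generator drives each session, and the seed is stored in the
  session log for replay.
* All grids in tests are ≤ 121×121; nothing needs compiled code.
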