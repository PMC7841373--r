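---
title: "Macro-micro segmentation of swimming sessions from IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macro-micro segmentation of swimming sessions from IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimseg)
```

## The problem and the model

A pool training session alternates rest and swimming bouts; each bout is a
sequence of 25-m laps separated by turns, and each lap passes five phases:
wall push-off, glide, strokes preparation (underwater kicking before the
first arm cycle), swimming, and turn. `swimseg` detects all of this from
6-axis inertial signals recorded on the sacrum (SA), head (HE), wrists
(RW/LW) and shanks (RS/LS), expressed in each segment's anatomical frame
(x anterior-posterior forward, y longitudinal up, z mediolateral right;
acceleration in g, angular velocity in deg/s).

The method is deliberately rule-based. Every detector composes a handful
of primitives: thresholding, extremum detection `EXT(s, TH)` (local peaks
or troughs compared with a threshold), sharp-change detection `SC(s, TH)`
(thresholding the derivative of a heavily low-passed signal), PCA,
single-sided spectra, empirical mode decomposition (EMD), and the
Hilbert-Huang instantaneous energy (squared analytic-signal amplitude).
Macro analysis finds approximate anchors -- bout start/end from the
posture change between upright rest and horizontal swimming, the
approximate turn from the dominant wall-contact peak -- and micro analysis
refines them into the five phase-begin events per lap, with
technique-specific and location-specific rules.

Assumptions inherited from the measurement protocol: in-water starts (no
dives), one technique per bout, sensors pre-synchronized, signals already
in the anatomical frame (or calibrated into it with
`estimate_calibration()` / `apply_calibration()`), moderate continuous
pace so that a lap contains at least two arm cycles and five kicks.

## Thresholds and tunable parameters

`threshold_set()` bundles every constant. The detection thresholds keep
their published defaults: wrist bout envelope `TH_BW` = 1.6 g, wrist turn
`TH_LW` = 200 deg/s, technique thresholds `TH_StyleSA` = 0.16 g,
`TH_StyleHE` = 0.2 g, `TH_StyleWmean` = 1.7 g, `TH_StyleWvar` = 0.01 g^2,
strokes-preparation gates `TH_SPSA` = 1 g (+ variability gate 0.06 g),
`TH_SPHE` = -0.5 g (prominence 0.1 g), `TH_SPRW` = -0.9 g,
`TH_SPRS` = 1.3 g, swimming-onset gates `TH_SSA_FCBaS` = 200 deg/s,
`TH_SSA_BrS` = 550 (deg/s)^2, `TH_SSA_BF` = 0.1 g, `TH_SHE_FC` = 5000 and
`TH_SHE_BFBrS` = 12000 (deg/s)^2, `TH_SHE_BaS` = 1000 (deg/s)^2,
`TH_T_RS` = 1.7 g; common noise-removal low-pass 10 Hz, order 2. The shank
lap threshold `TH_LS` is not stored: it is computed at run time as the
highest peak in a 2-s reference window placed at 30% of the bout span
(solidly inside first-lap swimming).

Parameters this implementation had to fix where the method description is
silent:

- **Sharp-change low-pass `sc_fc` = 0.15 Hz.** Posture changes are slow
  (below ~0.2 Hz) while stroke content starts at ~0.6 Hz with amplitudes
  up to 2 g on some channels; only a sub-stroke cutoff separates the two
  on the derivative. An absolute slope floor (`sc_min_slope` = 0.1 g/s)
  keeps noise-only sessions from producing bouts.
- **Search windows.** Push_B within [anchor - 1 s, anchor + 2 s] (from the
  anchor only for the first lap, whose anchor *is* the posture change);
  Glid_B within 3 s after Push_B; StPr_B within 8 s after Glid_B; Swim_B
  within 10 s after StPr_B; Turn_B within [anchor - 3 s, anchor + 1 s].
  These cover the plausible phase-duration ranges with margin and are all
  configurable.
- **Tie-breaking.** Where several extrema qualify, the first in time wins
  (the events are phase *beginnings*); the dominant-peak rules
  (push-off, turns) take the largest qualifying local maximum instead.
- **Technique window.** 6 s centered at 55% of the lap span -- at
  realistic phase durations this sits inside the swimming phase and covers
  at least two arm cycles (nominal 0.6 Hz) and five kicks (2.5 Hz).
  Spectral peaks for the butterfly/breaststroke split are searched in the
  stroke band 0.3-1.5 Hz so kick harmonics cannot masquerade as the
  stroke fundamental.
- **Turn types.** Tumble and simple turn variants exist for the Turn_B
  rules, but no inertial rule decides the type; by default front crawl and
  backstroke map to tumble, breaststroke and butterfly to simple
  (competition convention), overridable per bout.
- **Wrist technique rule order.** The published mean/variation thresholds
  target butterfly and front crawl "respectively" without an order; this
  implementation checks backstroke (PCA axis) first, then front crawl
  (variance of the low-passed |Acc| below `TH_StyleWvar`), then butterfly
  (mean above `TH_StyleWmean`), else breaststroke: a low-variation wrist
  signal is front crawl regardless of its mean.
- **Shank StPr_B.** After the first kick peak above `TH_SPRS`, the event
  is the adjacent crossing of 1 g on |Acc| *before* that peak (the kick
  onset, where |Acc| leaves the gravity baseline). Reading "the next
  sample" strictly forward would land half a kick cycle late, incompatible
  with the near-zero shank error this event is known for.
- **Wrist StPr_B.** `TH_SPRW` = -0.9 g is applied to |Acc| - 1 g: a norm
  is nonnegative, so the trough criterion must act on the deviation from
  the gravity baseline (near free-fall during the initial sweep).

## Onset rules: crossings, energies and EMD

Several Swim_B rules describe an *increase* (or decrease) of a quantity
past a threshold. They are implemented as the first genuine
below-to-above threshold crossing, not the first qualifying peak -- a peak
reading would add a fixed quarter-period delay to every onset. Three
numerical safeguards matter here:

- **Edge transients.** Zero-phase filtering uses odd-reflection padding,
  and the Hilbert/EMD-based rules analyze a window extended 2 s to the
  left of the search range, so decomposition edge artifacts can never be
  the "first crossing".
- **Sustained crossings.** Instantaneous-energy onsets must stay above the
  threshold for at least 1 s (80% of samples); ringing transients fail
  this, genuine envelope onsets pass. A search range that starts already
  above threshold counts as an onset only if sustained (this happens when
  a short strokes-preparation phase merges the onset with the window
  edge).
- **Mode selection.** EMD assigns one mode per time scale present, so "the
  second intrinsic mode" is ambiguous when the noise floor, a kick
  harmonic or a clean signal shifts the mode count. The detectors select
  the intrinsic mode with the largest spectral peak inside the stroke band
  (0.3-1.5 Hz) -- the second mode on typical noisy recordings -- which
  makes the rule invariant to mode-count shifts. EMD itself uses classic
  sifting with natural cubic-spline envelopes, mirror extension of the
  boundary extrema, and a Cauchy-type stopping criterion of 0.2; the
  residual is defined as input minus the sum of the modes, so the
  reconstruction identity is exact.

Degenerate inputs raise typed conditions: a window with no qualifying
extremum raises a `swimseg_detection_error` naming the event and location;
a segmentation whose events violate
Push_B < Glid_B < StPr_B < Swim_B < Turn_B raises a `swimseg_order_error`
with the offending pair. The pipeline records these per lap and continues.

## Anchoring across locations

Each invocation analyzes one location, with macro anchors by default from
the same location. The wrist is the exception: its bout detection keys on
the |Acc| envelope of arm cycling and therefore only starts at the first
strokes of the first lap, leaving the first push-off out of reach of
wrist-derived anchors. `run_full_analysis(..., anchor_location = "SA")`
anchors any location's micro detectors (and its technique label) on the
sacrum macro outputs -- the sacrum being the most reliable macro location
-- which is how the acceptance checks drive the wrist and shank detectors.

## What the simulator emulates -- and what it does not

`simulate_session()` builds piecewise-smooth templates (raised-cosine
pulses, derivative-of-Gaussian transients, amplitude-modulated sinusoids)
plus white noise, and stamps every event into the returned ground truth:

- posture-change level shifts on Acc_y at bout boundaries (upright 1 g to
  horizontal 0 g, anterior axis picking up the -1/+1 g gravity component
  for prone/supine techniques);
- a push-off transient whose defining feature sits exactly at Push_B (on
  the sacrum, an odd transient whose concavity change is at the event);
- glide quiescence with a small settling trough/peak at Glid_B;
- kick bursts from StPr_B (shank |Acc_x| beyond `TH_SPRS`, sacrum bursts
  beyond `TH_SPSA`, head dips beyond `TH_SPHE`, a wrist free-fall dip
  beyond `TH_SPRW`);
- arm-cycle oscillations from Swim_B with the entry trough before the
  first cycle peak on the wrists, rolling (front crawl/backstroke) or
  pitching (breaststroke/butterfly) angular velocity on trunk and head,
  and technique-specific wrist |Acc| levels straddling the style
  thresholds;
- turn complexes: a tuck transient at Turn_B followed by the wall-contact
  spike (the approximate-turn anchor) at 75% of the turn phase -- for
  backstroke the rotation peak coincides with Turn_B, which is why the
  approximate turn is passed through as Turn_B for that technique;
- per-lap phase durations drawn from truncated normal distributions
  (+/- 3 sd, floored at 20% of the mean so durations stay positive) with
  the validated study statistics as defaults; stroke frequency 0.6 Hz and
  kick frequency 2.5 Hz, consistent with the two-arm-cycle and five-kick
  window assumptions; rests of 30 s between bouts.

Two templates deserve a note. The breaststroke trunk pitching ramps up
over ~3 s: an energy threshold of 550 (deg/s)^2 against a full-amplitude
250 deg/s oscillation is only meaningful if the oscillation builds up --
with an abrupt onset the analytic envelope's leading skirt crosses such a
low threshold seconds early. And the shank carries a small kick-synchronous
pitch ripple through strokes preparation, without which a noise-free
window would contain an exactly-zero segment that destabilizes EMD.

What passing tests on these signals shows: the detectors implement their
rules correctly, the rules compose into a consistent segmentation, and the
thresholds have the margins the design claims. What it does not show:
performance on real swimmers. The templates have no inter-swimmer style
variability, no stroke-to-stroke variation, no drag or hydrodynamic
content, no sensor drift, and event signatures are placed exactly where
the rules look for them. Timing offsets that are intrinsic to a rule (the
quarter-kick delay of the sacrum StPr_B extremum, the crossing delay of
ramped swimming onsets) are visible in the synthetic errors; observer
disagreement and biomechanical delays between body segments are not.

## Validation metrics

`detection_scores()` matches events one-to-one in time order within a
tolerance (default 300 ms, larger than the worst inter-observer limits of
agreement reported for such annotations) and fixes true negatives at zero,
since the detectors only report occurrences: accuracy = (tp + tn)/total
with total = tp + fp + fn. Precision with zero detections is defined as 0;
with no truth and no detections all scores are vacuously 1.
`event_error_stats()` reports signed detected - truth errors in ms (sample
sd), `phase_duration_errors()` the absolute (ms) and relative (%) duration
errors, `bland_altman()` the bias and 95% limits of agreement.
`threshold_sensitivity()` re-runs an arbitrary pipeline with every numeric
threshold at +/-10% and tabulates metric deltas, recording pipeline
failures as row status rather than crashing. Timing errors respond
continuously (a few ms) to crossing-type thresholds and to sample
quantization, so the zero-delta property on clean data is stated -- and
tested -- for detection scores (sensitivity, precision, technique
accuracy, matched fractions), the metric type for which margins are
meaningful.

## Problem sizes used by the tests

Unit tests run single-bout sessions per technique; the end-to-end checks
use 20 seeded default sessions (4 bouts x 2 laps, all four techniques,
noise 0.05 g / 5 deg/s) for macro/micro recovery, a 200-lap session for
the duration-distribution check, 1000 random series for the extremum
oracle, and one noise-free session for the full threshold sweep. These
sizes keep the whole suite within a few minutes on one CPU while giving
every rule multiple independent exercises.

## Known limitations

- Dive starts are out of scope (in-water push-off starts only); replacing
  the push-off templates and rules with dive signatures would be the
  extension point.
- Mixed-technique laps (medley transitions mid-lap) and open-water
  swimming (no wall) are not supported.
- Wrist-anchored analysis cannot segment the first lap's pre-swimming
  phases; anchor on the sacrum instead.
- The energy-based swimming-onset rules carry an intrinsic delay that
  grows as the oscillation builds up gradually; the wrists are the
  reliable location for Swim_B.
- The simplified functional calibration (standing + squats/arm rotation)
  recovers axes up to the accuracy of the gravity and rotation-axis
  estimates; it is a stand-in for a full functional calibration protocol,
  and sessions recorded directly in the anatomical frame can skip it.
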