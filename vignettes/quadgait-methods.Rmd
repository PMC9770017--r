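---
title: "Methods: phase-dependent gait perturbation analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-dependent gait perturbation analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadgait)
```

## The measurement problem

When a cutaneous nerve of the foot dorsum (the superficial peroneal nerve)
is stimulated during quadrupedal treadmill walking, all four limbs adjust
their timing, trajectory and muscle activity, and the adjustment depends
strongly on where in the step cycle the stimulus arrives. Quantifying this
requires a chain of measurements: stance onsets and offsets per limb from
toe trajectories; per-limb step cycles; assignment of each stimulus to one
of four phases of the ipsilateral (stimulated) hindlimb cycle — mid-stance,
stance-to-swing transition, mid-swing, swing-to-stance transition; the
triad of control (pre-stimulus), stimulated and first post-stimulus cycles
for every limb; spatiotemporal metrics (cycle/stance/swing durations,
support-period decomposition, step and stride lengths, joint angles,
maximum marker heights); EMG burst duration and normalized mean amplitude;
and finally per-phase repeated-measures statistics across animals.

`quadgait` implements that chain as composable functions over tidy tables,
plus a synthetic-session generator that produces marker, EMG and stimulus
data with *known* injected effects, so every stage of the pipeline can be
validated by parameter recovery.

## Conventions

* Coordinates are SI: x in meters along the direction of travel, y in
  meters above the belt surface (y = 0 on the belt). Real tracking output
  must be calibrated to meters before use.
* Kinematic event times live on the video frame grid (1/60 s by default);
  EMG events on the EMG grid (1/5000 s).
* Limbs are named by role relative to the stimulated hindlimb:
  ipsilateral and contralateral hindlimbs, homolateral and diagonal
  forelimbs.

## Event detection

The original scoring of paw contact was visual; an explicit algorithm is
required for reproducibility. Contact is declared when toe height is below
a threshold (default 5 mm) for at least 3 consecutive frames; the stance
onset is the first frame of each such run that follows a non-contact
frame. Stance offset follows the operational definition of the most caudal
toe displacement: the minimum of toe x within `[onset, next onset)`.
Because early swing advances the toe very slowly, tracking noise drags the
raw argmin into the swing by an amount that grows with swing duration —
a bias that would distort measured swing-duration ratios. The estimator
therefore returns the *earliest* sample statistically indistinguishable
from the minimum, with the noise scale estimated from the residuals of a
line fitted to the stance portion of the trajectory (belt-driven stance
motion is exactly linear, so this scale is zero for noiseless data and the
raw minimum is returned unchanged).

Cycle duration is the interval between successive stance onsets, stance
duration from onset to offset, and swing duration is cycle minus stance —
an identity that holds exactly by construction.

## Phase windows and triads

The published analysis states four phases and an exclusion rule but not
numeric window bounds. The defaults are symmetric and disjoint: mid-stance
and mid-swing are the central 40% of their sub-phase (fraction 0.3–0.7),
and the transitions are ±10% bands around stance offset and stance onset.
All bounds are configuration keys (`phase_windows()`), so sensitivity to
the choice can be tested. The stance/swing split uses the stimulated
cycle's own measured duty factor, not a session average, because phase is
defined relative to the perturbed cycle.

For each limb, the stimulated cycle is the limb's own cycle containing the
stimulus onset; control and post are its immediate neighbours. Whether
non-ipsilateral limbs should instead be aligned by time is not specified
in the source protocol; per-limb containment is used and recorded as a
convention. A triad is invalid if the phase is excluded, any limb lacks
three consecutive complete cycles, or another stimulus falls inside the
ipsilateral triad span.

## Support periods

A support period is a maximal interval with a constant set of limbs in
stance. Decomposition collects all stance-interval endpoints inside one
ipsilateral cycle window, labels each sub-interval by midpoint membership
and merges equal neighbours. Canonical lateral-sequence walking (duty 0.65,
limb phase offsets 0 / 0.5 / 0.25 / 0.75) produces exactly eight periods
per cycle, alternating triple and double support; at higher duty factors a
diagonal double support is replaced by quadrupedal support, giving nine
categories in total (four doubles, four triples, quad). Category durations
recurring within one window are summed. Configurations outside the walking
taxonomy (fewer than two limbs, girdle pairs) are labeled `other` and
flagged. The decomposition is verified against a brute-force dense-grid
labeling oracle on random schedules.

## Spatial metrics

Step length is the absolute horizontal separation of homologous toes at
the leading limb's contact frame (magnitudes only, matching how such
values are reported). Stride length on a treadmill is the horizontal
stance displacement plus belt speed times swing duration; on unperturbed
noiseless cycles this equals belt speed times cycle duration to numerical
precision (treadmill conservation), which the tests assert at 1e-6 m.

Joint angles (hip: iliac crest–trochanter–knee; knee:
trochanter–knee–malleolus; ankle: knee–malleolus–MTP) are included angles
at the vertex in [0°, 180°], flexion decreasing; they are invariant to
rigid motions of the marker set. Excursion is max − min over the cycle.

Maximum marker heights are cycle maxima of y. Per-frame tracking jitter
biases a raw maximum upward, and the bias is proportionally worst for the
low control-cycle toe apex, deflating stimulated/control height ratios.
Heights are therefore extracted from a zero-phase low-pass filtered series
(default 12 Hz at 60 frames/s); the multiplicative attenuation of the
filter cancels in ratios, while the additive noise bias shrinks with the
noise power. For noiseless data `height_smooth_hz = NULL` reproduces the
exact construction apex.

## EMG analysis

Channels are band-pass filtered (zero-phase Butterworth, 30–1000 Hz,
effective order 4), full-wave rectified, and smoothed into an envelope
(zero-phase low-pass, 50 Hz default). Burst scoring — originally visual —
is an explicit double-threshold detector: a burst opens after ≥ 20 ms above
baseline median + 3·MAD and closes after ≥ 20 ms below median + 1.5·MAD.
Baseline statistics are seeded from the lower quartile of the envelope
(extensor bursts can occupy most of a trial at duty 0.65, which would drag
a global median into the burst level) and re-estimated twice excluding
detected bursts. One burst — the longest — is retained per limb cycle,
matching one-burst-per-cycle reporting; a window whose envelope never
drops below threshold yields a full-window burst with a quality flag.

Mean amplitude integrates the rectified band-passed signal (not the
smoothed envelope — the choice is recorded here since the source is
ambiguous) over the burst divided by burst duration; amplitudes are
normalized to the same triad's control-cycle mean (control ≡ 100%), which
makes them invariant to channel gain.

## Statistics

For each phase and variable, each animal contributes the mean over its
valid triads per cycle role (control/stimulated/post). With at least two
animals, the three cycles are compared with the Friedman
repeated-measures rank test (average ranks and tie correction; `df = 2`),
with Shapiro–Wilk normality reported per cycle but never gating the
nonparametric test. "Bonferroni post hoc" is operationalized as pairwise
Wilcoxon signed-rank tests of stimulated-vs-control and post-vs-control
with raw p doubled (two reported comparisons) and capped at 1; the exact
original post hoc statistic is unstated, and both the statistic and the
number of corrected comparisons are configurable. Percent change is the
mean over animals of each animal's 100·(value − control)/control — the
per-animal-ratio convention matching the repeated-measures design — with
its SD.

A degenerate matrix with all columns identical returns a Friedman
statistic of 0 and p = 1.

## The synthetic generator

The generator is a forward model of the study conditions: seven animals
walking at 0.3–0.5 m/s (default 0.4), video at 60 frames/s, EMG at
5000 Hz, stimulus trains of 25 × 0.2 ms pulses at 300 Hz at 1.2× motor
threshold delivered every five to six cycles, 5–20 stimuli per phase. The
train descriptor, including its stated nominal 88 ms duration, is stored
verbatim and never derived from pulse count and frequency.

**Footfall schedules.** Each limb steps with the animal's cycle period
(log-normal across animals, σ = 0.05) and duty factor 0.65 at the
canonical phase offsets. Timing jitter (total SD 8 ms per event)
decomposes into a rhythm component shared by all events of a cycle
(variance share 0.85, representing cadence/speed fluctuation) plus
independent per-event noise: cycle durations fluctuate realistically while
intra-cycle inter-limb intervals stay tight, as in steady walking. Duty is
held at 0.65 for every animal because the planted support-period effects
are expressed relative to the canonical phasing, whose double-support gaps
scale with (offset − duty); per-animal duty variation would make the
largest planted support targets geometrically unrepresentable within the
swing envelope. Event times are snapped to the video frame grid, the
package's event-time convention.

**Markers.** Toe trajectories are closed-form: stance moves backward at
belt speed from the anterior extreme position, swing advances by a
minimum-jerk profile while toe height follows a flat-topped bell (steep
take-off/landing, apex plateau, default 3 cm) — the plateau makes the
sampled maximum equal the apex exactly, and the steep landing keeps
contact detection unbiased by apex height. Proximal markers come from a
sagittal kinematic chain driven by prescribed joint-angle waveforms,
constructed so that the measured included angles equal the prescribed
waveforms exactly (the angle-recovery oracle asserts 1e-6°). One body-size
factor scales segment lengths and girdle heights together so belt
clearance is size-invariant. Gaussian marker jitter (default σ = 1 mm,
about one pixel at the stated camera resolution and field of view) is
added last.

**EMG.** Each channel is a 30–1000 Hz noise carrier normalized to unit
mean rectified amplitude, multiplied by a phase-gated envelope (flexors
SRT/BFP/ST/BB in swing, extensors BFA/VL/LG/SOL/TRI/ECU in stance, 20 ms
raised-cosine edges), plus an independent baseline floor (5% of the mean
burst amplitude).

**Perturbation.** Stimulated cycles are regenerated from modified
schedule parameters rather than by warping signals, so ground truth is
exact. Temporal multipliers move the limb's stance offset and next onset;
the following cycle absorbs the shift, so later cycles stay phase-locked
(a mid-swing stance-offset move is formally acausal relative to the
stimulus, which is irrelevant to measurement). Support-period multipliers
are expressed relative to the animal's nominal control-cycle geometry and
realized by moving the event that terminates the target period; any
member-limb offset that the extension would overrun is pushed several
frames past the new boundary so detection noise cannot split the period.
When a target would overrun the cycle window it is capped at the window
edge and the realized multiplier recorded in the ground-truth table. Toe
apex gains, per-touchdown step-length multipliers (solved against the
trailing limb's closed-form position), joint flexion deltas and per-burst
EMG gains annotate the affected cycles for the synthesizers. The shipped
`phase_effects.yaml` carries the reference effect sizes used for
parameter-recovery validation.

Large realized perturbations have mechanical side effects the profiles do
not list — e.g. the stance-to-swing support extension shortens the
homolateral swing substantially — which is expected: limb timing is
coupled, and only the profiled targets are validated.

## What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: periodic
limb phasing with realistic cycle variability, inter-animal random
effects, phase-targeted stimuli with placement jitter, frame-grid
measurement granularity, tracking noise and EMG baseline noise. It does
not attempt musculoskeletal dynamics, ground-reaction forces, 3-D
kinematics, skin-marker slippage, tracking outliers or stimulus artifacts.
Passing recovery tests therefore shows the *pipeline* is unbiased and
correctly calibrated under these conditions — not that every property of
real video and EMG is handled.

## Problem sizes and numerical choices

Validation runs use seven animals with 10 stimuli per phase for temporal
and EMG recovery and 20 per phase (the upper end of the study's 5–20
range) for support-period and spatial recovery, where the smaller
denominators make percent changes noisier. The type-I calibration runs
2000 effect-free sessions (7 animals × 10 sham triads) at the
schedule level — schedules, triad logic and the Friedman test are the
real pipeline components; marker synthesis and detection, validated
separately by the zero-noise and recovery suites, are bypassed per
replicate. Tolerances: durations are compared to ground truth at one
video frame; treadmill conservation at 1e-6 m; angle recovery at 1e-6°;
the support decomposition must match the brute-force oracle exactly up to
its grid resolution.

## Known limitations

* Marker coordinates must arrive calibrated in meters; no pixel
  calibration is provided.
* Knee position is measured directly from the knee marker; with real
  skin-marker data, triangulation from segment lengths would be needed to
  combat skin slippage.
* The burst detector replaces expert visual scoring; its output format
  admits manual-override tables, but no override reader is shipped.
* Phase classification is post hoc from kinematic cycles, not from the
  online extensor-burst trigger used during acquisition.
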