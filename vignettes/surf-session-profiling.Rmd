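---
title: "Profiling surf sessions from smartphone sensors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling surf sessions from smartphone sensors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfprofiler)
```

This vignette is the package's own account of the science behind it: the
models each stage implements, the assumptions they rest on, the tunable
parameters and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Problem and frame conventions

A surfer carries a smartphone between the shoulder blades, logging inertial
sensors at 50-100 Hz and GPS at 1 Hz. The task is to segment the session
into seven activities: wave riding, paddling, sprint paddling, duck diving,
laying still, sitting, and a rejection class `other` for transitions that
match no known pattern. The sensor frame is fixed as X = mediolateral (short
phone axis), Y = cranio-caudal (long axis; gravity ≈ +Y when the torso is
upright), Z = normal to the phone face (gravity ≈ +Z when prone). This is
the only assignment consistent with sitting/laying being read off the Y/Z
gravity components while paddling rolls the X component, and it is
configurable at the orientation-fusion layer should a device be mounted
differently.

Streams recorded at ~100 Hz are decimated by 2 (plain under-sampling, no
anti-alias filter — the signals of interest live well below 5 Hz and the
frequency stage tolerates uneven sampling, so pure decimation is both faster
and honest about what it does). Timestamps are seconds from session start;
converters from epoch milliseconds are provided. Uneven sampling is
tolerated throughout rather than resampled.

## Orientation fusion

`fuse_stream()` implements a gradient-descent quaternion filter of the
Madgwick AHRS family. The state is a unit quaternion $q$ rotating
sensor-frame vectors into North-East-Down. Each sample applies

$$ q_{k+1} = \mathrm{normalize}\!\left( q_k \otimes
   \exp\!\left(\tfrac{\omega\,\Delta t}{2}\right)
   \;-\; \beta\,\Delta t\, \frac{\nabla f}{\lVert \nabla f \rVert} \right), $$

where $f(q)$ stacks the residuals between the predicted and measured
gravity direction and the predicted and measured magnetic field (with the
Earth-field reference re-derived from the current estimate, which removes
sensitivity to the absolute declination). Two deliberate numerical choices:

* **Exact gyro integration.** The gyroscope term uses the quaternion
  exponential rather than the customary first-order Euler step. For constant
  body rate the integrated track then coincides with the closed-form
  axis-angle solution to machine precision, which makes the $\beta = 0$
  dead-reckoning limit exactly testable; for varying rates it is strictly
  more accurate at identical cost. The descent correction remains a
  first-order step, as in the standard filter.
* **Gradient linearised at the pre-update state**, so a measurement already
  consistent with the estimate produces a zero correction: a consistent
  stationary input is a fixed point of the filter.

The gain $\beta$ (dimensionless) weighs measurement corrections against
gyro propagation. The default 0.1 is standard practice for this filter
class at 50 Hz with smartphone-grade sensors; the filter starts at the
identity quaternion and runs a 2 s warm-up at $\beta_{init} = 2.5$ so the
estimate snaps onto the measured gravity/magnetic directions before
settling. Samples with a zero-norm accelerometer or magnetometer reading
fall back to gyro-only propagation and are flagged — magnetic disturbance
near the shore is plausible and should degrade gracefully rather than
corrupt the estimate.

Gravity in the sensor frame is the NED Down vector rotated through $q$ and
scaled to $g_0$ (9.81 m/s², configurable); linear acceleration is the exact
residual `accel − gravity`, so the decomposition reconstructs the
measurement by construction.

## Windowing and features

Decisions are made on 1 s windows hopped every 0.5 s (half-open intervals
$[t_0, t_0+1)$), i.e. a new label every half second from the previous
second of data — long enough to smooth chop-induced transients, short
enough for near-real-time use. Trailing windows keeping at least half their
nominal coverage are kept (flagged partial), shorter tails dropped. Each
window carries mean gravity per axis and the YZ linear-acceleration
magnitude $\sqrt{a_y^2+a_z^2}$ aggregated by max (mean is also exposed);
max is the default because the wave rules key on acceleration *peaks*. GPS
speed attaches by nearest fix to the window centre with a ±2 s staleness
cap and earlier-fix tie-break: 1 Hz fixes against 0.5 s decisions force a
hold policy, and a 2 s cap bounds how stale a held speed can be. Windows
with no fix in range carry a missing-speed sentinel that no wave rule can
fire on.

## Wave detection

Three rules define a candidate ride: (1) take-off only from a laying-family
stance (`paddle`, `sprint_paddle`, `dive`, `lay`) or a transition
(`other`) — never from sitting or from inside another wave; (2) take-off
requires speed at or above `v_takeoff` together with YZ acceleration at or
above `a_sustain`; (3) riding continues while speed stays at or above
`v_sustain` and acceleration at or above `a_sustain`. The "fast increase of
speed" at take-off is operationalised as a level crossing of `v_takeoff`
between consecutive windows rather than a derivative estimate, because
differentiating 1 Hz GPS speed is noise-dominated. Closed candidates
separated by at most one window merge, tolerating single-window GPS
dropouts.

Post-processing then (a) refines the end-ride moment to the **last
per-sample (50 Hz) YZ linear-acceleration measurement above 90 % of the
mean in-wave acceleration** — refinement operates on raw samples, not
window aggregates, and can only shorten a ride; (b) validates the refined
candidate: duration strictly greater than 3 s, with acceleration and speed
peaks meeting the same `a_sustain`/`v_takeoff` thresholds (one threshold
set serves both detection and validation; nothing in the rule structure
suggests a second set, and sharing keeps the tuning surface minimal);
(c) extracts statistics: duration, mean of the GPS speeds inside the ride
(nearest-fix fallback, flagged), and peak per-sample YZ acceleration.
Events are only emitted after their end has been seen, one hop later at
most.

The numeric defaults `v_takeoff` = 2.5 m/s, `v_sustain` = 2.0 m/s,
`a_sustain` = 3.0 m/s² are empirical values re-derived against the
synthetic generator, sitting roughly midway between the strongest
paddling-family signals the generator produces (sprint bursts ≈ 2.4 m/s²,
sprint speed ≈ 1.8 m/s) and the weakest wave signals (sustained ride
acceleration ≳ 3.5 m/s², ride speeds ≥ 4 m/s); all are config-exposed and
should be re-tuned for other devices or mounting points.

## Stances

Non-wave windows classify by which axis carries gravity: mean |gravity-Y| ≥
8.8 m/s² → `sit`, else mean |gravity-Z| ≥ 8.8 → `lay`, else `other`.
The 8.8 m/s² cut fixes "nearly 9.8" as within ~26° of axis alignment; the
constructor refuses thresholds at or below $g_0/\sqrt2$, which would let
both axes qualify at once. Window means rather than instantaneous samples
are thresholded for robustness to chop; absolute values let a face-up
orientation still read as laying. The decision uses gravity features only,
so it is invariant to any linear-acceleration content.

## Laying activities

Runs of consecutive `lay` windows form laying periods. The
**frequency-domain classifier** subdivides each period into 2 s sub-windows
with 1 s overlap — at ~0.5 Hz per full (left+right) stroke cycle, 2 s is
the shortest window guaranteed to contain one — and computes Lomb-Scargle
periodograms of the gravity X and Y signals on 101 evenly spaced
frequencies over [0, 5] Hz (0.05 Hz spacing; the 0 Hz bin is excluded from
peak search after mean-centring). The Lomb-Scargle estimator is used
because the raw streams are not exactly evenly sampled and interpolation
would colour the spectrum.

`lomb_scargle()` itself returns the classical variance-normalised
periodogram (white noise → expected power ≈ 1 per frequency; a pure
sinusoid → ≈ n/2 at its frequency). For classification,
`laying_spectrogram()` rescales powers to absolute amplitude units,
$2\,\mathrm{var}(y)\,P/n$ ≈ half the squared amplitude of the matching
sinusoid. The rescaling matters: the orientation filter low-passes sensor
noise into a faint smooth wobble of the gravity estimate, and under pure
variance normalisation that wobble is spectrally indistinguishable from
genuine paddling — only its absolute amplitude gives it away. Within-window
power *ratios* (the dive and paddle comparisons below) are unaffected by
the common scale.

Each sub-window classifies by a fixed decision tree:

1. **dive** if the gravity-Y low-frequency peak (≤ 1 Hz) exceeds the
   gravity-X peak and the power floor — the spectral footprint of the
   downward dip while pushing the board under a wave;
2. **sprint paddle** if gravity-X dominates (X peak > Y peak and > floor)
   with its peak at ≥ 0.8 Hz and sub-window YZ acceleration ≥ 2.0 m/s² —
   faster strokes push the peak beyond the regular band, and the
   acceleration gate captures the surge felt at a wave's cusp;
3. **paddle** if gravity-X dominates with its peak at ≤ 1 Hz;
4. **lay** otherwise (the default class).

The sprint test precedes the paddle-band test so that stroke rates above
1 Hz remain classifiable — an upgrade path rather than a separate class
boundary. The "low frequencies" band for dives mirrors the paddle band
(≤ 1 Hz); the power floor `min_peak_power` defaults to 0.15 m²/s⁴ (an
oscillation of ~0.55 m/s² amplitude), an order of magnitude above
filter-residual wobble and well below real paddling. Isolated labels are
then smoothed: a sub-window disagreeing with two agreeing neighbours takes
their label, an endpoint run of length one takes its neighbour's; passes
repeat to a fixed point, which makes smoothing idempotent by construction.

The **legacy time-domain variant** assigns the whole period one binary
label: maxima/minima of gravity-X (peak detection via `pracma::findpeaks`,
minimum amplitude 0.5 m/s²) must number at least 3 with inter-peak
intervals of coefficient of variation ≤ 0.5; gaps longer than twice the
median interval — isolated pauses — are excluded from the regularity
measure. "Sufficiently periodic" is not a quantified notion; CV of
inter-peak intervals is the simplest scale-free regularity statistic, and
the gap exclusion reproduces the variant's documented failure mode: a
paddle-still-paddle period collapses to a single label (usually paddle),
whereas the frequency variant emits separate runs. The package keeps both
precisely so this structural difference is demonstrable
(`classify_laying_td()` vs `classify_laying_freq()`).

## Evaluation

`sample_confusion()` scores one true/predicted pair per whole second whose
midpoint lies inside a truth segment; seconds outside any segment are
excluded (ground truth never contains `other`). The predicted label at a
second is taken from the window whose centre is nearest the second's
midpoint (earlier window on ties) — with 0.5 s hops some mapping from
decisions to 1 s samples must be fixed, and nearest-centre is the least
biased one. Rows of the confusion matrix conserve annotated seconds; row
percentages sum to 100.

`wave_event_metrics()` matches predicted to annotated events greedily by
greatest temporal overlap, requiring overlap of at least half the shorter
event (configurable), each event matching at most once. Precision counts
matched detections among detections inside annotated coverage — detections
in uncovered time are tallied separately rather than judged — and recall
counts matched truth events. With zero evaluable detections precision is
reported as 1 with an explicit zero-support flag.

## The synthetic generator

`generate_session()` renders an activity script into sensor streams by
synthesising the orientation trajectory first and deriving ideal readings
from it — the exact inverse of the fusion model — then adding white
Gaussian noise. Consequently generated accelerometer = generated gravity +
generated linear acceleration *exactly*, and recovery tests of the fusion
stage are well-posed. Morphology per activity: paddling rolls gravity-X
sinusoidally at 0.5 Hz (~2 m/s² amplitude) with a gravity-Y ripple at twice
the stroke rate and roughly 40 % of the amplitude; sprint paddling runs at
1 Hz with YZ bursts peaking ≈ 2.4 m/s²; dives are a ~2 s gravity-Y dip of
~3 m/s²; sitting puts gravity on +Y, laying on +Z; waves ramp GPS speed to
a per-wave peak drawn from U(4, 8) m/s with sustained YZ acceleration
≳ 3.5 m/s². Gyroscope readings are the exact body rates of the orientation
trajectory; the magnetometer sees a 45 µT field at 60° inclination.
Segment transitions are 1 s smooth interpolations belonging to the
following segment, so truth tracks tile the session without gaps and never
contain `other`.

Default noise levels — accel σ = 0.15 m/s², gyro σ = 0.01 rad/s, mag
σ = 0.5 µT, GPS speed σ = 0.3 m/s — are plausible smartphone-grade values.
`random_script()` draws cycles (paddle out with an occasional dive, sit,
sprint, wave, recovery lay) whose expected composition matches the typical
session budget of roughly half paddling, ~42 % stationary and ~4 % wave
riding, with wave durations ~N(8.97 s, 2 s) truncated to [4.5, 15] s.

What the generator deliberately does **not** emulate: sea-state chop and
broadband body motion, GPS multipath and speed bias under acceleration,
magnetic disturbances, board physics, or ambiguous annotation boundaries.
Passing the end-to-end recovery tests therefore shows the pipeline is
internally consistent — each stage recovers what the signal model encodes —
not that field performance on real recordings would match; thresholds
re-derived here would need re-tuning on field data.

## Problem sizes and determinism

The recovery tests and the acceptance script use 20 seeded 30-minute
sessions at the default configuration — enough for ~150 wave events and
36 000 annotated seconds, which stabilises the pooled rates while keeping a
full run in the low minutes on one core. Every random draw flows from the
session seed; profiling itself is deterministic, so identical inputs and
configuration give byte-identical outputs.

## Known limitations

* Thresholds are tuned to the generator's study conditions; real devices,
  mounts and sea states will need re-tuning (all values are config-exposed).
* Sprint paddle is intrinsically boundary-ambiguous with both paddling and
  the wave take-off; its per-second recall is the weakest of the seven
  classes in the shipped reports.
* The stance rule assumes the phone stays roughly aligned with the torso; a
  loose mount breaks the axis-gravity reading.
* No sequential model links consecutive activities beyond the wave take-off
  gate; a session grammar could resolve some transition confusions.
* In-wave manoeuvre detection and stroke-by-stroke paddle counting are out
  of scope.
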