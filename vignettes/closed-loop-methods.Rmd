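---
title: "Closed-loop cutaneous stimulation at a desk: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop cutaneous stimulation at a desk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimloop)
```

# What this package models

Closed-loop cutaneous stimulation rigs track a freely moving mouse with a
camera, estimate body-part keypoints in real time, and steer a laser to a
chosen keypoint through a pair of galvanometer mirrors whenever
user-defined conditions are met. `stimloop` re-implements every
computational stage of such a rig — calibration, trigger logic, random-access
multi-animal scheduling, a maze task engine, and the post-hoc behavioral
analyses — against a *virtual rig*: a gait-realistic keypoint simulator, a
frame renderer, a distorted forward optics model, and latency models stand
in for animals and hardware, so the whole loop runs and is testable on a
laptop.

All geometry uses 0-based pixel coordinates, origin top-left, x rightward,
y downward; physical units come only from the chessboard scale factor
(0.45 mm/pixel by default). Timestamps are seconds with a frame interval
of exactly 1/fps; timing jitter belongs to the virtual rig's latency
models, not the timebase.

# The virtual rig

## Gait simulator

`simulate_gait()` walks a virtual mouse along a circular path at constant
body speed. The tail base and snout advance continuously; each hind paw
alternates between a *stance* (anchored to the platform) and a *swing*
that linearly translates it to its next anchor, with left and right paws
half a cycle out of phase. Default phase durations are stance
350 ± 44 ms and swing 100 ± 1 ms; drawn durations are rescaled so the
sample realizes those moments exactly, because the sessions *are* the
stated study conditions rather than draws around them.

One subtlety is deliberate: the stated durations are *measurements* under
the displacement-threshold convention used by `gait_phases()` (a frame is
static when the adjacent displacement corresponds to < 20 px/s). A frame
interval straddling a phase boundary is still labeled static while its
swing overlap is below `threshold / v_swing`, which inflates measured
stance by `2 * dt * threshold / v_swing` (about 2 ms at the default body
speed). The generator therefore shifts its latent schedule by this
analytic slack so that the *measured* durations realize the stated ones.
The same reasoning gives the swing trajectory its shape-agnostic
treatment: only the timing statistics are contractual; linear
interpolation between anchors is a convenience.

Speed-category presets (`gait_preset()`) shorten stance as body speed
rises (20 s, 2.2 s, 383 ms, 150 ms for stationary/low/medium/high at 6,
70, 170, 300 px/s), which reproduces the qualitative fall of the
static-frame fraction from ~0.997 to ~0.59 across categories. Keypoint
likelihood is a constant 0.95; an optional dropout fraction (default 0)
drops frames to 0.3 to exercise the likelihood-threshold path.

## Optics and latency

`optics_model()` maps steering voltages to a spot pixel through a linear
gain per axis plus a smooth bivariate polynomial distortion (bounded below
5% of the platform width — the construction rescales the realized field,
not the coefficients) and optional sub-pixel spot observation noise.
`random_optics()` draws reproducible degree-2 distortions. Delays follow
the measured closed-loop characterization: processing 84 ± 12 ms and
actuation 3.3 ± 0.5 ms, truncated at zero and summed per event
(≈87 ms end to end).

## Synthetic trials

Latency-trial generators (`simulate_me_trials()`, `simulate_pose_trials()`)
draw response onsets from truncated normals whose *location* is solved
numerically so the truncated distribution's mean equals the target
(4.74 s within 1.5–9.8 s; 0.81 s within 0–10 s) — a truncated normal's
mean is not its location parameter — and then remove residual sampling
error of the sample mean. Motion-energy trials include the single-frame
stimulus flash artifact at the true onset (which the analysis uses for
onset refinement) and sub-threshold baseline noise.

`generate_state_trials()` emits two-state tail-base trajectories
(4 s, stimulus at the midpoint): per-state speeds 90.8 ± 28.3 and
32.5 ± 13.9 mm/s, heading coherences 0.9 ± 0.1 and 0.1 ± 0.1, and a
0.681 fast-state weight realized deterministically as `round(weight * n)`
trials (116 trials reproduce the 79/37 composition). Headings follow
wrapped-normal jitter; because coherence is defined through the analysis
pipeline (10-frame circular smoothing), the map from target R to jitter SD
is calibrated once by internal simulation under a fixed internal seed,
mirroring the trial window geometry, and cached. The post-stimulation
regime (fast trials slow to half speed and lose coherence; slow trials
gain coherence) begins 0.1 s after the stimulus — a withdrawal-scale
response-onset delay that also keeps the post regime out of the smoothed
pre-window.

# Calibration

A 100 × 100 voltage raster (10,000 points) is realized through the optics
and each commanded voltage paired with its detected spot
(intensity-weighted centroid of the connected region around the global
maximum; ties resolve to the brighter component, then smaller (y, x)).
`fit_map()` fits each voltage axis as a polynomial surface in the spot
pixel by ordinary least squares on the full bivariate monomial basis,
domain-normalized to [-1, 1] for conditioning. Degree 3 is the default:
it is the lowest degree that drives held-out error on a degree-2-distorted
simulated rig well below the pixel-scale QC tolerance (1.2 px), and
training error is non-increasing in degree. No regularization — the raster
is dense and well conditioned, and rank deficiency is refused explicitly.
The direction of the fit (voltages as functions of pixels, rather than
inverting a pixel-of-voltage fit) is a deliberate choice: it is the lookup
the control loop needs.

The stored residual MAE is converted from voltage to pixel units through
the local finite-difference gain at the domain centre (an approximation;
the volt-unit residual is stored alongside). `evaluate_map()` closes the
loop — predict voltages for a target pixel, realize them through the
noise-free optics, measure the Euclidean miss — and raises a remap
recommendation when the error exceeds the weekly platform-drift scale
(1.94 mm).

# The control loop

The stillness trigger fires when the target keypoint's x and y population
standard deviations are both strictly below `v` (default 1 px) and every
frame's likelihood strictly exceeds `l` (default 0.8) throughout `t`
(default 2 s). The strict inequalities and the interpretation of the
dispersion bound as a standard deviation follow the protocol definition;
the window is `round(t * fps)` frames. Sessions evaluate the trigger on
the trailing window each frame, enforce a refractory interval (strictly
greater-than), sample per-event delays, and target the keypoint *from the
trigger frame* — the loop cannot see the future, so accuracy degrades with
delay and with speed, which the tests assert as monotone properties.
After each stimulus the window re-arms from the fire frame, preventing one
long still epoch from yielding a burst.

Adjudication is geometric: a hit lands within the paw footprint radius
(5 px ≈ 2.3 mm, roughly half a hind-paw width) of the intended paw at the
fire frame; a confusion lands instead within another paw's footprint.
Speed categories for the accuracy table use the tail-base speed with a
10-frame rolling mean and lower-inclusive bins [0,20), [20,120),
[120,220), [220,∞) px/s. The speed-category characterization uses a
likelihood-only trigger (unbounded `v`, one-frame `t`, 500 ms refractory);
the stillness rule is the open-arena protocol preset.

# Multi-chamber scheduling and the maze

Per-chamber motion energy is the summed absolute frame difference inside
the chamber ROI with values strictly below 10 intensity units zeroed. A
chamber is idle when every transition in the trailing 2 s stays strictly
below 30,000 summed units — the per-transition reading of the idle rule;
the windowed-sum alternative is noted here and not used. These thresholds
are 8-bit / 230 × 230 px presets stored in config; other bit depths or ROI
areas need re-tuning. Idle chambers outside their 10 s scheduler
refractory are selected uniformly at random from a seeded stream; protocol
presets (e.g. ≥ 1 min per mouse) layer on top.

The maze engine encodes the one-way-door topology as a directed graph over
seven rectangular zones; zone membership uses the snout (the poke sensor
is nose-based) while trajectory analytics use the tail base. Transitions
not in the graph are logged as tracking glitches and ignored. A reward
port re-arms only when its timeout (drawn once per session, uniform
45–60 s per port — per-session for reproducibility) has elapsed *and* the
mouse has exited the reward chamber since the last reward. Corridor
stimulation fires on entry and then at the corridor's paired frequency
(5 Hz left / 1 Hz right by default) until exit. Euler-tour condition
ordering traverses every ordered pair of distinct conditions exactly once
(length n(n−1)+1, seeded tie-breaks, no self-pairs — the self-pair variant
is excluded by choice and documented here).

# Analysis suite

*Preprocessing.* Frames at or below the likelihood floor (0.8 open arena,
0.85 maze) are dropped; single-frame jumps > 30 px between consecutive
retained frames are removed as tracking errors (the jump test deliberately
does not apply across gaps, where large displacements are legitimate
motion); interior gaps are filled linearly between anchors formed from up
to three valid frames per side; boundary gaps are masked, never
extrapolated.

*Speed* is displacement over the frame interval with a 10-sample rolling
median, converted to mm/s by the scale factor.

*Latency.* The motion-energy pipeline refines the onset to the largest
peak within ±0.2 s (the flash artifact), re-windows, zeroes the artifact
sample, denoises (3-sample median, then 7-sample Gaussian σ = 2), excludes
trials with crossings in 0–1.5 s as not idle, and reports the first
≥ 1000-unit crossing within 1.5–9.8 s. The pose pipeline measures
Euclidean departure from the −2–0 s baseline mean and responds on a strict
> 3 px rule within (0, 10] s, using only likelihood > 0.8 frames.

*Heading coherence* is the mean resultant length of 10-frame
vector-averaged headings over a 2 s window. The smoothed vectors are *not*
renormalized: renormalizing overlapping window averages floors R near 0.35
for incoherent headings, which would make coherence values near 0.1
unattainable; without renormalization the statistic spans its full range.
Zero-displacement frames carry the last defined heading forward (dropping
them is the noted alternative).

*Movement states.* A two-component Gaussian mixture (full covariance, via
mclust, deterministic given the seed) on standardized (speed, coherence)
features; the component with the higher mean speed is labeled fast-direct,
never by component index. A negative mean silhouette flags degenerate
single-cluster data. State dependence takes per-trial post − pre deltas;
within a cluster the test against zero change is the one-sample t (a
two-sample unequal-variance form is undefined against a constant), and
Welch's t proper compares deltas between clusters. All-zero deltas report
t = 0, p = 1; nonzero constant deltas are flagged undefined.

# Problem sizes and what the tests show

The test-suite and acceptance problem sizes are the package's choices for
routine verification: ten 60 s gait sessions (≈2,650 phase segments per
phase), 200 trials per latency pipeline, 116 movement-state trials, one
100 × 100 calibration raster with an interleaved held-out grid, a 2 h
closed-loop session for the refractory invariant, and 50 seeds × n ∈ 2…6
for Euler-tour coverage.

The virtual rig emulates the *structure* of real recordings — stance/swing
alternation, delay-degraded targeting, flash artifacts, idle/active
bouts — but not everything real data contains: no tracker mislabeling
between bilateral parts (the forepaw-confusion rate emerges from real
tracking ambiguity and is not contractual), no occlusions, no photometric
variation, no multi-animal interaction. Passing parameter-recovery tests
therefore shows the pipelines are unbiased and correctly implemented at
the stated conditions; it does not certify performance on degraded real
video. Known limitations: the swing trajectory shape is schematic; the
maze agent is a scripted waypoint follower, not a behavioral model; the
idle threshold presets assume 8-bit 230 × 230 crops; and the calibration's
pixel-unit residual uses a local gain approximation.
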