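---
title: "Methods: gaze-shift and saccadic arousal analysis in gazeorient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-shift and saccadic arousal analysis in gazeorient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeorient)
```

# The analysis problem

gazeorient implements the analysis pipeline for a cued face-viewing
paradigm used to study social orienting, in particular in Williams
syndrome (WS).  Each trial shows a fixation cross for 1 s, then a face
for 1.5 s, positioned so that gaze starts either inside the eye region
("eyes-cued") or inside the mouth region ("mouth-cued").  A session is
60 trials, 30 per condition, with ten actor identities displaying angry,
happy and neutral expressions in a fully balanced design (20 trials per
emotion, each actor-by-emotion pairing once per condition).

The dependent variables are: the proportion of mouth-cued trials with a
first gaze shift to the eyes; the proportion of eyes-cued trials with a
shift away from the eyes; the latencies of those shifts; and the peak
saccadic velocity divided by saccadic amplitude, an index of tonic
arousal (lower values indicate hypo-arousal).  Group comparisons use
random-intercept linear mixed models with likelihood-ratio tests,
BIC-approximated Bayes factors, and marginal f² effect sizes.

Because no raw data accompany the study this emulates, the package ships
a synthetic-gaze generator whose ground truth makes every downstream
stage testable end to end.

# Coordinates and geometry

Gaze is expressed in degrees of visual angle with the screen centre as
origin, x rightward and y downward positive (the screen-pixel
convention).  Pixel coordinates convert per axis as the arctangent of
the physical offset over the viewing distance — exact at these
eccentricities, and exactly invertible, which the tests assert to 1e-9.
Angular distances between gaze points use the great-arc angle between
3-D gaze direction vectors, computed in the numerically stable
half-angle (chord) form so that coincident points give exactly zero.

The study does not publish its screen geometry or AOI extents, so the
defaults (eyes 8° × 3°, mouth 6° × 2.5°, AOI centres 5° apart
vertically; a 1920 × 1080 px, 510 × 287 mm display at 600 mm in the
examples) are explicit fixtures, not reconstructions.  The cued AOI is
always centred on the fixation-cross location, which is how the paradigm
positions its stimuli.

# The synthetic-gaze generator

The generator is first-class, tested code: its role is to define the
study conditions under which the pipeline is validated.

**Saccade model.**  Saccades follow a raised-cosine velocity profile,
`v(t) = (V_p/2)(1 − cos(2πt/D))`, chosen because its peak velocity has
the closed form `V_p = 2A/D` — an exact oracle for the velocity stages.
Durations follow the linear main sequence `D = 21 ms + 2.2 ms/deg × A`,
which puts peak velocities of 4–10° saccades in the physiological
100–500 deg/s range and makes `V_p/A = 2/D` decrease with amplitude, as
the main sequence requires.  Hypo-arousal is simulated as a
multiplicative scaling of `V_p` at fixed amplitude by inflating `D`,
matching the arousal index being the `V_p/A` ratio.  Asymmetric velocity
profiles, glissades, microsaccades and smooth pursuit are out of scope.

**Trial model.**  Gaze starts each trial wherever the previous trial
ended; if that is away from the cross, a return saccade to the cross is
generated about 250 ms into the fixation period (and recorded in the
ground truth), so the sample stream never contains non-physiological
position jumps.  With a condition-specific probability the stimulus
epoch contains exactly one shift from the cued AOI to the other AOI, at
a latency drawn from a log-normal shifted by 100 ms (positive and
right-skewed, as saccadic latencies are).  A small fraction of shifts
(default 2%) lands outside both AOIs, mirroring the paradigm's
observation that such landings are rare.  Landing points are uniform in
the target AOI shrunk by a 0.5° margin.

**Noise model.**  Isotropic Gaussian position noise per sample (default
SD 0.3°), independent per-sample dropout (default 2%), and optional
contiguous blink gaps.  This emulates the precision and data loss of a
remote corneal-reflection tracker, but deliberately not its full error
structure: real trackers show temporally correlated drift,
participant-dependent calibration bias, and systematic offsets near
blinks.  Passing the recovery tests therefore demonstrates correctness
of the algorithms under a fair noise floor, not performance on any
particular commercial tracker.

**Cohorts.**  Groups are defined by mean parameters plus participant
heterogeneity: logit-normal jitter on shift probabilities (SD 0.5),
log-normal jitter on latency means (SD 0.15) and on the velocity scaling
(SD 0.08).  This induces the random-intercept structure the mixed models
assume.  The study-shaped preset (`cohort_config_ws_td()`) has 37
WS-like participants with no eye bias (equal shift probabilities and
latencies in both conditions) and velocity scaling 0.757 — the ratio of
the published group means of the velocity index, 22.45/29.67 — against
50 typically-developed-like participants with an eye bias
(shift-to-eyes probability 0.75 vs shift-from-eyes 0.45; latencies
450 ms vs 600 ms).  These values were fixed once, from the published
group-level pattern, as the generator's definition of the study
conditions.

# Event detection (I-VT)

Velocity is the central-difference point-to-point angular speed: sample
`i` gets the angular distance between samples `i − 1` and `i + 1` over
their time span; run endpoints use one-sided differences.  Samples with
speed strictly above 30 deg/s are saccadic, all others fixational.  The
strict inequality is a deliberate convention so the boundary case (0.25
deg/sample at 120 Hz = exactly 30 deg/s) is testable: it classifies as
fixation.

Post-processing, all exposed as configuration:

* gaps of invalid samples up to 75 ms are linearly interpolated before
  velocity computation; longer gaps leave velocity undefined and break
  events;
* an optional 3-sample median position pre-filter for noisy recordings
  (the pipeline enables it by default; the bare classifier does not);
* saccade events shorter than 10 ms are discarded;
* saccade events with a start-to-end displacement below 1.5° are
  reclassified as fixation.  Noise-driven velocity spikes have
  near-zero net displacement, so this displacement gate is what
  separates them from real saccades; 1.5° is five times the per-sample
  noise displacement scale at the default noise level and far below the
  ~4–7° inter-AOI saccades the paradigm analyses;
* adjacent fixation runs are merged, and fixations shorter than 60 ms
  are left unclassified.

Saccade amplitude is the straight-line (start-to-end) angular
displacement, not path length — the conventional definition; the event's
peak velocity is the maximum sample speed within it.  Because event
boundaries sit where speed crosses the threshold, a small fraction of
the true displacement (about 1% for a raised cosine) falls outside the
event; this partially cancels the interpolation loss in the peak, which
is why the velocity/amplitude index is recovered more accurately than
either of its factors.

Whether the original MATLAB filter smoothed velocity or applied duration
constraints is not stated anywhere; the defaults above are this
package's explicit choices, validated against the generator: at the
default noise level the tests require at least 95% of ≥ 4° saccades
detected with onset error within 2 samples and mean amplitude error
within 10%.

# Peak velocity and the arousal index

At 120 Hz the velocity peak falls between samples, so peak velocity is
systematically underestimated.  Following the up-sampling rationale, x
and y are interpolated onto a 10× denser grid (1200 Hz) with a cubic
interpolating spline (Forsythe–Malcolm–Moler end conditions, the
`stats::splinefun` default, as the conventional reading of a "simple
spline") before the same central-difference velocity operator is
re-applied.  Original samples are reproduced exactly at their own
timestamps; gaps are propagated, never interpolated across.  Recordings
declared at 60 Hz are refused outright: the peak cannot be recovered at
that rate even after up-sampling, so 60 Hz data are excluded from
peak-velocity analyses (the pipeline skips the stage and logs why).

The arousal index for a participant and condition is the mean over
qualifying saccades of peak velocity divided by amplitude (units 1/s).
Only saccades with amplitude strictly exceeding 4° qualify, regardless
of direction, and the mean pools all qualifying saccades across the
condition's trials (not trial means first) — the source leaves the
pooling unspecified; pooling is this package's choice and is logged as
such.

A numerical note: for a single saccade at the smallest qualifying
amplitudes (A ≈ 4°, D ≈ 30 ms, i.e. ~3.6 samples at 120 Hz), the
recovered peak at the least favourable grid alignment can deviate by up
to ~5% — an information limit of cubic interpolation at that density,
not a bug.  Averaged over grid alignments, as any real mean over
saccades does, the index is recovered within 2%, and the tests assert
exactly that, along with the strict superiority of 120 Hz + up-sampling
over raw 60 Hz extraction at every amplitude on a 4–12° grid.

# Gaze shifts, trial validity, inclusion rules

The first gaze shift of a trial is the first saccade after stimulus
onset whose onset position lies in the cued AOI and whose landing (the
centroid of the following fixation, or the saccade endpoint if none
follows) lies outside it.  Latency is anchored to saccade onset — the
standard in the saccadic latency literature; the source is silent on
this.  AOI containment is inclusive at the boundaries.  Shifts landing
outside both AOIs are excluded from the proportion and latency analyses
entirely (numerator and denominator), as the paradigm treats them;
`latency_agreement()` provides the corresponding diagnostic — the
correlation between latency-to-the-other-AOI and latency-to-anywhere —
which approaches 1 when such landings are rare.  Anticipatory shifts
(latency < 80 ms) are flagged and retained by default, with a
configuration flag to drop them.

The source never defines a "valid trial".  Here a trial is valid iff
gaze at stimulus onset (nearest valid sample within 50 ms) lies inside
the cued AOI, and at least half of the stimulus-epoch samples are valid;
both criteria are configurable.  A participant-condition contributing
fewer than 5 valid trials is excluded from that condition, as the
analysis rules require.

# Mixed models, Bayes factors, effect sizes, power

All models are Gaussian random-intercept linear mixed models fitted by
full maximum likelihood (never REML: likelihood-ratio and BIC
comparisons across fixed-effect structures require ML), via `lme4`.
Proportions are modelled linearly, as in the source analysis — fidelity
over statistical taste; no logistic variant is offered.  Each effect of
interest is tested by comparing the model containing it to the next
most complex model without it:

* likelihood-ratio χ² with df equal to the parameter-count difference;
* `BF10 = exp((BIC_null − BIC_full)/2)`, the BIC approximation to the
  Bayes factor, with `BF01 = 1/BF10` (the tests assert reciprocity to
  machine precision and consistency with the published pairwise
  tables at 2 decimal places);
* BIC uses `k·ln(n) − 2·logLik` with `n` the number of observations
  (rows), not participants — this matches the BIC of the fitting
  routine the source used, and the choice changes the Bayes factor, so
  it is documented here;
* marginal f² per Nakagawa & Schielzeth:
  `f² = (R²m_full − R²m_null)/(1 − R²m_full)` with marginal R² the
  variance of fixed-effect predictions over the sum of fixed, random-
  intercept and residual variances (computed in-package; negative
  differences clamp to 0);
* follow-up p-values are reported uncorrected with Benjamini–Hochberg
  pass flags at FDR 0.05 (via `stats::p.adjust`).

For the power machinery, a two-group design with fraction `p` of
observations in one group and group effect `b` has marginal
`f² = p(1−p)b²/(σ²_b + σ²_e)` against an intercept-only null, which
`calibrate_group_effect()` inverts.  `power_simulation()` generates
random-intercept datasets at the calibrated effect (defaults: groups of
37 and 50 participants, two repeated measures each, variance components
0.5 + 0.5), refits template `lme4` models to each replicate, and counts
likelihood-ratio rejections at α = .05.  With `f² = 0` the same
machinery estimates the type-I error, which the tests require to lie in
[0.03, 0.07].

The degenerate case of a constant outcome is handled without fitting:
the intercept equals the constant and both variance components are
zero.  Non-convergence is flagged on the result rather than raised.

# Problem sizes and determinism

The validation suite uses sizes chosen to exercise the study's design
while keeping a full run in the minutes range: 500 power replicates and
1000 null replicates for the calibration checks, 200 replicates for the
f² recovery, six 60-trial sessions for detection recovery, and one full
87-participant cohort (37 + 50) for the qualitative signature.  Every
stochastic stage is reproducible from an integer seed: the same seed
gives byte-identical sessions, and the pipeline writes a manifest
(configuration, seed, package and R versions) alongside its outputs.

# Known limitations

* The generator's noise is white; real tracker noise is not, and event
  detection on real data may need the median pre-filter plus stricter
  duration constraints.
* Only monocular/averaged gaze is handled; there is no native parsing of
  proprietary tracker formats.
* The emotion factor is generated and carried through the metadata, but
  the default analysis plan does not model it; the model-comparison
  interface accepts arbitrary nested pairs for such follow-ups.
* Linear models on proportions can predict outside [0, 1]; this is
  intentional fidelity to the emulated analysis.
* The BIC Bayes factor is an approximation (unit-information prior);
  it is not a substitute for a full Bayesian treatment.
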