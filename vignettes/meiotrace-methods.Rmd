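---
title: "Models and methods behind meiotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(meiotrace)
```

This vignette explains the models inside `meiotrace`, the choices made
where the design was genuinely open, and what the synthetic oocyte
generator does and does not emulate. It states no empirical result that
the package's tests and `scripts/acceptance.R` do not themselves compute.

## The measurement pipeline

### Coordinates and alignment

Raw annotations are chromosome-center markers in voxel units; conversion
to microns is pure componentwise scaling (defaults 0.104 um/pixel in x/y,
1 um/slice in z), with no half-pixel offset — marker coordinates are
treated as continuous blob centers, so the affine part of the camera
model is irrelevant after the per-frame centering that follows.

Every frame is translated so the centroid of the 20 chromosomes sits at
the origin; this removes stage drift and slow sample translation but not
rotation. The rotation is fixed once per oocyte by PCA of the chromosome
positions after the metaphase plate has formed: the two leading principal
components span the equator plane and the smallest one is the plane
normal, which for a bipolar spindle is the pole-to-pole axis. We call the
coordinate along that normal `z` throughout; its absolute value is the
distance to the equator plane. The basis is made right-handed, and the
sign of the normal is fixed against the fitted spindle long axis (whose
own sign is made deterministic by a largest-component-positive rule),
falling back to "+z of the input frame" when no spindle cloud is
available. The sign is a pure convention: every downstream quantity uses
either |z| or a sign-symmetric statistic.

Two automation choices replace manual judgment calls:

* **Equator-formation time** is detected as the first frame at which the
  RMS distance of the chromosomes to their best-fit (total least squares)
  plane drops below 2 um and stays below it for 3 consecutive frames.
  The 2 um threshold and 3-frame persistence are package conventions; the
  persistence guard exists because a 20-point cloud's smallest sample
  eigenvalue fluctuates strongly, and single-frame dips during
  congression (when several chromosomes cross the equator simultaneously)
  must not count as plate formation. Absence of detection is a valid
  outcome and is how severe knockdown recordings are routed out of the
  classification path.
* **The PCA snapshot** pools all frames from the detected equator time to
  the end of the recording, each centered on its own frame centroid,
  instead of using the single formation frame. A single 20-point snapshot
  taken at the moment the plate first satisfies the threshold is close to
  isotropic (plate radius barely above plate thickness) and can tilt the
  recovered normal by tens of degrees; pooling the aligned frames, whose
  anisotropy is strong, pins the normal while changing nothing else. The
  `degenerate` flag is raised when the in-plane/normal eigenvalue ratio
  is below 1.2.

### Speed decomposition

With cylindrical radius `r = sqrt(x^2 + y^2)` about the pole-to-pole
axis, each inter-frame interval yields a signed axial speed from the
change of |z| (positive toward the plane), a signed radial speed from the
change of r (positive toward the axis), and a non-negative tangential
speed from the in-plane chord `d_xy` as `sqrt(d_xy^2 - (dr)^2)/dt`. Two
axial columns are exposed because two questions are asked of the data:
`v_axial` (from |z|) answers "toward or away from the plane" and is what
all population summaries use; `v_axial_path` (= |dz|/dt) is the
geometric path speed and is the quantity that closes the exact identity
`v_axial_path^2 + v_radial^2 + v_tangential^2 = v_total^2`. The two
differ only on intervals that cross the equator. The chord-based
tangential speed converges to the arc speed `r dphi/dt` as the per-frame
angle goes to zero; at 0.05 rad/frame the relative gap is under 0.1%.

### Step segmentation

The four-step structure is recovered by exhaustive least-squares
changepoint search on the population mean |axial speed| curve, smoothed
with a centered 3-frame moving average (shrinking windows at the edges):
three breakpoints, each segment at least 3 intervals, minimizing total
within-segment variance; the Step III/IV boundary is constrained not to
exceed the detected equator time. The search is exact and deterministic
(about 7,000 candidate triples at 36 intervals, evaluated with prefix
sums). A flat profile cannot be segmented meaningfully; it is reported as
`degenerate` with boundaries at the quartiles, and a recording with no
detected equator as `undetermined`.

### Trajectory classification

Each chromosome is encoded as its |z| sequence on a fixed grid of
31 points, +/-150 min around the Step III onset T0 (the recovered II/III
boundary of its oocyte), with out-of-recording points carried as a
0-valued sentinel plus a mask channel; values are scaled by 0.1 to bring
microns to unit order. The classifier is two stacked GRU layers (hidden
size 32 each) whose final hidden state feeds a one-hidden-layer
perceptron (32 units, ReLU) with a 3-way softmax, trained by full-batch
Adam (learning rate 0.01) on the cross-entropy, with early stopping after
25 epochs without a 1e-5 loss improvement and a 200-epoch cap. The
forward and backward passes are implemented directly in R matrix code and
are gradient-checked against central finite differences in the test
suite. Because a recurrent network occasionally stalls in a poor basin
from an unlucky initialization, training performs up to 3 random restarts
and keeps the fit with the lowest final training loss; a restart is
skipped once a fit reaches loss < 0.1. All of these are defaults of
`gru_spec()` and configurable; none are printed in a reference to copy,
so they are package choices. The split is 9:1, stratified by label,
seeded. Ties in the argmax are broken by the fixed class order
retracing < congressing < quasi-static.

A deterministic rule-based baseline (`baseline_rule_classify()`) exists
purely as a falsifiable reference: quasi-static if mean |z| < 1.5 um
(the definitional bound), else retracing if the sequence peaks at >= 8 um
and later returns below 3 um, else congressing. The GRU must match or
beat it on synthetic data; the baseline's known failure mode is
large-amplitude congressing oscillation being mistaken for retracing.

Evaluation computes one-vs-rest ROC curves by threshold sweep over the
class probability and AUC by the trapezoid rule, which equals the
Mann-Whitney concordance with ties counted 1/2 (asserted exactly in the
tests); both the macro average and the per-class minimum are reported. A
class with no positives gets an NA AUC rather than a number.

### Group statistics

The one-sided Mann-Whitney U test enumerates all label assignments
exactly (valid under ties) when the smaller group has at most 8
observations and the combined sample at most 25, and otherwise uses the
normal approximation with tie correction and continuity correction; the
two branches agree to within 0.01 at the crossover sizes. The direction
of the alternative must be declared by the caller and is never inferred
from the data. Fisher's exact test sums hypergeometric probabilities by
the minimum-likelihood rule and reports the conditional maximum-likelihood
odds ratio (solved by root-finding on the noncentral hypergeometric
mean); a zero margin gives p = 1 with a degenerate flag. Multiplicity
adjustment is Benjamini-Hochberg by default, Bonferroni on request —
"adjusted" alone does not pin a method, and BH is the common choice for
a handful of planned pairwise comparisons.

## The synthetic oocyte generator

The generator is a piecewise kinematic model, not a mechanistic one: the
study conditions are summary statistics of real oocytes, so the simulator
is built from constant-rate drifts, a random-turning oscillation and
mean-reverting fluctuation, *calibrated* so that the printed summary
values emerge when the full measurement pipeline (alignment included) is
run on its default output. The calibration constants are frozen fixtures
in `R/sim-profiles.R`.

Defaults and their origins (per `sim_config()`): 20 chromosomes, 10-min
frames; step durations 30/60/150/120 min (not printed anywhere; chosen so
Step III lasts well over an hour and the +/-150 min classifier window
holds 31 samples); class weights 0.15/0.65/0.20; Step I outward drift
targeting a 0.17 um/min population mean; Step III population mean axial
speed target 0.18 um/min; retracing excursions peaking at 12 um
(per-chromosome peaks drawn N(12, 0.5)) with a 0.30 um/min return over
30 min; peak radial congression rate 0.10 um/min sustained for three
frames; quasi-static time-averaged |z| bounded by 1.5 um; spindle
elongation 2 um pole-to-pole with a 2 um midplane-radius shrink across
Step III; annotation noise 0.3 um SD per coordinate per frame.

Per class, the axial path is:

* **retracing** — rise from the Step III start offset to the peak over
  the first third of Step III, a brief hold, the 0.30 um/min descent,
  then a slow settle;
* **congressing** — a constant-path-speed oscillation through the
  equator whose turning points are drawn per chromosome (alternating
  poles, heights uniform in 0.6-0.9 of the Step III start offset),
  filling all of Step III, then a slow (0.08 um/min) Step IV settling
  onto the plate. The random schedules, a 0-1 frame start delay and the
  stratified pole assignment decorrelate the crossings, which matters:
  the plate-formation detector watches the smallest eigenvalue of a
  20-point cloud, and synchronized crossings would fake plate formation
  mid-congression. The path speed (0.33 um/min at the default target) is
  the main calibration constant for the 0.18 um/min measured mean; it
  exceeds the measured mean because turning points and equator crossings
  do not advance |z|;
* **quasi-static** — a mean-reverting AR(1) fluctuation about the
  midplane (per-frame correlation 0.8, stationary SD 0.5 um), which keeps
  the time-averaged |z| near 0.4-0.5 um, comfortably inside the 1.5 um
  definitional bound even after alignment error.

Chromosome angular positions are stratified around the spindle axis and
pole signs are balanced within each class, reflecting the even
distribution of chromosomes over the spindle surface; both also keep the
per-frame centroid near the true axis so the centering step does not
inject spurious axial motion. The whole scene (chromosomes and spindle
cloud) receives a per-oocyte random rigid rotation and a drifting
translation, deliberately, so that frame centering and PCA alignment are
exercised non-trivially; spindle clouds are uniform-on-surface samples
(rejection sampling with the area-element weight) of the configured
ellipsoid, 500 points per frame. The configured equator time stored with
a recording is obtained by applying the same detection rule to the
noise-free canonical positions, so detection on the noisy observed data
is expected to land within a frame or two of it.

Small calibration gains (Step I drift x0.97, radial template x1.01)
absorb the net attenuation of the measurement pipeline — alignment
error, per-frame re-centering and smoothing — so the measured values,
not the latent ones, match the configured targets. The Step I drift of
the mobile classes is additionally inflated for the quasi-static share
of the population, whose Step I axial speed is only measurement noise
(~0.05 um/min), so that the *population* mean lands at 0.17.

Knockdown presets are qualitative multipliers, since no knockdown rates
are printed: KIF11 scales all motion to 0.2x and freezes congression
(sluggish/stationary, no equator ever forms); KIF2A replaces congression
with a fast, nearly memoryless random walk (2x speed, direction
persistence 0.1, no equator); KIFC1 is near-control (0.9x); CENPE and
KIF20A leave a 1.5 um residual misalignment offset at Step IV; KIF18A
and KIF4A reduce the retracing weight to 0.03 (folded into congressing,
quasi-static untouched). The numeric values are package conventions
chosen to reproduce the ordering sluggish < control < chaotic.

What the generator does **not** emulate: intensity images (no
photorealism, no segmentation errors beyond Gaussian annotation noise),
microtubule-level mechanics or force balance, chromosome-identity errors
(identity is given by construction; the tracing-error QC is exercised by
fault injection in the tests), anaphase, and any correlation between a
chromosome's identity and its trajectory class. Passing tests therefore
demonstrate that the pipeline recovers what this kinematic family
encodes, not that real oocytes satisfy the model.

## Numerical choices and degenerate inputs

* Ellipsoid fitting minimizes the algebraic residual of the general
  quadric under a unit-norm constraint (smallest right singular vector),
  computed in centroid-centered coordinates for conditioning; the fit is
  rejected unless the quadric's eigen-structure is elliptic. Coplanar or
  collinear clouds (smallest singular value < 1e-10 of the largest) and
  clouds of fewer than 9 points are errors. Recovery is exact to ~1e-6
  on noise-free on-surface samples.
* The tracing-error QC threshold is mean + 2 *population* SDs of the
  per-interval displacements over chromosomes (the divisor-n SD; with 20
  values the distinction from the sample SD is immaterial, but a
  convention must be fixed), with a strict `>` comparison so that a
  zero-variance interval flags nothing. The candidate chromosome is
  included in its own mean/SD — the simplest reading. Flags are reported,
  never auto-corrected.
* Retracing pole assignment is uniform at random (balanced within the
  class); nothing in the model favors one pole.
* Population confidence bands are the normal approximation
  (mean +/- 1.96 SE); with 20-200 series per time point this is adequate
  and, unlike a bootstrap, deterministic. A single series yields an NA
  band with a warning.
* All simulator and training randomness flows from explicit seeds through
  an RNG-state-preserving wrapper; no call disturbs the caller's RNG
  stream.

## Problem sizes

The test suite and the acceptance script run the default study design:
cohorts of 10 oocytes x 20 chromosomes (200 trajectories, the size at
which the class-ratio checks have ~2.5-point binomial SD), 37 frames at
10-min spacing, 500-point spindle clouds, a 180/20 stratified split, and
property checks over ~1,000 random-walk intervals. A full end-to-end run
(simulation, alignment, training with restarts, evaluation) completes in
a few minutes on one CPU.

## Known limitations

* The equator-detection threshold (2 um) and persistence (3 frames) are
  conventions tuned to 20-chromosome mouse MI oocytes; other systems may
  need different values, which is why both are arguments.
* The Step III/IV boundary is capped by the detected equator time; in
  recordings where the plate forms unusually early the recovered boundary
  inherits that cap.
* The GRU is trained on synthetic trajectories only; applying it to real
  recordings requires retraining on annotated data, for which
  `split_train_test()`/`train_classifier()` are the intended path.
* The exact Mann-Whitney branch enumerates up to C(25, 8) label
  assignments; beyond its size limits the tie-corrected normal
  approximation is used, which is accurate to ~0.01 at the crossover.
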