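---
title: "Models, statistics and design choices in arenaneuro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, statistics and design choices in arenaneuro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arenaneuro)
```

This vignette documents the statistical models the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic generator does and does not emulate, and the design
choices made where more than one reasonable construction existed. It
states no empirical numbers beyond what the package's tests and the
acceptance script themselves compute.

## The synthetic session generator

`generate_session()` produces a complete session: a hexagonal arena
(default 2.4 m tall, 1.5 m sides, benches near 1.5 m), a behavioral
stream, a Poisson spiking population with planted structure, and the
ground truth needed to score recovery.

**Behavior.** A bout-level Markov chain over K syllables (default K = 12,
mean dwell 1.5 s, matching a typical freely-moving repertoire) is realized
at the pose frame rate; leaving a state is a geometric event with mean
`dwell_s`, and the successor is drawn from the transition matrix with the
diagonal removed. The center of mass integrates per-syllable horizontal
speed along a heading whose angular velocity is an Ornstein–Uhlenbeck
process (time constant 0.5 s, stationary sd `sqrt(heading_diff)`); wall
encounters steer smoothly back toward the center at a bounded turn rate.
Vertical position relaxes (rate 1.2 /s) toward per-syllable set points
that place syllables on the floor, bench or ceiling, plus optional
per-bout set-point jitter (`z_jitter`) so the same syllable occurs at
several heights, as real animals repeat actions at different elevations.
All stochastic drives are band-limited (OU or smoothed AR) rather than
frame-wise white: real movement is smooth at 40 Hz, and a zero-phase
smoothing estimator can only track band-limited truth. Pose frames are
rendered from per-syllable posture templates (crouch, stretch, limb
oscillation at a syllable-specific frequency) rotated by body yaw; the
face block additionally rotates by the head-body yaw offset (smooth AR,
sd ~0.5 rad), pitch and roll, so head orientation is recoverable from the
face keypoints alone. Isotropic keypoint noise defaults to 4 mm,
comparable to multi-camera triangulation error at this arena scale.

**Population.** Per 500 ms bin, each unit's rate is the rectified sum of
baseline + Gaussian spatial field + frame-tuned linear drive + syllable
gain × context gain + anticipatory blend, and counts are Poisson. The
rectified-linear construction keeps every planted effect analytically
switchable — setting one gain to zero nulls exactly one downstream
statistic, which is what the recovery suites exploit. Spatial field
centers are drawn from the session's own occupancy (with 10 cm jitter) so
every field overlaps visited space; a field in never-visited air would be
unrecoverable for any method and would only measure occupancy, not the
estimator. The anticipatory component blends the unit's syllable gain
toward the upcoming syllable's gain, ramping linearly over `ramp_lead_s`
before each transition: this is the simplest generative account of a
population state that drifts toward the next behavior's pattern before
onset. One global seed fans out to named substreams (behavior, spikes,
shuffles, ...) so stages can be regenerated independently.

**What the generator does not emulate:** camera images and triangulation
failures, multi-animal interactions, non-Poisson spiking (bursting,
refractoriness), slow representational drift, and correlated noise across
units. Passing the recovery suites therefore demonstrates correctness of
the estimators under the stated generative model, not robustness to every
artifact of real recordings.

## Pose cleaning and kinematics

Coordinates are smoothed by a running median (0.2 s) then a running mean
(0.4 s); both are centered, hence zero-phase. Skeleton edges whose length
deviates more than 3×MAD from that edge's median mark both endpoints
missing for the frame (linearly interpolated), and elbow/knee angles
outside 15–170° are flagged. The center of mass is the confidence-weighted
mean of the 12 non-face joints — the trunk-and-limbs centroid is the
conventional proxy when no segmental mass model exists. Body yaw comes
from the hip-midpoint→shoulder-midpoint axis; head yaw/pitch from the
nose − ear-midpoint vector and roll from the inter-ear axis. A constant
anatomical offset between the nose−ear axis and the "true" gaze direction
only rotates the head-frame basis, which leaves any linear model on
head-frame features invariant, so no calibration step is needed.

Features are bin-averaged onto the 500 ms neural grid (bins with under
50% frame coverage are invalid) rather than snapshot-sampled; averaging is
the natural aggregation for rate models and suppresses frame-scale noise.
The looming proxy — no standard formula exists for a geometric proxy of
visual expansion — is the approach rate over distance,
`-d/dt(wall_dist)/max(wall_dist, 0.05)`, zero for a stationary animal and
large when closing on a nearby surface; the 5 cm floor prevents blow-up at
contact. Height tiers default to pooled terciles of floor-relative height
but accept fixed boundaries (both conventions are in use for such
arenas); angular sectors are half-open 120° wedges, zone = tier·3 +
sector.

The lagged design replicates VIS/BODY_KIN/HEAD_KIN at −1.0…+1.0 s in
0.5 s steps, leaves position unlagged, and appends a linear drift column:
(5+3+4)×5 + 3 + 1 = 64 columns; edge bins lacking full lag context are
masked.

## Ridge encoding and unique variance

Validation must respect temporal autocorrelation: contiguous 30 s blocks
are assigned cyclically to folds and a 2 s embargo strips training bins
near every test bin (a trailing partial block joins the last full block).
The penalty is chosen per outer fold by an inner blocked/embargoed CV
(k−1 folds over the training blocks) on the 20-point grid; features are
z-scored with training statistics only; held-out predictions are pooled
and R² uses the pooled held-out mean. The solver is the SVD closed form,
which yields coefficients for the whole penalty grid from one
decomposition and makes the 100-shuffle unique-variance loop cheap: for
each shuffle the fold SVD is shared across all units, so population-level
decomposition runs in seconds.

Unique variance freezes each unit's penalty at the full-model choice
(otherwise regularization changes would masquerade as feature-group
contributions), block-permutes one group's rows in 10 s chunks (chunk
order uniform, chunks intact, permutation restricted to valid bins), and
takes the mean held-out R² drop. The one-sided p treats the intact R² as
one more draw from the shuffle distribution — `(1 + #{drop ≤ 0})/(n+1)` —
which is the empirically calibrated permutation form (the test suite
verifies uniform p on 200 null units); BH correction is applied across
units within each group, and the significance gate additionally requires
ΔR² ≥ 0.005 and full-model R² > 0.01.

## Reference frames

The three frame models share one base (speed + drift) and add six
features each — center-of-mass velocity and displacement-from-arena-center
expressed in world axes, yaw-rotated body axes (gravity preserved), or the
fully rotated head frame — so they are complexity-matched by construction
and the per-bin vector norms are frame-invariant. "Displacement" admits a
second reading (per-bin position change), implemented behind the
`displacement` switch; the default is displacement from the arena center.
Bins invalid in any frame are dropped from all three so comparisons stay
sample-matched. Winners break ties allo > body > head (ties are
measure-zero but tests need determinism). The RF-index is the normalized
contrast of rectified improvements, (U_a − U_b)/(U_a + U_b); it is
undefined when neither frame improves on base, and such units are
excluded from tier medians. Tier-stratified refits intersect the
full-session temporal folds with tier bins (blocking preserved), select
their own penalty per tier, and enforce the validity rules (≥50 tier
bins, ≥2 usable folds, ≥20 test bins, rate variance > 1e-6); the paired
floor-vs-ceiling Wilcoxon uses units valid in all three tiers.

## Syllable segmentation

The per-animal scale is the geometric mean of median torso length
(shoulder-mid to hip-mid) and median shoulder width; an alternative using
97.5th-percentile statistics sits behind `scale_stat`. Division by this
scalar makes all 66 pairwise body-joint distances exactly invariant to
uniform body-size differences. PCA keeps 20 components; with two or more
animals, components whose point-biserial correlation with identity
exceeds 0.3 in magnitude are removed so syllables reflect behavior, not
morphology.

The Morlet transform (center frequency 6.0, exposed in the arguments)
runs in the frequency domain; amplitudes are z-normalized per frequency
row — by default over all frames, or over training frames only via
`norm_frames` to avoid leakage when a reference embedding is reused.
Heights are z-scored and weighted ×3 (vertical stratification is the
dominant contextual axis in a tiered arena) and speeds ×2 (separating
stationary from dynamic behavior).

The 2D embedding backend is pluggable. The default is a deterministic
neighbor-graph spectral embedding: a 15-neighbor cosine k-NN graph over
(at most 2500 evenly subsampled) training frames, the two smallest
non-trivial eigenvectors of the symmetric normalized Laplacian, and
similarity-weighted neighbor projection for held-out frames. A linear
PCA-2D backend is provided for quick, fully linear runs. The density grid
(300×300, Gaussian σ = 1.5 cells) uses robust (0.1%/99.9% quantile)
raster limits: a handful of projected outliers must not stretch the grid
and compress the density modes. Watershed runs on the density landscape
with the minimum peak separation increased from 1 until the initial
region count stops exceeding the cap (default 40).

Initial basins are consolidated to `k_final` syllables by **topological
persistence**: the basin whose density peak has the lowest prominence
(peak minus its highest saddle to any neighbor, with background contact
counting as a saddle at zero) merges into the neighbor across that
saddle, repeatedly. Fragments of one diffuse behavior are connected
through high saddles and coalesce first, while modes separated by deep
valleys persist. A Ward-linkage alternative on mass-weighted basin
centroids is kept behind `merge_method = "ward"`; in our planted-motif
experiments centroid-space Ward is unstable when the watershed fragments
a diffuse cloud (recovery varies widely across seeds), whereas the
persistence rule is uniformly stable — this motivated making persistence
the default for an unsupervised pipeline that cannot rely on
merge-by-inspection.

Post-processing applies a sliding-window mode filter over 1 s (the median
of categorical labels is meaningless, so the mode replaces it) and
absorbs bouts shorter than 1 s into the longer temporal neighbor (ties to
the preceding bout), iterating until no short bout remains. Labels align
to neural bins by the nearest behavioral frame within 0.5 s; the 10 most
frequent syllables are retained and rarer ones excluded.

The planted-motif recovery suite uses three motifs with 10 s mean bouts:
the wavelet at the lowest analysis frequency (0.5 Hz) has roughly ±2 s of
temporal support, so bouts must be long relative to it or boundary frames
— whose scalograms mix adjacent motifs — dominate the error. This is a
property of the method itself, not of the generator: short-bout behavior
is intrinsically harder for any spectrogram-based segmentation.

## Population decoding

The decoder is multinomial logistic regression with balanced class
weights; balanced accuracy (mean per-class recall) is the score, so a
constant classifier sits exactly at 1/K. Folds are valid only when train
and test both contain every class. Permutation nulls refit the decoder
under label permutations that preserve the fold structure — uniform
permutations for syllables, contiguous 10 s block permutations for
spatial labels (mirroring the regressor-shuffle chunk). Residualized
decoding removes, per unit, the held-out linear prediction from
VIS/BODY_KIN/HEAD_KIN/drift covariates (near-zero ridge penalty as a
singularity fallback) before decoding again; residuals are held-out, so
no covariate fit ever sees its own test bins.

The temporal generalization matrix samples ±4 s peri-transition windows,
assigns transitions to 5 stratified folds, drops training transitions
within 2 s of any test transition, z-scores and reduces features to at
most 50 principal components with train-fold statistics, and tests every
train-lag classifier at every test lag. Confusion-vs-transition structure
is the Spearman correlation between the symmetrized row-normalized
confusion matrix and the symmetrized empirical bout-transition matrix
over off-diagonal pairs, with a class-relabeling null; below 4 classes
the p is flagged unreliable. Syllable tuning vectors are per-unit
z-scores of syllable-mean rates, viewed as unit-by-unit and
syllable-by-syllable Pearson correlations, with selectivity = max |z|.

## Manifold statistics

The mandatory embedding backend is linear: principal components of the
z-scored rate matrix, with signs fixed by the largest-loading rule. For
decoding, a separate transform is fit on each training fold and test bins
are projected through their fold's transform. For geometric statistics
(context ratio, drift, transition velocity) a single all-data transform
is used instead: per-fold principal axes are not mutually aligned, and
concatenating coordinates from differently-rotated bases scrambles
centroid geometry. A contrastive backend slot exists; requesting it warns
and falls back to the linear baseline. The spatial-lite label family
(com_x, com_y, speed, yaw_rate) structurally excludes vertical position —
`fit_embedding()` refuses a spatial-lite label matrix containing com_z —
so height-related structure in that space cannot come from supervision.
Context analyses use the 8-dimensional linear space, the dimensionality
that matches the quantitative decoding baseline for this backend.

The context ratio compares, per syllable present in ≥2 tiers with ≥20
bins each, the RMS distance between same-syllable bins in different
tiers against the RMS distance within a (syllable, tier) cell, both in
closed form from per-cell means and variances
(E‖x−y‖² = tr Σ₁ + tr Σ₂ + ‖μ₁−μ₂‖² across cells). The ratio is exactly 1
when context has no effect — a property the within-syllable tier
permutation null requires — and grows with between-tier centroid
separation. Per-syllable ratios aggregate tier pairs by mean (max behind
a switch) and average across syllables.

Anticipatory drift restricts to clean transitions whose outgoing bout
spans the whole ±2 s pre-onset window, so pre-onset similarity reflects
the current behavior rather than older bouts. Cosine similarity (about
the global mean state) between the embedded state and the session-wide
next- and current-syllable centroids is computed per lag; the ramp
statistic is the t-score, across transitions, of the per-transition
pre-onset slope of next-centroid similarity. The studentization matters:
aligned pre-onset states are less variable than circularly shifted ones,
so the raw mean slope is conservative under the 500-shift circular null,
while the t-score is exchangeable and its null p is uniform (verified by
simulation in the test suite). Transition velocity compares consecutive
embedding-state steps inside transition windows against baseline bins at
least 2 s from any transition, as percent elevation, under the same
circular-shift null. Eta² per embedding dimension is SS_between/SS_total
for one-way groupings by syllable and by tier; single-class groupings
return 0 with a flag.

## Numerical conventions and degenerate inputs

Angles are radians in (−π, π]; the frame is right-handed, z up, origin at
the arena floor center. Zero-variance design columns are centered but not
scaled, so they drop out of the ridge fit; zero-variance units are
excluded with a report. Constant wavelet rows are zeroed rather than
divided by zero. Watershed cells left unlabeled at basin boundaries take
the nearest labeled basin. Fold plans refuse sessions with fewer full
blocks than folds; a 299 s session has only nine full 30 s blocks.
Permutation p-values always include the observed statistic in the null
set, so the smallest attainable p is 1/(n+1).

## Problem sizes in the test and acceptance suites

The suites are sized as a scientist would size a simulation study:
single-session analyses use 600 s sessions with 40–60 units (enough bins
for 5-fold blocked CV with ~150-bin inclusion); the null-calibration
suite uses 200 baseline-only units on one 600 s session; the
context-ratio suite uses 1200 s sessions with 80 units (recorded sessions
of this kind run 30–60 min with hundreds of units) across 10 seeds; the
drift null calibration uses 100 replicate 180 s sessions; the motif-
recovery fixture uses a 360 s stream of three long-bout motifs.

## Known limitations

The linear embedding backend cannot represent curved population
manifolds; statistics on it are conservative relative to a nonlinear
supervised embedding. The spectral 2D backend approximates, but is not,
the stochastic neighbor embedding used in the field's segmentation
pipelines. The generator's Poisson assumption understates the variance of
real spike counts, so real-data p-values will be somewhat less
well-calibrated than the synthetic suites suggest. Identity filtering is
only defined for two animals via a binary label; multi-animal studies
need a categorical extension. The paired tier analysis inherits the
pseudoreplication caveats of unit-level inference: units recorded
simultaneously are not independent, and session- or animal-level
hierarchical modeling is out of scope here.
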