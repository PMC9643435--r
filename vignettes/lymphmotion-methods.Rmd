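---
title: "Models and methods behind lymphmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lymphmotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`lymphmotion` analyses the motility of lymphocytes in multi-channel
time-lapse confocal microscopy of lymphoid tissue: B-cells (CD20), T-cells
(CD3), follicular T-helper cells (PD1), and the follicular dendritic cell
(FDC, CD35) network. The pipeline covers movie preprocessing, cell detection
and track linking, translation/rotation-invariant movement features, ellipse
morphology, descriptive motility statistics, dense optical flow on the FDC
channel, four "information level" phenotype classifiers with a unified
pixel-level evaluation, layer-wise relevance propagation (LRP), and k-means
clustering of tracks into directed and undirected movement classes.

Because real recordings are large external downloads, the package ships a
synthetic-movie generator that emulates the statistical structure the
analysis assumes. Every downstream stage is tested closed-loop against that
generator's ground truth.

# The synthetic world

## Cell tracks

Tracks follow a correlated random walk in the plane. Per-frame speeds are
log-normal — the simplest heavy-tailed positive law — and headings evolve by
wrapped-normal turning angles. Each track belongs to one of two movement
regimes that differ *only* in heading persistence:

* **directed**: turning-angle sd `directed_turning_std` (default 0.25 rad),
* **undirected**: turning-angle sd `turning_angle_std` (preset-specific,
  1.2–2.2 rad).

This mirrors the two features that later define the data-driven (DD)
clusters: net displacement and the spread of turning angles.

The speed law is calibrated from published summary pairs. For a log-normal
distribution `mean/median = exp(sdlog^2/2)`, so a (mean velocity,
track-median velocity) pair pins down the dispersion
(`dispersion_from_mean_median()`). The default presets use

| phenotype | mean (um/min) | median (um/min) | sdlog | undirected sd (rad) | directed fraction |
|-----------|--------------:|----------------:|------:|--------------------:|------------------:|
| CD20      | 2.00          | 1.65            | 0.620 | 2.2                 | 0.23              |
| CD3       | 2.06          | 1.72            | 0.601 | 1.2                 | 0.35              |
| PD1       | 2.55          | 2.11            | 0.615 | 1.6                 | 0.38              |

so one preset reproduces both velocity statistics simultaneously, and the
qualitative ordering (PD1 fastest and largest, CD20 turniest and least
directed) holds by construction. Cell densities are free configuration
parameters — no absolute density is asserted anywhere.

## Rendering

Cells are drawn as anisotropic Gaussian blobs. The preset diameter is the
full width at half maximum (FWHM) along the major axis; the 50%-of-peak
segmentation used by the morphology module therefore recovers it directly.
Orientation drifts slowly (angular random walk, sd 0.15 rad/frame) and
eccentricity fluctuates around its preset mean (AR(1), sd 0.05), creating
the per-track eccentricity variability that the morphology module
summarises. Imaging noise is Poisson shot noise plus Gaussian read noise
applied after an optional PSF blur. Everything is deterministic given the
scene seed.

Boundary handling reflects positions into the frame. This matters for
experiments that rely on net displacement: a directed track reflected off a
wall loses displacement, so scenes for long-term-movement experiments should
be large enough (or slow enough) that tracks rarely reach the border.

## The FDC network

The network is a random geometric graph (nodes uniform, edges to the two
nearest neighbours). Nodes oscillate sinusoidally with amplitude `A` (um)
and period `T` (frames); phase and direction vary smoothly across the field
of view, and each segment moves rigidly with the field value at its
midpoint, so the rendered deformation magnitude equals the node oscillation
(no interpolation shrinkage). The per-frame displacement of a sinusoid
sampled at integer frames has time-mean `(4/pi) A sin(pi/T)`, which
`fdc_amplitude_for_speed()` inverts: the published 0.27 um/min becomes an
amplitude, not a tuned constant. Filaments carry a "bead" intensity
modulation along their length so image gradients exist along both axes —
without it, optical flow could not see the along-filament motion component
(aperture problem).

The ground-truth flow field is rasterised with the same splatting as the
intensity image and is reported on the filament core (pixels above 15% of
peak); below that, blur tails of unrelated segments mix and the field is no
longer a meaningful "network motion".

Lymphocyte–FDC coupling adds `coupling_strength` times the locally smoothed
FDC displacement to each lymphocyte step, producing the positive local
speed correlation the microenvironment analysis measures; at the default
`coupling_strength = 0` the populations are independent.

# Preprocessing and units

The fixed preprocessing order is low-intensity cut-off, then Gaussian blur,
then per-channel min–max rescale; the order and parameters are recorded in
the movie's provenance because blurring measurably changes downstream
velocity estimates. Exact cut-off and blur values are not published;
defaults are 2% of the channel maximum and sigma 1 px, both configurable.
Constant channels normalise to zeros (with a warning) rather than dividing
by zero.

Velocity conversion: at 0.4 um/pixel and 20 s/frame the exact factor is
`0.4 * 60/20 = 1.2` um/min per px/frame, but the conventional published
factor is 1.23. When a track carries calibration metadata the exact
metadata factor is used (closed-loop recovery is then unbiased); the literal
1.23 is the default only for bare pixel-unit tracks. The discrepancy is
deliberate and surfaced rather than silently resolved.

# Tracking

Detection is band-pass filtering (small Gaussian minus local background),
local maxima with brightness-ranked suppression at the `separation`
distance, sub-pixel centroid refinement, and an integrated-mass filter;
masses are computed on the 8-bit-scaled raw frame so the published
`minmass = 5000` keeps its meaning. Linking is per-frame optimal bipartite
assignment (Jonker–Volgenant) minimising total squared displacement with a
per-link bound `max_speed` and birth/death dummies; a track missing up to
`memory` consecutive frames stays eligible for reconnection, and tracks
with fewer than `filter_frames` observed points are dropped. All defaults
are the published pixel-unit values (25 / 15 / 20 / 10 / 20 / 5000). Gap
imputation is linear interpolation with an explicit `imputed` flag.

# Movement features

The invariant representation per track is the (speed, acceleration
magnitude, turning angle) series at interior time points. Velocity uses
centered differences by default (the published convention; forward
differences are available and are what the generator calibration targets,
since generated step speeds are drawn per forward step). Turning angles are
signed, clockwise-positive in image coordinates (y down); a mirrored
convention would flip signs but leaves magnitudes, spreads and all
classification inputs unchanged. Zero-length segments have undefined
angles: they are set to 0, flagged, and excluded from min/max statistics
only.

The 15-entry feature vector is {mean, sd, min, max} of each of the three
series plus total, net and maximum distance, in a fixed documented order.
Min/max are taken after unit conversion (the choice is immaterial to any
ranking). Standardization statistics are always fitted on training folds
and applied to held-out data.

# Descriptive statistics

"Mean velocity per time frame" is the pooled grand mean over all steps;
"mean track median velocity" averages per-track medians. Group comparisons
use the two-sided Mann–Whitney U test (exact for small untied samples,
normal approximation with tie correction otherwise) at the published
significance threshold 1e-4. The diffusion check regresses mean net
displacement at lag tau on sqrt(tau).

# FDC optical flow

Dense flow is iterative pyramidal Lucas–Kanade: structure-tensor windows,
bilinear warping, per-iteration updates clamped to 1 px. Pixels are valid
only where the tensor has both texture energy and a bounded condition
number; textureless or dark pixels get zero flow and an invalid flag. The
aggregation window default (sigma 9 px) is deliberately large: at sub-pixel
motion amplitudes (~0.2 px/frame) the magnitude of a noisy flow estimate is
biased upward, and wide windows suppress that bias. This was calibrated on
synthetic network movies; the generator's stated world (analytic amplitude,
default noise) was never adjusted.

Patch speeds are the mean flow magnitude over a patch's valid pixels
(default patch 5 um), unit-converted exactly. A patch is "FDC-occupied"
when its mean intensity exceeds the 75% quantile of patch intensities;
shape-based exclusion of CD35-stained B-cells is *not* implemented — a
known limitation. The microenvironment analysis pairs each track step
within 8 um of an occupied patch centre with that patch's speed and reports
Pearson and Spearman correlations.

# Information-level classifiers

The four levels are: (1) logistic regression on the 15 standardized track
features; (2) 1D CNN on (v, a, r) series zero-padded to length 60 with a
padding mask excluded from pooling; (3) 2D CNN on 64x64 single-frame
patches; (4) 3D CNN on 16x64x64 video patches. The CNN architectures are
three conv blocks (filters 128/64/32 kernel 3 for level 2; 256/128/64
kernel 3x3 or 3x3x3 for levels 3–4; "same" padding), each with ReLU, max
pooling of size 2 and dropout (rate 0.25 — unpublished, configurable),
then concatenated global max and average pooling and a softmax head; L2
weight decay 0.001 everywhere. Level 2 trains with plain SGD (lr 0.001),
levels 3–4 with Adam (lr 0.001). Epochs and batch size are unpublished:
defaults are early stopping on a 10% train-split validation set, at most
100 epochs, batch 32.

No deep-learning framework exists in the supported environment, so the
package carries a small exactly-tested engine (im2col + BLAS matrix
multiplication; finite-difference-checked gradients; closed-form-checked
parameter counts). Training the full-width 2D/3D networks is not feasible
inside a CPU test budget; `build_model(filter_scale =)` scales the filter
banks for desk-scale experiments, and the test suite uses scaled models
with few epochs. A green scaled test establishes that the architecture,
training loop and evaluation are correct, not that full-width models were
trained.

Cross-validation: intra-patient is leave-one-movie-out; inter-patient is 3
folds partitioning patients with no overlap, seed-deterministic. Each fold
is fitted five times by default with different initialisations; training
folds are downsampled to 1:1 class balance. Patch sampling centres on a
detection with probability 0.5 and is uniform otherwise, so both cell and
context appear. `run_task()` reports sample-level AUC by default; the
unified pixel-level evaluation (below) is implemented and exercised, but
using it inside every CV fold would exceed any reasonable test budget.

# Pixel-level evaluation

Spatial models are scored with overlapping moving windows (borders always
covered); per-pixel scores are means over covering windows. Track-level
models paint each track's score on a disk (default radius 5 px — the width
is unpublished) around every track point, averaging overlaps. Remaining
blank pixels receive the score of their nearest scored pixel in (t, x, y)
with a configurable temporal weight (default 1 frame = 1 px) and a
deterministic tie rule (lowest t, then y, then x); the fill is exact
nearest-seed (verified against brute force) and idempotent, and never
changes scored pixels. AUC is computed over labelled pixels, optionally
excluding context-free pixels (all context channels below 5% of their
maximum) and subsampling deterministically for tractability. Pixels are
pooled within a fold rather than averaged per movie.

# Interpretability

LRP uses the epsilon rule on dense layers, the average-pooling branch and
the first (possibly signed-input) convolution, and the z+ rule on deeper
convolutions; max pooling routes relevance to its argmax. Relevance
absorbed by biases is tracked explicitly, so conservation holds as
`sum(input relevance) + bias relevance = explained logit` up to epsilon
leakage (bounded at 5% in the tests, observed ~1e-6). The exact LRP variant
used in the original analyses is unpublished; this rule assignment is
common practice. Level 1 is interpretable by design via its signed
coefficients, ranked by magnitude with canonical-order tie-breaking.

# DD-clustering

k-means (k = 2, >= 10 restarts, seed-deterministic) on standardized
selected movement features — by default net displacement and turning-angle
sd, the two features the T-vs-B logistic regression ranks highest; an
8-feature variant is supported because the published figure caption and
body text disagree (2 vs 8). The cluster whose centre has larger net
displacement is named "directed"; the rule is applied after clustering, so
restarts can never flip the semantics. Clustering is pooled across
phenotypes; compositions are reported per phenotype.

# What a green test does and does not establish

The generator emulates: phenotype-specific blob size/eccentricity,
heavy-tailed speeds with published means and medians, two-regime heading
persistence, a pulsating filament network at the published mean speed, shot
and read noise, and optional FDC–lymphocyte coupling. It does not emulate:
z-stacks and projection artifacts, photobleaching, fluid drift, densely
packed touching cells, staining variability across patients, or real
inter-patient covariate shift. Closed-loop recovery therefore validates the
implementation of the estimators, not the biological claims; inter-patient
"generalization" on synthetic patients is easier than on real ones.

# Numerical choices and degenerate inputs

* Constant frames normalise to zeros; empty detection frames return empty
  tables; empty groups, blank maps, single-class truths and unfitted models
  raise explicit errors.
* Assignment ties break towards the lowest track id; watershed ties towards
  the lowest (t, y, x); k-means label semantics are post-hoc.
* The ellipse fit estimates background from the patch border ring (robust
  when a blob's tails fill the patch) and flags blobs touching the border.
* Seeds derived from a base seed stay below 2^31.

# Known limitations

* The brute-force watershed fill is exact but O(blank x seeds); filling
  full-length movies is expensive (tests use clips).
* Optical flow on filaments without intensity texture underestimates the
  along-filament component (aperture problem); the generator adds texture,
  real CD35 recordings may not.
* The Imaris-comparison percentage adjustments, three-class tasks, 3D
  tracking, and reproduction of the published real-data AUC tables are out
  of scope.
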