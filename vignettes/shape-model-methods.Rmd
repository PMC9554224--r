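---
title: "Statistical shape modelling of macular OCT layer boundaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modelling of macular OCT layer boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octasm)
```

# The problem

Machine-learning models that discriminate multiple sclerosis (MS) or
neuromyelitis optica (NMO) from healthy controls (HC) using macular optical
coherence tomography (OCT) are starved for labelled volumes. `octasm`
implements a remedy: a 3D active shape model (point distribution model,
PDM) of the eight retinal layer boundaries that synthesizes new,
anatomically valid boundary stacks from a handful of training eyes, plus
the full validation machinery needed to decide whether the synthetic data
are usable — histogram similarity metrics, pairwise map-correlation
analyses, and a classification experiment in which synthetic data augment
an RBF-SVM's training folds.

The package works on *boundary geometry only*. Thickness maps — the
biomarkers actually used for MS/NMO discrimination — are derived entirely
from boundary positions, so no B-scan texture is ever synthesized or
needed.

# Data model

An eye is a `BoundaryStack`: heights (axial pixels, larger = deeper) of 8
boundary surfaces on a grid of 25 B-scans x 512 A-scans, spanning a 6 mm x
6 mm macular field, with laterality, class label and subject id. The
boundaries delimit, inner to outer, the mRNFL, GCIPL, INL, OPL, ONL, MEZ
and RPE layers; boundary 8 minus boundary 1 is the total retina. Validity
(enforced by the S4 validity method) requires finite non-negative heights
and non-crossing boundaries at every grid cell.

Heights are stored in axial pixels throughout; conversion to micrometres
happens in exactly one place, the thickness module, via the geometry's
axial pitch. The default pitch is 3.87 um/px, a configurable convention:
spectral-domain devices of this grid layout have an axial sampling near
3.9 um, but the exact value cancels out of every scale-free analysis and
only sets the units of thickness. All grids are 1-based, matching both R's
native indexing and the landmark convention below, so no index translation
layer exists anywhere in the package.

Left eyes are stored as acquired and flipped along the A-scan axis by
`normalizeLaterality()` so the nasal side lies on the right; every
thickness computation refuses stacks that have not been normalized.

# Landmarking

Each boundary on each B-scan carries 91 landmarks: the first at A-scan
column 1, the last at column 512, the 46th pinned to the macular centre
`x_mac`, and the rest spaced evenly on either side — 8 x 25 x 91 = 18,200
points per eye, giving a shape vector of length 54,600 (all x, then all y,
then all z, boundary-major). Because the centre is pinned, even spacing is
generally non-integral; landmark x positions are therefore real-valued and
boundary heights at landmarks are obtained by linear interpolation of the
dense boundary. Densification back to the full grid is piecewise-linear
interpolation through the landmarks; sampling that interpolant at its
knots returns the knots, which is the round-trip identity the tests
assert.

The macular centre is found automatically as the argmin of the
total-retina thickness map after 3 x 3 moving-average smoothing,
restricted to the central third of the grid; ties break deterministically
(smallest B-scan, then smallest A-scan) with a logged message. Automatic
localization by the thickness minimum is this package's convention — the
foveal pit is the unique global thickness minimum in normal macular
anatomy — and the smoothing window guards it against pixel noise. One
fovea is shared by all boundaries of a stack.

# The point distribution model

Training shapes are aligned by Procrustes analysis to the first shape as
reference. The default transform family is **translation only**: rotation
or scaling would change axial distances and thereby distort metric
thickness, which is the quantity every downstream analysis consumes;
translation leaves thickness exactly invariant. Rigid
(`translation+rotation`, closed-form Kabsch/SVD) and `full-similarity`
modes are available behind the `alignMode` flag for experimentation.

PCA uses the small-sample Gram trick: with n training shapes and a
54,600-dimensional shape space, the n x n inner-product matrix of centred
shape vectors is eigendecomposed; its non-zero eigenpairs are exactly
those of the full covariance, at a cost independent of the ambient
dimension. The tests verify this equivalence against brute-force
covariance eigendecomposition on small instances to 1e-8.

The retained mode count t is the smallest number of leading modes reaching
98% cumulative variance, capped at n - 1. Synthesis draws mode weights
independently as b_k ~ N(0, lambda_k) truncated at +/- 3 sqrt(lambda_k) —
the standard ASM plausibility box — reconstructs mean + P b, densifies,
and validity-checks the candidate (ordered boundaries, non-negative
heights, strictly increasing landmark columns). Invalid candidates are
rejected and redrawn, at most 100 attempts per accepted stack; the
acceptance rate is reported so a silently degenerate model cannot hide.
Synthesized shapes live in the aligned reference frame; no back-transform
is applied because thickness is translation-invariant. Three choices here
— the 98% variance rule, the truncated-Gaussian weight law, and rejection
for anatomical validity — are this package's design decisions where the
method family leaves them open; all three are explicit parameters or
documented behaviour rather than hidden constants.

# Thickness maps and histogram metrics

Layer thickness is the height difference of consecutive boundaries times
the axial pitch; the total retina is boundary 8 minus boundary 1. Maps are
kept at native 512 x 25 resolution for every metric; an optional bilinear
`resizeMapForDisplay()` exists for plotting only.

Histograms use a shared default grid of 2 um bins on [0, 400] um — wide
enough for any macular layer or total-retina map — with half-open bins,
the last bin closed, out-of-range pixels clipped into the end bins with a
warning, and frequencies normalized to sum to 1. Four similarity measures
are computed per pair: the Pearson correlation of bin frequencies, the
chi-square distance sum((H1-H2)^2 / H1), the histogram intersection
sum(min(H1, H2)), and the Bhattacharyya coefficient sum(sqrt(H1 H2)) with
Hellinger distance sqrt(1 - BC). Two numerical choices deserve note. The
chi-square distance is *asymmetric by definition* (its denominator is the
first histogram); the package preserves the asymmetry and skips bins where
H1 is zero, with an optional epsilon regularizer for users who prefer a
finite everywhere variant. The correlation of a histogram that is constant
over its bins is undefined and returned as `NA`, never silently 0 or 1.

## The t-test protocol and a statistical caveat

Real-versus-synthetic layer agreement is summarized with a two-sided Welch
t-test. A tempting protocol is to pool all 512 x 25 pixels of all maps as
independent observations; with tens of thousands of highly spatially
correlated "observations" per group, that test rejects for mean
differences far below any anatomically meaningful scale and its nominal
level is meaningless. The package therefore feeds the test *per-eye mean
thickness* values (one number per eye per layer), which are plausibly
independent across eyes; `twoSampleTTest()` itself is a generic Welch test
and accepts any samples a user prefers. This is the one place the package
deliberately deviates from a pixel-pooling description of the protocol,
for the documented statistical reason.

# Pairwise map comparisons

The spatial pattern of thickness — invisible to histograms — is assessed
by the peak zero-mean normalized cross-correlation (ZNCC) between map
pairs: the ZNCC is evaluated at every integer 2D shift whose overlap
covers at least 50% of the map area, each shift normalized by the
overlapping regions' own means and SDs, and the maximum is taken. The
overlap constraint and per-shift normalization are this package's
convention for an otherwise underdetermined "maximum of the
cross-correlation"; they make the score scale-free and bounded in [-1, 1].
The implementation is FFT-based (overlap sums are cross-correlations
against an all-ones mask, so each map needs one preparation pass and each
pair a single inverse FFT) and is verified against a brute-force shift
scan in the tests. Constant maps have no defined correlation and raise an
error. The mean absolute error is computed at zero shift only, because it
is defined as a direct thickness difference.

The three-way protocol compares a validation set (eyes never used in
model fitting), the training set, and a synthetic set: distributions of
peak ZNCC and MAE over all validation x training pairs (real/real),
validation x synthetic and training x synthetic pairs, plus the
Kolmogorov-Smirnov D between each pair of distributions. With 100
validation, 30 training and 100 synthetic eyes this yields 3000 / 10,000 /
3000 comparisons. Validation and training sets sharing a subject id is
refused as leakage.

# The augmentation experiment

Features are 15-dimensional: per eye, the mRNFL, GCIPL and total-retina
maps (the layers most discriminative for MS/NMO) are each projected onto a
5-component PCA basis fitted on vectorized maps. A binary RBF-SVM
separates HC from one disease class under stratified outer 5-fold CV with
nested tuning; confusion counts are pooled over the outer folds before
metrics are computed, so each configuration yields one confusion table
over all subjects.

Design choices where the experimental recipe is open, fixed here a priori:

* inner CV is stratified 3-fold over the real training fold; the grid is
  C in 2^{-5, -3, ..., 15} x gamma in 2^{-15, -13, ..., 3}; ties resolve
  to the first grid point, deterministically;
* features are standardized with training-fold statistics (computed on the
  real training fold, so all arms of a fold share one scaler);
* PCA bases are fitted per outer fold on the real training fold only —
  fitting on all data would leak test information into the features;
* per augmentation factor k, one shape model per class is fitted on the
  training-fold stacks and k x (per-class fold size) stacks are
  synthesized, mapped, and projected with the fold's PCA; synthetic points
  participate in every inner training split of the tuning search;
* the SMOTE baseline interpolates between 5 nearest same-class neighbours
  in the 15-D feature space, generating exactly the same number of points
  as the shape-model arm. No SMOTE implementation ships with the
  environment's R packages, so the package carries the classical
  algorithm itself (~20 lines, property-tested).

Test predictions are always made on real held-out subjects; all
configurations share one fold partition per seed; and provenance is
asserted at run time — `assertNoLeakage()` errors if any held-out subject
id appears among the subjects used to fit a PCA basis or shape model. The
test suite includes a deliberate-leak case that must fail.

# The cohort generator

Clinical OCT cohorts of this kind are not redistributable, so the package
ships a seeded generator of artificial "ground-truth" stacks with their
statistical structure, used by every test and by the acceptance script.
Per eye: boundary 1 is a flat reference surface plus a Gaussian foveal pit
(default depth 100 um, radius 0.6 mm) and a smooth undulation; each layer
adds thickness = class mean + a per-subject offset N(0, class SD) + a
smooth zero-mean spatial field + per-pixel roughness, floored at 1 um. The
default per-class layer means and SDs are the HC/MS/NMO profiles of the
clinical population the package emulates (e.g. GCIPL 76.6 +/- 2.8 um in
HC against 55.2 +/- 6.6 in MS and 56.2 +/- 8.9 in NMO — the
ganglion-cell thinning that makes these diseases detectable from OCT at
all).

Generator conventions worth knowing:

* the pit thins the three inner layers (mRNFL, GCIPL, INL), tapering them
  toward the pit centre as in real anatomy, and each tapered layer is
  renormalized so its *map mean* equals the configured class mean — the
  configured profiles are therefore exactly the population means of
  per-eye mean thickness, which is what the law-of-large-numbers tests
  and the t-test calibration rely on;
* the smooth field is a low-order 2D cosine series (order set by the 2 mm
  correlation length) with random coefficients rescaled to a 2 um
  pointwise SD — cheap, seedable, and dependency-free;
* per-subject RNG streams are derived by hashing the subject id with the
  master seed, so any subject can be regenerated bit-identically
  regardless of generation order;
* alternate cohort members are flagged (and stored) as left eyes so
  laterality handling is exercised end to end.

What the generator does *not* emulate: true spatial thickness profiles
(e.g. the GCIPL annulus and mRNFL arcuate pattern — layer fields here are
radially structured only through the pit), inter-layer thickness
correlations (the clinical total-retina SD of 12.8 um exceeds the 7.8 um
implied by independent layers; generated totals have the smaller spread),
segmentation artefacts, and axial curvature of the retina. Tests passing
on these fixtures therefore demonstrate that the *pipeline machinery* is
correct and that the model preserves the statistics the generator does
encode; they are not a clinical validation on real OCT.

# Problem sizes and determinism

The statistical suites run at the study's own scales where that is cheap —
5 training eyes and 100 synthesized per t-test replicate (20 seeds), the
30/100/100 pairwise protocol — and at 30 eyes per class for the
classification experiment, with augmentation factors 1, 2 and 4 over 10
seeds for the trend checks; larger factor sweeps (8, 16) are available
through the same interface. Every stochastic entry point takes an explicit
seed, derives any sub-seeds from its own stream, and restores the caller's
RNG state, so whole pipelines reproduce bit-for-bit from one master seed.

# Known limitations

* Independent truncated-Gaussian mode weights ignore any non-Gaussian
  structure of the training distribution; with 5-eye training sets the
  eigenvalues themselves are noisy, and synthetic between-eye spread can
  undershoot the real one (visible in the clinical profiles the generator
  copies).
* Translation-only alignment leaves residual tilt in the shape space; the
  leading mode of a small cohort often mixes tilt with thickness
  variation.
* The pooled-fold confusion table makes configuration comparisons
  paired but provides no fold-level dispersion estimate; run several
  seeds for that.
* Near-ceiling fixture classification: the default class profiles are
  separable enough that the augmentation experiment saturates near
  perfect accuracy, so augmentation gains on fixtures are small and tie
  heavy; the experiment's value on fixtures is mechanism verification,
  not effect-size estimation.
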