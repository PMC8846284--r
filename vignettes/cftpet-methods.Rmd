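---
title: "Methods: computer-aided classification of parkinsonian disorders from DAT PET"
author: "cftpet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computer-aided classification of parkinsonian disorders from DAT PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The diagnostic problem

Parkinson's disease (PD), multiple system atrophy (MSA) and progressive
supranuclear palsy (PSP) share parkinsonian motor signs but differ in
prognosis and management. All three involve loss of presynaptic dopamine
transporter (DAT) in the striatum, which PET with a DAT tracer such as
^11^C-CFT images directly. Single summary indices (putamen-to-caudate
ratios, whole-nucleus uptake) separate parkinsonism from non-dopaminergic
mimics well but discriminate poorly *between* PD, MSA and PSP. The premise
of this package is that the *spatial pattern* of subregional uptake — the
rostrocaudal gradient within caudate and putamen, the bilateral asymmetry,
the pallidal and midbrain levels — carries the differential signal, and
that a linear classifier over subregional features can extract it.

`cftpet` implements the full chain: MRI-assisted ROI segmentation, rigid
MRI-to-PET registration, equal-volume subregioning of caudate and putamen,
striatal-to-occipital ratio (SOR) and asymmetry-index feature extraction,
linear support-vector classification with leave-one-out cross-validation
(LOOCV), stage-stratified training strategies, and random-forest
region-contribution analysis. Because no imaging data are distributed with
the package, a synthetic phantom generator reproduces the statistical
structure the classifier assumes, so every stage is testable end to end.

## Quantities and conventions

**SOR.** For a subregion $s$ with mean uptake $\bar u_s$ and pooled
left+right occipital mean $\bar u_{occ}$,

$$\mathrm{SOR}_s = \frac{\bar u_s - \bar u_{occ}}{\bar u_{occ}},$$

the specific-binding-ratio convention standard in DAT PET (the occipital
cortex is essentially devoid of DAT, so it estimates the nonspecific
level). A `plain_ratio` alternative ($\bar u_s/\bar u_{occ}$) is provided
behind a switch because published group means are compatible with either
convention in magnitude; the default follows the dominant literature.
SOR is bounded below by $-1$ (uptake cannot be negative) and is exactly
invariant under global rescaling of the PET volume. Mean (not total)
uptake is used: the equal-volume construction makes totals and means
proportional, and means are independent of the scanner grid.

**Asymmetry index.** For a subregion measured on both sides,

$$\mathrm{AI} = \frac{\mathrm{SOR}_{high} - \mathrm{SOR}_{low}}
{\tfrac12(\mathrm{SOR}_L + \mathrm{SOR}_R)} \in [0, 2]$$

when both sides are nonnegative; AI is undefined (flagged `NA`, not an
error) when the two-side mean is not positive. AI is computed for the six
split subregions only; pallidum and midbrain contribute SOR features but no
asymmetry, mirroring how such tables are conventionally reported.

**Coordinates.** All world coordinates are millimetres in RAS orientation
(+x right, +y anterior, +z superior); voxel (1,1,1)'s center is
`origin + spacing/2`. Transforms are stored fixed←moving as
$p \mapsto R_z R_y R_x (p - c) + c + t$. NIfTI files with non-axis-aligned
or negative-diagonal affines are rejected rather than silently reoriented.

## The phantom generator

`generateSubject()` renders a paired anatomical volume, uptake volume and
ground-truth label map on a configurable grid (default 64³ at 2 mm). Ten
ellipsoidal ROIs (left/right caudate, putamen, pallidum, midbrain,
occipital) are mirror-symmetric about the mid-sagittal plane, pairwise
disjoint, and elongated along +y for the split nuclei so that anatomical
thirds are well defined. Geometry is expressed for a 128 mm reference field
of view and rescaled per axis, so smaller test grids keep their shape.

For each subject the generator draws, per split subregion, a bilateral SOR
level $s \sim N(\mu, \sigma)$ and an asymmetry $a \sim N(\mu_a, \sigma_a)$
truncated into $(-0.99, \infty)$ and $[0, 2]$ by redrawing, then realizes
side SORs as $s(1 \pm a/2)$ with the higher side assigned left or right by
a fair coin (group tables report only the magnitude of asymmetry, not its
side). Pallidum and midbrain draw one symmetric level. The PET plateau of
each subregion is $u_{occ}(1 + \mathrm{SOR})$, the occipital reference is
planted at $u_{occ}$, and i.i.d. Gaussian noise (default SD 0.05 at
$u_{occ} = 1$, i.e. 5% of the reference) is added. The MRI volume encodes
each region as `code × 100` plus Gaussian noise (SD 5) — the simplest
contrast from which a segmenter can learn all ten structures.

The default group profiles (`defaultGroupProfiles()`) plant the published
group-level SOR and asymmetry means/SDs for the six caudate/putamen
subregions in PD, MSA, PSP and normal controls — e.g. anterior putamen
SOR 1.13 ± 0.48 in PD versus 2.25 ± 0.74 in controls, and anterior-putamen
asymmetry 0.63 ± 0.38 in PD versus 0.25 ± 0.23 in controls. Pallidum and
midbrain levels are not published alongside them; the defaults (pallidum
0.40–0.50 in disease vs 1.0 in controls; midbrain 0.20–0.30 vs 0.50, SDs
of roughly half the disease–control gap) were chosen once as
literature-plausible values and are not tuned. The default cohort is 50 PD
+ 37 MSA + 20 PSP + 22 NC with early-stage fractions 22.0% / 45.9% / 40.0%
(11 + 17 + 8 = 36 early-stage of 107 patients). Stage is assigned by
drawing exactly `round(n × fraction)` early-stage subjects per group: the
training-strategy designs require the exact 36/71 split, which Bernoulli
assignment would almost never produce.

Two deliberate simplifications: subregional draws are independent within a
subject (real subregional SORs are strongly correlated through disease
severity — a flag for users: phantom cohorts are *harder* to classify than
the real cohort in this respect, because between-group mean differences are
the only signal), and plateaus are piecewise-constant over thirds (no
partial-volume blur, no scanner PSF). Passing tests therefore demonstrate
correctness of the machinery, not real-data accuracy.

`sampleCohortFeatures()` is a voxel-free mode of the same generative model:
it draws the per-subject SOR/AI values and emits the feature row directly.
Classifier null experiments and importance recovery use it (only the
feature distribution matters there); the voxel path is exercised by the
round-trip and partition checks.

## Segmentation

Two interchangeable backends satisfy one contract (all ten regions on the
input grid; missing regions flagged and warned, never fatal; constant
input → background map).

The **atlas backend** (default, zero training) stores one reference MRI
with its labels; a target is segmented by rigidly registering the
reference to it and propagating labels nearest-neighbor.

The **learned backend** is a compact neural voxel classifier: each voxel
is described by raw intensity, two box-smoothed context scales and its
normalized coordinates, and classified into 11 classes by a
single-hidden-layer softmax network (24 tanh units) trained by seeded
full-batch gradient descent with momentum. Training voxels are sampled
per class with replacement (1500 per class per volume) so tiny nuclei are
not swamped; the background keeps an 8× quota, half of it mined from the
boundary shells around bright structures where the smoothed features are
ambiguous. The per-epoch loss history is stored on the model and must
decrease. A full 3-D convolutional encoder–decoder would be
disproportionate for piecewise-constant phantoms on one CPU; the
multiscale-feature network keeps the same idea — classify voxels from
multi-resolution context — at desk scale, and reaches Dice ≥ 0.97 per
region on held-out phantoms. Exact score ties break toward the lowest
region code for determinism.

## Rigid registration

MRI-to-PET alignment is rigid (6 parameters) and maximizes histogram
mutual information (32 bins), the standard multimodal criterion. The
optimization is organized for robustness, because the MI surface of
piecewise-smooth volumes has local optima away from alignment:

1. **Capture.** At the coarsest pyramid level (mean-pooling factor 4) an
   exhaustive translation grid (±6 mm, 2 mm steps) and then a rotation
   grid (±5°, 2.5° steps) are evaluated — a few hundred cheap metric
   calls that land inside the attraction basin.
2. **Pyramid refinement.** Monotone compass (pattern) search at pooling
   factors 4, 2, 1, with steps halving from 2 mm/deg down to 1/32 mm/deg
   at native resolution. Pattern search accepts only improvements, which
   makes it reliable on the locally rough, quantized surface of a
   histogram metric; a 6-D Nelder-Mead simplex, tried first, stalled in
   false optima on roughly 1 trial in 10. At native resolution the metric
   uses a deterministic *edge-preferring* subsample: every voxel whose
   local gradient exceeds the 90th percentile plus a regular stride
   through the flat remainder. Flat voxels carry almost no alignment
   information, and a uniform random subsample was measurably biased
   (~0.5° residual); the gradient-weighted deterministic sample removes
   both the bias and the RNG dependence.

The identity is always kept as a candidate and the best final metric wins,
so registering a volume to itself returns the exact identity, and the
final metric can never exceed the initial one. On noisy 64³ phantoms,
random perturbations within ±5 mm / ±5° are recovered to about 0.1 mm /
0.1° (worst case in 20 trials ≈ 0.2 mm / 0.2°). Labels are always
resampled nearest-neighbor; the PET volume is never resampled — features
are read on the native PET grid to avoid smoothing uptake values.

## Equal-volume subregioning

Each caudate and putamen is split into anterior/middle/posterior thirds of
equal volume. Plain k-means on voxel coordinates does not guarantee equal
volumes, so the split is two-stage: k-means (k = 3, world-mm coordinates,
10 restarts, seeded) locates centroids; a balanced greedy assignment then
enforces sizes. Capacities are `floor(V/3)` plus one for the first
`V mod 3` clusters in anterior→posterior centroid order; voxels are
processed in decreasing margin between best and second-best centroid
distance and assigned to the nearest centroid with free capacity. Cluster
names (anterior/middle/posterior) come from the realized mean +y of their
voxels, ties broken by mean +z. The result is an exact partition of the
parent mask with a maximum size difference of one voxel, deterministic
given the seed. Coordinates-only clustering is used (not intensity):
named anatomical thirds must be positional to be comparable across
subjects.

## Classification

The reference classifier is a linear SVM with **squared hinge loss**,
one-vs-rest for the three diseases:

$$\min_{w, b}\; \tfrac12\|w\|^2 + C \sum_i \max(0,\; 1 - y_i(w^\top x_i + b))^2.$$

This objective is convex and differentiable, so it is solved exactly and
deterministically by BFGS with the analytic gradient — no stochastic
solver, no iteration-order sensitivity. No installed R package offers the
squared-hinge variant, hence the in-package primal solver; on separable
fixtures its decisions are cross-checked against an established hinge-loss
SVM in the test suite. Features are standardized to mean 0 / SD 1 using
training rows only (constant columns are centered and receive zero
weight); the cost parameter is selected by inner 5-fold stratified
cross-validation over a log grid $10^{-3} \ldots 10^3$, ties toward the
smaller (stronger-regularizing) cost. The default feature vector is the
SOR set (14 striatal, optionally +2 midbrain); asymmetry indexes can be
appended by a flag but are off by default, since the published feature
count (16 subregions) matches the SOR-only reading. Logistic-regression
and random-forest backends sit behind the same interface for algorithm
comparisons; only the SVM carries acceptance coverage.

LOOCV predicts each subject from a model trained on all others; the
augmentation pool (used by stage strategies) is checked by subject id
against the held-out subject — leakage is a structural error, not a
warning. Four stage-stratified strategies probe how advanced-stage (AS)
data helps early-stage (ES) diagnosis: (1) train on 71 AS + 35 ES, LOOCV
over the 36 ES; (2) LOOCV within ES; (3) train all AS, test all ES;
(4) train on a 36-subject AS subsample (seeded), test all ES. Which of the
paper-scale pools exist is determined by the cohort's stage assignment;
the strategy runner errors if a requested pool is unsatisfiable.

On phantom cohorts drawn from the realistic (heavily overlapping) group
profiles, multiclass LOOCV accuracy is typically 0.50–0.60 against a 1/3
chance level — clearly above chance, but below the published real-data
80.4%, as expected from the independence simplification noted above.

## Evaluation

Confusion matrices are stored predicted × true with a fixed class order.
Per-class metrics collapse one-vs-rest: sensitivity TP/(TP+FN),
specificity TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN); overall accuracy
is trace/total. Zero-denominator metrics are reported `NA` and flagged so
degenerate classifiers still produce reports. AUC is the Mann–Whitney rank
statistic with midrank ties over held-out decision scores. Percentages are
displayed at one decimal, rounded half away from zero (matching how
clinical tables are printed; base R rounds half to even). Reconstruction
utilities (`binaryAccuracyFromSensSpec`, `accuracyFromErrorCount`) rebuild
accuracies from printed sensitivity/specificity/class sizes and from error
counts, which is how the published summary tables are verified for
internal consistency. One known printing quirk: a published PPV of 77.7%
corresponds to 14/18 = 77.78%, which rounds to 77.8 — the recomputed value
is reported.

## Region contributions

Feature importance uses random forests (500 trees), mean-decrease-in-
impurity importances normalized to sum to one, averaged over 10 seeded
fits to stabilize the ranking (a permutation-importance switch exists).
Aggregation is exact summation: 14 per-side values → 7 bilateral values →
3 nucleus totals, displayed as percentages at one decimal. The
midbrain add-on question — does adding midbrain SORs to the striatal set
change multiclass accuracy? — is answered by LOOCV on the 16-, 14- and
2-feature sets of the same subjects and an exact McNemar test on the
discordant pairs: $p = \min(1,\, 2\,P(X \le \min(b,c)))$,
$X \sim \mathrm{Bin}(b + c, 1/2)$, with the continuity-corrected χ²
variant available for large discordant counts. The exact form is the
right default at cohort sizes near 100, where discordant counts are small.

## Numerical choices and degenerate inputs

* Seeds: every random draw flows from one global seed through named
  substreams via a 32-bit FNV-1a hash (`deriveSeed(global, stage, id)`),
  so removing one subject never perturbs another's draws.
* SOR truncation at $-0.99$ and AI truncation into $[0,2]$ are redraws
  with a warning; after 100 failed redraws the mean is clamped (reachable
  only with pathological profiles). Truncation shifts realized AI means
  below strongly-asymmetric profile means; cohort recovery checks
  therefore target SOR means, which truncation leaves essentially
  untouched at the default profiles.
* Regions with fewer than 3 voxels cannot be tripartitioned (error naming
  the region); one-sided label maps warn but remain representable, since
  degraded segmentations must be expressible.
* Tripartition of a 91-voxel region yields sizes {31, 30, 30} with the
  extra voxel going to the anterior cluster — the documented
  anterior-first capacity rule.
* All-zero/constant anatomical input yields an all-background label map
  with ten missing-region warnings rather than an error.
* Registration of a volume to itself returns the exact identity (identity
  candidate), and label resampling through the exact identity on the same
  grid is a voxel-for-voxel passthrough.

## Problem sizes in the shipped checks

The test-suite and acceptance-script experiments use: 64³ phantoms at 2 mm
(48³ for the pipeline smoke run); 3 training + 2 held-out phantoms for the
learned segmenter; 20 random rigid perturbations and 20 randomized
geometries for the registration and partition properties; 25 subjects per
group for cohort-mean recovery; 200 permutation replicates (n = 15) for
the classifier null; and 10 planted cohorts (n = 60) for importance
recovery. These sizes were chosen to make each property statistically
meaningful while keeping a full run on one CPU comfortable.

## Known limitations

* Phantoms have no partial-volume effect, no scanner PSF, no attenuation
  or scatter artifacts, and no head motion; segmentation and registration
  accuracies on them do not transfer to clinical data.
* Real-data accuracies (80.4% multiclass etc.) depend on a cohort that is
  not distributed; the package reproduces the *arithmetic* of the
  published tables and the *behavioral properties* of the method, not the
  headline numbers.
* Within-subject correlation of subregional uptake is not modeled.
* The learned segmenter is a stand-in at phantom scale, not a clinical
  segmentation tool.
* LOOCV over all 107 patients is assumed for the headline tables (the
  natural reading of the design); the assumption is noted here because it
  is not directly verifiable.
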