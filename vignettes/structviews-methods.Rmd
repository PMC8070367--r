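---
title: "Multi-view standardization of radiotherapy structure names: models and design"
author: "structviews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view standardization of radiotherapy structure names: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Every radiotherapy treatment plan carries a *structure set*: the contoured
organs-at-risk (OARs), targets (PTV) and planning helper structures a
physician delineated on the planning CT. The names attached to these
structures are free text — the same femoral head may be "LtFemoral Head",
"Left Fem" or "Fem hdneck Lt" depending on the physician, vendor and
clinic. Pooling plans across institutions for quality surveillance or
outcome modelling therefore requires mapping each structure to a standard
(TG-263-style) class automatically.

structviews classifies each structure into a fixed label set (prostate:
Femur_L, Femur_R, Bowel_Large, Bowel_Small, Bladder, Rectum, PTV, other;
lung: Esophagus, SpinalCord, Brachial_Plexus, Heart, PTV, other) using two
complementary *views* of the same object:

* **text view** — the physician-given name;
* **geometric view** — the 3D shape and location of the contoured volume
  inside the planning image.

Neither view is sufficient on its own. Names are highly informative but
ambiguous across clinics — the canonical failure is the bare label
"bowel", which means small bowel at some centers and large bowel at
others. Geometry disambiguates location but knows nothing about the
planning intent encoded in names (a PTV and the prostate occupy almost the
same voxels). The package implements two ways of combining the views and
the two single-view baselines they are judged against.

## The geometric view

For one patient, the bounding box of the planning image is computed from
the outer voxel corners (`computeBoundingBox()`). A fixed occupancy grid —
96 × 96 × 48 voxels by default — is stretched over that box, and a
structure's contour polygons are rasterized onto it
(`rasterizeStructure()`): grid voxel (i, j, k) is 1 exactly when its
centre lies inside (or on the boundary of) a filled contour polygon
assigned to z-slab k. Polygons are filled with the even-odd rule, so
annular contours keep their holes, and several contours in one slab are
OR-combined. The 96 × 96 × 48 bitmap is flattened to a binary vector of
length 442,368 in a fixed order (x fastest, then y, then z). Bony anatomy
is extracted from the CT by thresholding: HU strictly above 1300 → 1
(`extractBonyAnatomy()`), and can be concatenated to the structure vector
(length 884,736) to give the classifier skeletal context.

Design choices worth stating explicitly:

* Rasterization happens **directly at the target resolution** by
  voxel-centre membership, not at native CT resolution followed by
  pooling. The direct rule is deterministic and is verified voxel-for-voxel
  against a brute-force point-in-polygon oracle in the test suite.
* **Boundary centres count as inside**; the HU threshold is exclusive
  (exactly 1300 → 0). Nearest-neighbour resampling breaks exact half-way
  ties toward the higher index in x/y and the lower slice in z.
* The grid spans the full image box **per axis** (anisotropic voxels when
  the box is anisotropic). The alternative — isotropic voxels padding the
  short axes — changes only the geometry of the grid, not the pipeline,
  and is left to sensitivity analysis.
* Contours falling outside the image box are **clipped silently**: real
  plans contain couch structures and markers beyond the imaged volume.
* A contour with fewer than 3 points cannot enclose area and is skipped
  with a warning.

The resulting feature matrix is extremely sparse binary, so dimensionality
is reduced with **truncated SVD without mean-centering**
(`fitTruncatedSvd()`); centering would destroy sparsity and is not part of
the method. The decomposition is computed exactly from the symmetric
eigendecomposition of the smaller Gram matrix (n × n when n ≤ d), which is
deterministic at these problem sizes; each component's sign is fixed by
making its largest-magnitude entry positive so serialized models are
stable. The SVD is **fitted on training rows only**; held-out rows are
projected with the frozen basis, preventing leakage across
cross-validation splits. k = 100 components feed the image single view and
late integration; k = 50 is used inside intermediate integration (both
configurable; a k = 100 fit can be truncated to 50 with
`svdTruncate()` since the subspaces nest).

## The text view

Preprocessing is deliberately minimal — lowercasing only
(`preprocessName()`) — because abbreviations, digits and symbols carry the
signal in structure names. The classifier (`trainTextModel()`) is a
supervised mean-embedding model over hashed character n-grams: each
whitespace token is wrapped in boundary markers (`<`, `>`), its contiguous
n-grams for n in 2–5 (plus the whole wrapped token when longer than the
maximum n) are hashed into a 2^20-bucket space, the document vector is the
mean of the occupied buckets' 200-dimensional embedding rows, and a linear
softmax layer produces class probabilities. Training is plain SGD on
cross-entropy, 25 epochs, learning rate 0.5 decaying linearly to zero; all
randomness flows from one seed and training is bitwise reproducible on a
machine. These hyperparameters are package defaults in the established
range for short-text subword classifiers, exposed in the configuration; no
external constraint fixes them.

Two explicit fallbacks: an n-gram never seen in training embeds to zero,
and a name with *no* known n-grams yields the zero document vector and
hence the uniform class distribution — an out-of-vocabulary prediction is
visible as exactly uniform probabilities rather than an arbitrary class.

## Integration

* **Intermediate integration** concatenates the 200-dim document vector
  (first) and the 50-dim reduced geometric vector (second) into a 250-dim
  feature (`buildIntermediateFeature()`) and trains a single random forest
  (100 trees, √p feature subsampling, unlimited depth, seeded; `ranger`
  under the hood) with probability output.
* **Late integration** keeps the two single-view models separate and fuses
  their probability vectors per structure: element-wise average
  (`fuseAvg()`, still a distribution) or element-wise maximum
  (`fuseMax()`). MAX scores are deliberately **not renormalized** — the
  argmax is unchanged by renormalization and the raw maxima show which
  view asserted each class. Argmax ties break by label-set order, making
  predictions deterministic.
* Early integration (concatenating the raw 442,368-dim image vector with
  text features) is out of scope by design: the dimensionality imbalance
  makes it impractical, and it is absent from the package.

`trainPipeline()` / `predictPipeline()` orchestrate the stages per mode
(`text`, `image`, `intermediate`, `late_avg`, `late_max`, `mlb`), with all
stage seeds derived from one master seed.

## Evaluation

`computeMetrics()` reports macro-averaged precision, recall and F1 plus
accuracy (trace/total) from a truth-by-prediction confusion matrix.
Macro averages run over the **union of labels present in truth or
prediction** (not the full label set), and per-class ratios with zero
denominator count as 0. The union convention matters: on an external test
set missing one class entirely (e.g. a prostate cohort with no large-bowel
structures), the always-majority baseline is averaged over N = 7 labels,
not 8, and this is the only convention whose closed forms —
macro recall = 1/N, macro precision = a/N, macro F1 = (2a/(1+a))/N for
majority fraction a — reproduce the reference baseline rows the test suite
pins at two decimal places.

The majority-label baseline (`majorityLabelBaseline()`) always predicts
the most frequent training label ("other" on any realistic structure-set
cohort) and anchors the bottom of the metric range: any model worth
keeping must clear it by a wide margin on macro F1.

Splitting schemes mirror multi-center practice: stratified k-fold at
structure level (per-fold class counts within 1 of proportionality),
leave-one-center-out (`centerCrossValidation()`), and whole-center holdout
(`centerHoldout()`) so no center ever straddles train and test. Patient- or
center-level grouping for the k-fold case is available by splitting on
those ids instead of labels.

## The synthetic cohort generator

No clinical structure-set corpus is distributable with the package, so the
generator (`generateCohort()`) creates multi-center cohorts with the
statistical structure the pipeline assumes, and it is first-class, tested
code — the end-to-end claims are demonstrated on it.

* **Geometry.** Each patient is a 96 × 96 × 48 phantom at 4 × 4 × 5 mm
  (a body-scale 384 × 384 × 240 mm field of view): air background
  (−1000 HU), a soft-tissue body ellipsoid (0 HU), and bony landmarks
  above 1400 HU (vertebral cylinder; femoral-head spheres for prostate, a
  sternum bar for lung). Organs are ellipsoids with class-specific
  location/size priors, jittered per patient (centre sd 6 mm, size scale
  U(0.85, 1.15)); the PTV overlaps the disease site; "other" structures
  are random ellipsoids anywhere in the body. Contours are traced per
  slice as closed 24-gons.
* **Naming.** Each center fixes one preferred alias per class from an
  alias table (the prostate aliases are published real-world variants;
  the lung aliases are synthetic variants in the same style, labelled as
  such), then per-patient noise applies whole-string case flips (p = 0.15),
  substitution by another alias of the class (p = 0.10) and suffix tokens
  (p = 0.10). A configurable fraction of centers (default 0.5) is
  *ambiguous*: their convention maps one bowel class to the bare name
  "bowel", with the opposite convention at other ambiguous centers. This
  is the mechanism the fusion models must exploit — the text view cannot
  resolve "bowel" across centers, while the generated bowel centroids
  differ by construction.
* **Imbalance.** 8–12 "other" structures per patient against 7 (or 5)
  labeled ones make "other" the modal class (about 60% of structures),
  emulating the severe imbalance of real planning data.
* **Reproducibility.** All randomness derives from one master seed through
  named substreams (center profiles, per-patient naming, per-patient
  geometry, splits), so the manifest is byte-identical between runs and
  independent of whether geometry is generated.

What passing tests on this cohort do **not** show: real organs are not
ellipsoids, real HU textures and partial-volume effects are absent, real
naming noise is richer than three perturbation types, and real center
effects (protocol differences, scanner fields of view) are not modelled.
The synthetic benchmark demonstrates that the pipeline's machinery —
featurization, leakage-free reduction, fusion, center-aware evaluation —
behaves as designed under the assumed data-generating process, not that
any particular accuracy will be achieved on clinical data.

## Problem sizes and numerical choices

The package's own benchmark (test suite and `scripts/acceptance.R`) uses
40 centers × 5 patients (≈ 3,400 structures, ≈ 2,500 training rows),
trains on 30 centers and tests on 10 — a desk-scale cohort chosen so the
whole end-to-end run completes in minutes while keeping every pipeline
stage at its published dimensionality (442,368-dim features, k = 50/100,
250-dim intermediate vectors). Other fixed numerics: polygon
boundary tolerance 1e-9 in grid units; SVD rank guard at singular value
1e-10; probability sums validated to 1e-9; DICOM decimal strings written
at 4 decimals (coordinates round-trip within 1e-4 mm).

## DICOM I/O

The package writes and reads explicit-VR little-endian DICOM CT series and
RT structure sets with a minimal built-in codec — enough of the standard
for lossless round-trips of synthetic cohorts, verified in the tests
against an independent reader. Physician-given names are preserved
byte-for-byte with one documented caveat inherited from DICOM itself:
string values are space-padded to even length, so a name of even length
that genuinely ends in a space cannot be distinguished from its padded
form; the reader strips exactly one trailing pad byte. Only axial series
are supported (non-axial series are rejected with a clear error), and a
frame-of-reference mismatch between structure set and series warns and
keeps the record by default (multi-vendor exports are inconsistent), with
a strict mode available.

## Known limitations

* The geometric view compresses a 3D shape into top SVD components of a
  bitmap; fine shape semantics are lost, and this bounds image-only
  accuracy on subtle classes.
* AVG/MAX fusion weights both views equally; a weighted average would be
  the natural next step when one view is systematically stronger, and the
  fusion API accepts per-view weights for experimentation without making
  them part of the validated surface.
* Only OAR/PTV/other classes are modelled; GTV/CTV and derived structures
  fall into "other".
* The DICOM codec is intentionally minimal: one transfer syntax, axial
  geometry, no compressed pixel data.
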