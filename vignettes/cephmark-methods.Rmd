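---
title: "cephmark: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cephmark: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cephalometric analysis quantifies craniofacial skeletal relationships from
defined anatomical points (Nasion, Sella, the Gonions, ...) and is a routine
step before orthodontic treatment and orthognathic surgery. Marking the
points by hand in a 3D CBCT scan is slow and shows clinically relevant
inter-observer variability, which motivates automatic landmarking.

`cephmark` implements a complete single-stage pipeline:

1. volumes are resampled to 1.6 mm isotropic spacing;
2. a single-stack 3D hourglass network maps the volume to one activation
   grid per landmark;
3. each activation grid is decoded to a world coordinate by a thresholded
   center of mass;
4. the coordinates feed a cephalometric engine (46-landmark schema, 16
   characteristic measures) and an evaluation suite (Euclidean distance,
   SDR, Mann-Whitney U tests with Benjamini-Hochberg correction).

Clinical CBCT data cannot be redistributed, so the package ships a seeded
skull-phantom generator that makes every stage trainable and testable from
code alone.

# Heatmap encoding and decoding

A landmark at continuous voxel position $c$ is encoded as a Gaussian sphere
$h(v) = \exp(-\lVert v - c\rVert^2 / 2\sigma^2)$, truncated to zero beyond
$3\sigma$, with $\sigma = 1.5$ voxels by default. Two conventions deserve
comment:

* **$\sigma$ is in voxel units of the target grid.** On the 1.6 mm
  training grid, $\sigma = 1.5$ voxels corresponds to 2.4 mm, which is the
  conventional grid-relative interpretation in heatmap regression.
* **The peak is not renormalized.** The peak value reaches 1 only when the
  landmark falls exactly on a voxel center; a sigmoid output can represent
  any value in $(0,1)$, so no correction is needed.

Decoding zeroes all voxels below 50% of the channel maximum and takes the
intensity-weighted center of mass. The threshold suppresses diffuse
low-level activation that would otherwise bias the estimate toward the grid
center; channels peaking below `min_peak = 0.1` are reported absent. Both
values are configuration, not constants. For landmarks at least $3\sigma$
inside the grid, the encode-decode round trip is accurate to well under
half a voxel (0.8 mm on the 1.6 mm grid); this is the representation's
quantization floor and the natural lower bound on any downstream accuracy.

# Network architecture

The network is a single-stack 3D hourglass:

* stem convolution: 256 features, kernel 7, stride 2, group norm (8
  groups), ReLU — the only resolution change besides pooling;
* residual blocks of three convolutions (64, 64, 128 features; kernels 1,
  1, 3), each convolution followed by group norm and ReLU except the
  block's last, whose output is summed with the (1x1x1-projected when
  channel counts differ) shortcut before a final ReLU;
* a contracting pathway of residual blocks each followed by 2x2x2 max
  pooling, an expanding pathway of trilinear upsamplings each followed by a
  residual block, and skip connections summed at equal resolutions;
* a final 1x1x1 convolution with sigmoid and no normalization, one output
  channel per landmark.

Design points that the architecture description leaves open, and the
choices made here:

* **Depth.** The number of pooling levels is configurable (default 4).
  Depth controls the receptive field; with a stem stride of 2 and depth 4
  the deepest features see far beyond 100 voxels, enough for global
  context on both clinical grids (~150^3 at 1.6 mm) and the 48^3 phantom
  grid. This matters: distinguishing bilaterally symmetric landmarks (GoL
  versus GoR) requires context well beyond the local blob, and the
  phantom experiments below use depth 4 for exactly that reason.
* **Padding** is "same"-style (pad 3 for kernel 7, pad 1 for kernel 3), so
  resolution changes come only from declared strides.
* **Residual wiring.** The shortcut joins by elementwise summation before
  the block's final ReLU (sum-then-ReLU).
* **Output resolution** is half the input resolution (the stem's stride);
  heatmap targets are generated directly on this output grid (spacing
  doubled, origin preserved, output voxel $o$ at input voxel $2o$). Loss
  and decoding on the native output grid avoid a resampling of the
  predicted maps.
* **Initialization** is fan-in-scaled Gaussian, fully seeded. The head
  convolution is scaled down (factor $10^{-3}$) so initial logits sit near
  zero and the sigmoid outputs start around 0.5 — inside the open
  interval $(0,1)$ regardless of depth, and close to the regime BCE
  training moves through anyway.

# Training

Training follows a plain, fully deterministic reference loop: batch size 1
with full (augmented) volumes, masked voxelwise binary cross-entropy
(channels whose landmark is absent from the annotation contribute
nothing), AdamW with learning rate 0.001 and decoupled weight decay 0.01
(betas at the conventional 0.9/0.999), and model selection by the lowest
validation mean Euclidean distance, with early stopping after `patience`
epochs without improvement. Validation averages over landmarks present in
both reference and prediction; predicted-absent landmarks are counted and
reported as misses rather than folded into the mean with an arbitrary
penalty distance.

Augmentation applies, identically to image and coordinates: random crops
(per axis, the retained window length is uniform in [25%, 100%] of the
axis and the position uniform — one concrete reading of "crop up to 75%
per axis"), a rigid rotation in (-15, 15) degrees and translation in
(-10%, 10%) of the extent, a local elastic deformation (coarse grid every
8 voxels, zero-mean uniform displacements up to 2 voxels, trilinearly
interpolated; landmarks are transported by the first-order approximation
$c' = c - d(c)$, accurate to $O(\lVert d\rVert\,\lVert\nabla d\rVert)$),
and contrast/brightness jitter. With every range zero the operation is the
exact identity, which the tests assert.

# The phantom benchmark

The generator renders a dark background, two bright ellipsoidal shells
(cranial and mandibular), and a bright sphere at every landmark with a
parabolic radial profile so the landmark is the exact local intensity
maximum; Gaussian intensity noise is added last. Per case it draws
per-landmark anatomical jitter (SD 2 mm), a shared rigid perturbation
(rotation up to 5 degrees, translation up to 3 mm), and, optionally, a
cohort shift for two-cohort studies. Everything is deterministic in
`(seed, case_index)`.

The phantom is deliberately schematic: it tests that the learning
machinery works (geometry plumbing, loss masking, optimization,
decoding), not that the network handles real anatomy, scanner artifacts,
or annotation noise. Passing phantom benchmarks therefore says nothing
about clinical accuracy — reproducing the clinical numbers would require
the original restricted data.

Two benchmark choices deviate from the clinical defaults, for reasons the
phantom itself creates:

* **Network depth 4 (toy width 8).** On a 48^3 grid with eight identical-
  looking blobs, a shallow hourglass cannot see enough context to assign a
  blob to the correct channel; with depth 2 each channel degenerates into
  a generic blob detector whose center of mass is the blob centroid. The
  tests use stem width 8 with depth 2 for capacity checks (single-volume
  overfitting) and depth 4 for the end-to-end benchmark.
* **Milder augmentation.** The paper-scale crops (down to 25% per axis)
  are well-posed on full-head scans where any window carries rich context,
  but on an 8-blob phantom a small crop often contains a single anonymous
  blob — the channel assignment becomes ill-posed and training stalls at
  the blob-centroid solution. The phantom benchmark therefore trains with
  crops retaining at least 70% per axis, rotations within 10 degrees,
  translations within 5%, and 1-voxel elastic displacements. The clinical
  defaults in `train_config()` are unchanged.
* **Learning rate 0.01.** The clinical recipe's 0.001 step size is kept
  as the default, but on the 12k-parameter toy network the logits must
  travel several units from their near-zero start and the per-step
  movement under Adam is bounded by the learning rate; 0.01 reaches the
  same solutions in a tenth of the epochs on the phantom task. Benchmark
  settings live in `benchmark_train_config()`.

Problem sizes for the shipped benchmark runs (training-set-size study: 10,
20, and 40 phantoms, three seeds each, a fixed epoch budget; main run: 40
training / 10 validation / 10 held-out phantoms) were chosen so the whole
study runs on a single CPU in minutes.

# Cephalometric measures

The 46-landmark schema (16 bilateral pairs, 14 midline points; 12 dental,
9 facial-surgery, 25 skeletal entries) is a versioned built-in table. From
it the engine derives 16 characteristic measures in three families:

* **Point-to-point distances** (mm): anterior facial height (ANS-Me) and
  the left/right effective mandibular (Co-Gn) and midfacial (Co-A)
  lengths. Endpoints follow the McNamara convention, which names the
  measures but leaves the endpoints to the analyst.
* **Vector components** (mm): signed projections on the anterior axis of
  the Frankfort frame — Nasion perpendicular to A, Pogonion to Nasion
  perpendicular, the upper-incisor verticals, and the signed offset of
  each lower incisor edge from the A-Pogonion line. Implementing "vector
  components" as projections on the Frankfort anterior axis is the 3D
  generalization of the classical "mm anterior to Nasion perpendicular"
  reading.
* **Plane angles** (degrees): SNA, SNB, their signed difference, the
  mandibular plane angle (TLS plane through Me/GoL/GoR versus the
  Frankfort plane), and the Frankfort-versus-true-horizontal angle. SNA
  and SNB are computed as classical three-point angles; no plane
  construction exists for them.

The Frankfort frame fits a total-least-squares plane through the *visible*
Porions and Orbitales (any three suffice), orients its normal toward
Nasion (superior), takes the in-plane ear-to-orbit direction as anterior,
and completes the triad with `lateral = superior x anterior`. "True
horizontal" defaults to the scanner axial normal (0, 0, 1) and is
overridable; every other measure is rigid-motion invariant by
construction, and the tests verify this with random rigid motions.

Missing landmarks make the affected measures unavailable rather than
raising errors: absence is data. Removing one Porion still yields a frame
(three points); removing two kills all frame-dependent measures while
point-to-point distances and SNA/SNB survive.

# Evaluation statistics

Distances are plain Euclidean lengths in mm; the successful detection rate
is the percentage of distances at or below 2 mm (boundary inclusive), and
a measure is successful when its absolute reference-minus-prediction error
is at most 2 mm or 2 degrees. Distances above 10 mm are listed for manual
review but never auto-excluded — in the clinical workflow such cases were
adjudicated by radiologists, which a package cannot replicate
mechanically.

The Mann-Whitney U test uses midranks, exact enumeration when both samples
have at most 8 observations and no ties (where the full permutation
distribution is cheap), and otherwise the normal approximation with tie
and continuity corrections; tests verify exactness against brute-force
permutation and the approximation against `wilcox.test`. The
Benjamini-Hochberg step-up adjustment delegates to `stats::p.adjust` and
is applied across all landmark-level comparisons of one report — one
family per table; the family boundary is configuration because published
practice varies. Under a true null (identical cohorts), the tests check
that the BH-corrected discovery proportion at 0.05 stays at or below 0.10
over 200 simulated replicate evaluations.

Sample standard deviations (n-1 denominator) are reported throughout.

# Numerical conventions and degenerate inputs

* World coordinates are mm; continuous voxel indices put voxel centers at
  integer positions, so `voxel_to_world` is affine and exactly invertible.
* Resampled grid sizes use `round(size * spacing / target)` (minimum 1),
  keeping field-of-view drift at or below half a voxel per axis;
  out-of-field samples take the volume's minimum intensity (air).
* Landmark files always store world mm, never voxel indices, so
  annotations survive resampling; CSV absence is a missing row, JSON
  absence an explicit null.
* The TLS plane fit refuses fewer than three points or collinear points;
  `plane_angle` silently normalizes inputs within 1e-6 of unit length and
  rejects anything farther; three-point angles reject zero-length rays.
* BCE clamps predictions to `[1e-7, 1 - 1e-7]`; an all-masked target is an
  error ("no supervised landmarks") rather than a silent zero.
* The world frame orientation (LPS versus RAS) of input scans is treated
  as opaque header metadata: all measures except the true-horizontal angle
  are frame-invariant, and that one angle documents its dependence on the
  scanner axial convention.

# Known limitations

* The phantom has none of the hard parts of clinical CBCT: soft tissue,
  metal artifacts, device heterogeneity, anatomical pathology, annotation
  error. Benchmark numbers here are not clinical accuracy claims.
* Heatmap decoding is center-of-mass only; no sub-voxel quadratic
  refinement and no multi-peak handling (one landmark per channel by
  construction).
* Training is single-threaded reference code in R/C++ for full
  determinism; it is meant for phantom-scale experiments, not for
  training on hundreds of clinical volumes.
* NRRD support covers the subset the package itself writes (attached
  raw/gzip, little-endian float/double); DICOM series reading and
  Hounsfield calibration are out of scope.
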