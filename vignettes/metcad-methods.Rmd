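---
title: "Detecting brain metastases on 3D MR volumes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting brain metastases on 3D MR volumes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Brain metastases on contrast-enhanced T1-weighted MR images are bright,
mostly spheroid nodules; when the core is necrotic they enhance only at
the rim.  A volumetric study easily holds hundreds of slices, and small
enhancing vessels mimic small nodules, so computer-aided detection (CAD)
is used as a second reader: it proposes candidate lesions with
probability scores and a radiologist accepts or rejects them.  `metcad`
implements such a CAD chain end to end, together with the synthetic head
phantom used to test it.  This vignette records the model, the tunable
parameters, and the design decisions taken where the published
description of this family of systems leaves choices open.

## Pipeline

A case runs through five stages (`run_case()`):

1. **Normalization** (`normalize_intensity`).  MR intensity is relative,
   so every volume is rescaled by the single factor that brings the
   median intensity of a 3×3×3 neighborhood around a gray-matter seed to
   a fixed reference level (default 1000, arbitrary units).  A linear
   one-factor rescale preserves relative contrast — which the template
   matcher is invariant to anyway — and makes the clustering branch and
   the radiomic features comparable across cases.  The neighborhood
   median, rather than the seed voxel itself, keeps single-voxel noise
   out of the anchor.  The seed can be supplied manually (the clinical
   workflow) or chosen automatically (`auto_seed`): the in-volume voxel
   nearest the centroid of the largest above-threshold component whose
   intensity falls in that component's interquartile range.

2. **Brain extraction** (`ssrg`).  Seed region growing accepts a voxel
   when `|I(v) − I_seed| ≤ tolerance`; the spherical variant (SSRG)
   additionally requires *every* voxel within a sphere of radius `r`
   voxels (default 2) around a frontier voxel to satisfy the condition,
   which stops single-voxel leaks into structures of similar intensity.
   The intensity predicate itself is a design choice — only the
   all-voxels-in-sphere rule is inherited; we use the absolute deviation
   from the seed reference because it makes acceptance independent of
   visit order, so the mask is a deterministic function of the inputs
   (running-mean predicates are not).  Acceptance adds only the tested
   voxel, never the whole sphere: under these semantics
   `ssrg(r) ⊆ ssrg(r′)` for `r ≥ r′` and `ssrg ⊆ srg` are provable and
   are enforced as property tests.  Sphere membership is measured in
   voxel units by default (matching the per-pixel formulation);
   a spacing-scaled variant is a flag.  The default tolerance of 650
   normalized units is deliberately wide: the automatic seed may anchor
   the normalization in either gray or white matter, and 650 covers the
   gray/white intensity ratio from both anchors while still excluding
   background and strong enhancement.
   The raw grown region is post-processed by a morphological closing
   (dilation by `r + 1`, interior-hole filling, matching erosion),
   flag-controlled and on by default.  This recovers enhancing or
   necrotic lesions that the intensity condition excludes, *and* the
   narrow exclusion corridors that the spherical test carves around
   enhancing vessels — a plain hole fill fails exactly when such a
   corridor connects a lesion's cavity to the outside.  All containment
   and monotonicity properties are stated (and tested) on the raw masks.

3. **Candidate detection** (`detect_candidates`), two branches:

   * *Template matching* for small spheroid nodules.  Six binary
     spherical templates — solid and inner-hole (shell between 50% and
     100% of the radius, for rim-enhancing necrotic lesions) at
     diameters 2, 3 and 4 mm — are swept over the brain volume and
     scored by normalized cross-correlation over the full cubic window,
     `NCC = Σ(f−f̄)(t−t̄) / (n·σf·σt)`.  The window includes the
     template's zero margin: the dark surround carries the evidence that
     separates an isolated nodule from the interior of a larger bright
     structure.  Voxels above the NCC threshold are labelled under
     26-connectivity; each label yields one candidate at the label
     centroid with the template's radius and the label's maximum NCC as
     score.  Flat windows score 0 by convention (they are routine in
     background), and a 2 mm template is the floor: below that a
     template covers a single voxel at the 1 mm design resolution.
   * *K-means clustering* for large or irregular lesions.  In-mask
     intensities are clustered into seven classes (enhancing, four
     tissue/boundary classes, necrotic) by a deterministic 1-D Lloyd
     algorithm initialized at the seven evenly spaced quantiles — a
     seeded-random initialization would make the candidate set depend on
     an RNG state, which we refuse on reproducibility grounds.  The two
     extreme clusters are retained: the brightest captures enhancing
     lesions, the darkest necrotic cores.  Each extreme set is labelled
     twice: as-is, and after a radius-1 morphological opening that
     severs the thin tubes of vessels from lesions they touch (a fused
     lesion+vessel component would otherwise fail the shape gates).
     Labels pass three morphology gates — volume ≥ 65 mm³ (≈ a 5 mm
     sphere, where the template branch hands over), sphericity ≥ 0.4,
     extent ≤ 25 mm — and become candidates with the equivalent-sphere
     radius.  Sphericity uses the voxelized (face-counted) surface,
     under which a digitized ball scores ≈ 0.66, and the 0.4 gate is
     calibrated to that convention.  All three gates are calibration
     knobs, not published values; the extent ceiling is an upper bound
     we added because whole-tissue components (the white-matter core,
     ventricles) otherwise enter through the extreme clusters.

   The branches are merged (`merge_candidates`): candidates whose
   centroids lie within the larger of their radii collapse to the
   larger-volume one with the maximum score, in a deterministic order.

4. **Feature extraction** (`extract_features`).  Each candidate —
   resolved as its stored voxel set (cluster branch) or the equivalent
   sphere (template branch) — yields 30 features: volume, min, max,
   mean, SD, variance, skewness, kurtosis (non-excess), energy and
   entropy of the 32-level histogram; box-counting fractal dimension;
   14 co-occurrence (GLCM) statistics; and 5 run-length (GLRLM)
   statistics.  Quantization is min–max to L = 32 levels over the
   candidate set dilated by one voxel; first-order statistics use the
   candidate's own voxels, texture and fractal features the dilated set,
   so even a 2 mm candidate yields valid voxel pairs.  The GLCM pools
   all 13 unit-distance 3D directions at distance 1 into one symmetric
   matrix (per-direction averaging is noisier for regions of tens of
   voxels); the GLRLM accumulates maximal runs over the same 13
   directions, with gray levels entering the emphasis terms 1-based.
   Degenerate regions fall back to documented conventions (constant
   region: zero variance/skewness/kurtosis/entropy, energy 1; too-small
   fractal support: 0) and the vector carries a `flags` attribute.
   Every kernel is checked against a brute-force from-the-definition
   oracle on random ≤ 8³ regions.

5. **False-positive reduction** (`ann_train`, `predict`,
   `filter_candidates`).  A three-layer feed-forward network (30 inputs,
   15 hidden units by default, 2 outputs) with the scaled hyperbolic
   tangent activation `1.7159·tanh(2x/3)` in the hidden layer is trained
   by back-propagation (mini-batch gradient descent, momentum 0.9,
   learning rate 0.01, early stopping on a validation split).  The two
   output units pass through a softmax so the TP unit is a probability;
   raw tanh outputs are not.  The loss is class-weighted cross-entropy
   with inverse-frequency weights, because candidate sets are heavily
   FP-dominated.  Features are z-scored with training-set statistics
   stored inside the model.  The operating cutoff is chosen on training
   candidates as the smallest cutoff that maximizes FP removal subject
   to retaining at least 90% of true positives (`select_cutoff`); the
   tie-break toward the smallest cutoff risks the least TP loss on
   unseen cases for the same benefit.  The hidden width, epochs and
   protocol are free parameters here: 15 is the midpoint heuristic
   between layer sizes, and all are configurable and logged.

Two operating profiles share the detector: **algorithm A** (NCC
threshold 0.50) is the sensitive, FP-rich profile; **algorithm B**
(0.70) the conservative one.  The published description calls these
thresholds "experimentally determined" without printing them; 0.50/0.70
were chosen to reproduce the A-more-sensitive / B-fewer-FPs ordering on
phantoms and are configuration, not constants.  Because B's
above-threshold voxel set is a subset of A's, B's template candidates
are covered by A's — an invariant the tests check.

## Evaluation

`match_marks` assigns marks to nodules one-to-one, greedily by
descending probability then ascending distance; a mark hits when it lies
within nodule radius + 1 mm (one voxel at the design resolution).  The
hit criterion is unpublished for this family of systems; center-in-
sphere with a configurable margin is our choice and is reported with the
output.  `sensitivity_fp` reports sensitivity (optionally restricted to
nodules above a size floor) and FPs per case with controls in the
denominator; `froc_curve` sweeps the probability cutoff.  The JAFROC
figure of merit (`jafroc_fom`) is the probability that a lesion is rated
above a non-lesion mark, ties at ½, unmarked lesions at −∞; non-lesion
ratings are the highest FP mark per *normal* case, and unmarked normal
cases contribute no rating — the convention under which deleting an
empty control case provably leaves the FOM unchanged.  A variant flag
admits FPs on abnormal cases instead.  `jackknife_fom` supplies
leave-one-case-out pseudovalues and their SE.  Reader-study session
tooling and reader-vs-reader significance testing are out of scope.

## The phantom, and what passing tests mean

`generate_phantom` builds an ellipsoidal head: a gray-matter ellipsoid
with a white-matter core and two CSF-like ventricle pockets, inside a
detached brighter shell, with Gaussian noise (σ = 20 by default; a
Rician option exists since MR magnitude noise is Rician, but Gaussian is
the analytically tractable default).  Tissue levels
(0/150/400/600/1000 for background/CSF/white/gray/enhancing) are free
parameters — no intensity statistics are published for the clinical
cohort — ordered as contrast-enhanced T1 requires.  Nodules (default 5
per case, 3–10 mm, 30% rim-enhancing with necrotic cores) are placed by
rejection sampling with nodule–nodule overlap forbidden and
nodule–vessel contact allowed as a realistic hard case; their intensity
is drawn uniformly from [0.8, 1] × enhancing so template matches are
never degenerate.  Eight random-walk tubes at enhancing intensity play
the role of cortical vessels and sinuses, the dominant false-positive
sources for this kind of detector; the default count is set so the
phantom reproduces an FP-rich regime rather than a trivially clean one.
The dimmest nodule against gray matter has CNR 10 at the default noise.

The phantom is deliberately minimal: no tissue atlas, no bias field (a
multiplicative flag exists), no partial-volume modelling, no gyral
texture.  Passing the detection criteria here shows the chain is
implemented coherently — geometry, thresholds, features and classifier
fit together and the claimed invariants hold — not that clinical
sensitivity would match: real cohorts add coil inhomogeneity, motion,
anatomical texture and far more vessel clutter, and the published
headline numbers (87.3% sensitivity at 302.4 FP/case) come from such a
cohort and are not reproducible from synthetic data.

## Problem sizes and numerics

Test and acceptance runs use 96³ voxel volumes at 1 mm isotropic
spacing, 12 training cases, and 30 test cases (plus 10 controls in the
acceptance script) — sizes chosen so the whole suite runs comfortably on
one CPU while every nodule still spans a realistic voxel count.  K-means
runs at most 300 Lloyd iterations with a 10⁻⁶ relative-inertia stop;
NCC variance uses the population convention matching σ in its formula;
box counting requires at least three dyadic scales and clamps the fitted
slope to [0, 3]; all coordinates are 0-based in serialized form and
1-based inside R, with millimetre positions measured from the first
voxel centre.  Determinism is a contract throughout: phantoms, K-means,
training and matching are all seeded or seed-free, and identical inputs
give identical outputs byte for byte.

## Known limitations

* The clustering branch inherits K-means' sensitivity to the intensity
  mixture: its extreme clusters are only as meaningful as the contrast
  between enhancement, tissue and necrosis.  On low-contrast volumes the
  morphology gates do most of the work.
* A lesion fused with a vessel thicker than the opening radius, or a
  rim shell fragmented by noise, can still be lost by the cluster
  branch; the template branch only covers such lesions up to ~4 mm.
* The ANN is trained per-experiment; no pretrained weights ship with
  the package, because no clinical feature distributions do.
* `auto_seed` assumes the largest bright component is the head; it is a
  convenience for phantoms and pipelines, not a replacement for the
  manual gray-matter seed of the clinical workflow.
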