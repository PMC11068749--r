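---
title: "Methods: longitudinal CBCT volumetry of the mandibular condyle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal CBCT volumetry of the mandibular condyle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condylovol)
```

## The measurement problem

Degenerative joint disease of the temporomandibular joint (TMJ osteoarthritis)
remodels the mandibular condyle: bone is resorbed, mainly on the
anterior-superior joint surface, and new bone is deposited around the
resorption site. The *net* change in condylar volume between two CBCT scans
(`dV = Vpost - Vpre`) can therefore be small even while substantial turnover
is happening. This package measures the turnover components separately by
voxel overlap on one common grid:

* `Vpre`, `Vpost` — condylar-head bone volume at the two timepoints (voxels);
* `overlap` — voxels classified bone at both timepoints;
* `dV_minus = Vpre - overlap` — net decrease, bone **resorption**;
* `dV_plus = Vpost - overlap` — net increase, bone **deposition**;
* `dV = dV_plus - dV_minus` — exactly, by construction.

Voxel counts are the primary unit in every output; mm^3 equivalents
(`count x voxel volume`) are carried alongside, because surface-model volumes
and voxel counts need not agree exactly (see *Surface-model volumes*).

## The per-pair pipeline

`run_pair()` executes, in order:

1. **Auto-threshold** (`max_entropy_threshold`): the Kapur maximum-entropy
   threshold of the *pre-treatment* scan — the gray value maximizing the sum
   of Shannon entropies of the sub- and supra-threshold histogram partitions
   (256 uniform bins over the occupied range by default). The same threshold
   is *reused* for the post-treatment scan of the same joint, so both
   timepoints are segmented identically.
2. **Bone segmentation** (`segment_bone`): `intensity >= threshold`.
3. **Mandible selection** (`select_mandible`): one 26-connected component —
   the largest, or the one holding a seed point — removing the cranial
   structures (glenoid fossa, zygomatic arch) that share the field of view.
4. **Masked crop** (`crop_by_mask`): original intensities inside the mandible
   mask, a fill value elsewhere. The pipeline dilates the mandible mask by
   `crop_dilate = 4` voxels first: the partial-volume ramp at the bone edge
   carries the sub-voxel surface position, and a hard crop at the threshold
   surface would clip it, re-quantizing the edge (this measurably degrades
   both registration and re-segmentation; the shell lies far below the bone
   threshold and never enters a voxel count).
5. **Median filter** (`median_filter_3d`): radius 2 voxels, the pipeline's
   noise-suppression step; neighborhoods are truncated at grid edges rather
   than padded with invented values. Radius 0 disables it.
6. **Rigid registration** (`register_rigid`): 6-DOF voxel-based alignment of
   the post- to the pre-treatment mandible (details below).
7. **Resampling** (`resample`): the post-treatment volume is pulled onto the
   pre-treatment grid. Gray volumes use Catmull-Rom tricubic interpolation
   for measurement — the trilinear tent kernel smears blurred edge profiles
   enough to bias counts at off-center thresholds; masks always use
   nearest-neighbor.
8. **Common VOI** (`auto_head_voi` or manual boxes): one axis-aligned
   condylar-head box on the pre-treatment grid, from the union mask's
   superior portion down to the narrowest axial cross-section below the
   widest slice (the condylar neck waist; only *interior* minima qualify, so
   the mask's tapering bottom edge cannot masquerade as the waist), padded
   2 voxels laterally. The **validation VOI** spans `neck_height = 20`
   slices directly inferior with the same transverse extents and zero gap.
9. **Re-segmentation and measurement** (`measure_change`): both cropped
   heads are re-segmented with the saved threshold and the overlap
   decomposition is counted. The validation VOI is measured the same way;
   its disagreement fraction (`validation_delta / validation_total`)
   estimates residual segmentation/registration error in a region where true
   change is assumed negligible — the pipeline's built-in accuracy check.

## Registration details

* **Metric**: mean-squared intensity difference by default. The pipeline
  targets longitudinal pairs from one scanner under one protocol, where mean
  squares is markedly smoother near the optimum than a histogram-based
  metric; a Parzen-windowed mutual-information metric (`metric = "mi"`) is
  available for pairs with gray-value drift.
* **Pyramid**: 3 levels, shrink 4/2/1 with Gaussian smoothing 2/1/0 voxels;
  center-of-mass initialization; Nelder-Mead exploration at the coarsest
  level, then BFGS refinement at every level.
* **Robust second pass** (`trim = TRUE`): at the finest level the
  optimization is repeated excluding fixed voxels whose residual at the
  first optimum exceeds half the intensity range. Longitudinal pairs contain
  *genuine* change; without trimming, the lesion pulls the pose toward
  partially "explaining" it (about 0.12 degrees on noiseless phantoms —
  above what the validation logic tolerates).
* **Metric region**: the metric is evaluated only inside a 2-voxel-dilated
  mandible mask of the fixed image, keeping crop boundaries and empty
  background out of the similarity measure.
* The metric is evaluated densely — no stochastic sampling — so results are
  deterministic for given inputs and settings.

On noiseless, PSF-blurred phantoms the recovered pose is within about
0.03 degrees and 0.05 voxels of truth, and forward/reverse registrations
compose to identity within 0.1 voxel.

## Surface-model volumes

`mesh_volume()` reports the volume enclosed by the 0.5 iso-surface of a
binary segment: the field is zero-padded (so the surface always closes),
each inter-voxel cell is split into six tetrahedra (the Kuhn/Freudenthal
triangulation, consistent across cells), and the linear interpolant is
clipped exactly in each tetrahedron — for a binary field every tetrahedron
contributes a fixed fraction (0, 1/8, 1/2, 7/8, 1) of its volume by its
inside-vertex count; the 1/2 case follows from the mid-edge parallelogram
bisecting any tetrahedron. This equals the divergence-theorem volume of the
triangulated iso-surface without constructing it. Against analytic solids
the error is under 0.2% for a 20-voxel cube and under 0.1% for a
15-voxel-radius ball; against voxel counts, convex bodies agree within a few
percent. Voxel counts remain the canonical volume: they make the `dV`
identity exact; surface volumes are reported alongside only. This is also
why tabulated `dV`, `dV_minus`, `dV_plus` from surface-model workflows need
not satisfy `dV = dV_plus - dV_minus` to the last digit, whereas this
package's voxel counts always do.

## The synthetic phantom

`make_phantom_pair()` generates truth-labelled pairs: a condyle-like shape —
half-ellipsoid head (default semi-axes 8 x 10 x 6 mm) on an
elliptic-cylinder neck and cuboid ramus, plus a *disconnected* cranial slab
that exercises mandible selection — at 0.3 mm isotropic voxels on a
soft-tissue background (bimodal histogram, bone 1000 / background 100 by
default). Only the topology matters to the pipeline, not anatomical realism.

* **Digitization** is anti-aliased: each voxel's value is the fraction of
  3^3 aperture points inside the continuous shape, emulating the scanner's
  aperture integration. Crisp binary voxelization (supersample 1) aliases
  the surface; registering two crisp digitizations at different pose phases
  has a genuinely displaced optimum (~0.25 degrees / 0.3 voxels), which is a
  property of the aliased data, not of the optimizer.
* **Lesions are exact voxel cubes**, recorded before any degradation:
  resorption carves the `resorption_voxels` fully-interior head voxels
  nearest a seed on the anterior-superior joint surface; deposition apposes
  `deposition_voxels` fully-exterior voxels in compact layers at the pit rim
  (grown by iterative adjacency on the mandible — apposed bone has
  thickness; it is never a detached one-voxel shell). Choosing
  fully-interior / fully-exterior voxels makes the truth invariant to the
  threshold's exact level, which is what makes *exact* noiseless recovery a
  well-posed acceptance oracle.
* **Pose**: the post volume is digitized by mapping each aperture point
  rigidly into the pre frame and evaluating the continuous shape there (with
  lesions looked up at the nearest voxel cube) — never by interpolating the
  already-digitized pre volume, which would smear one image of the pair.
* **Degradation**: Gaussian PSF blur (SD in mm) and independent additive
  Gaussian noise on both timepoints; an optional `intensity_drift` offset on
  the post scan (CBCT gray values are not reproducible across scans; default
  0, magnitude deliberately uncalibrated).
* One seed controls all randomness of a call; identical specs generate
  bit-identical volumes.

The noiseless, unmoved phantom run uses `median_radius = 0`: a radius-2
majority filter provably deforms any carved concave lesion rim (a concave
edge voxel sees a majority-bone neighborhood), so exact recovery is only
defined with the noise filter disabled — on noiseless data it has nothing to
suppress.

## A known, quantified limitation: threshold level vs lesion edges

On the phantom's two-class histogram (~84% soft-tissue mass, ~13% bone), the
maximum-entropy criterion places the threshold near `background + 2.5
noise-SD` — at roughly the 13% level of the bone edge ramp, not the 50%
level. (This was cross-checked against an independent brute-force criterion
scan; it is the method's real behavior on such histograms, which the
threshold-reuse design then applies to both timepoints.) Because both
timepoints share the threshold, *pre-existing* surfaces cancel exactly in
the overlap decomposition. But every **new** edge a lesion creates — the pit
wall, the outer face of apposed bone — sits only in one timepoint, and with
a blur of SD one voxel its 13%-level surface is displaced ~1.1 voxels
outward from the true boundary. The measured pit therefore loses a one-voxel
shell over its wall area, and measured deposition gains one: with
cohort-mean lesion loads (111.74 / 39.02 mm^3), resorption is undercounted
by ~30-35% and deposition overcounted by ~50% on degraded phantoms, even
though the validation-region error stays well under 2% and pose recovery is
sub-voxel. No pit geometry escapes this (the shell-to-volume ratio is
~`3*delta/r` for any pit that fits the head). The same sensitivity of
segment extent to small threshold changes is a recognized property of CBCT
gray values. Consequences: the validation-region check and *relative* group
comparisons (the cohort statistics operate on ranks) are trustworthy, while
*absolute* lesion volumes at a tail-positioned threshold are biased in a
direction and magnitude this vignette quantifies; the acceptance suite
asserts the 10% recovery bound regardless and documents its failure rather
than hiding it.

## The synthetic cohort

`make_cohort_table()` emulates the study's condyle-level covariate
structure: 132 condyles of 66 patients by default — 10 patients with
*bilateral* erosion-and-pain (whose exclusion the clinical-factor stage must
get right), 45 erosion-and-pain condyles on distinct patients, 25
erosion-without-pain, 42 erosion-free. Continuous variables come from a
Gaussian copula with Spearman targets mapped through
`rho = 2 sin(pi rho_s / 6)`:

* Nonnegative quantities (`dV_minus`, `dV_plus`, durations, scan interval)
  use **moment-matched gamma marginals**: the reported group magnitudes have
  SD > mean (e.g. 111.74 +/- 135.54 voxels), which no truncated-at-0 normal
  can realize (its mean/SD ratio tends to 1 from above in the truncation
  limit), while a gamma reproduces the configured mean and SD exactly —
  which the generator's own law-of-large-numbers test requires.
* Bounded quantities use truncated normals: NRS rounded to 1..10 for painful
  joints (0 when pain-free), age truncated to 15..90.
* `dV` is **derived** row-wise as `dV_plus - dV_minus`, never generated; a
  rank-correlation target on `dV` itself is realized by splitting its
  implied covariance onto `dV_minus` (negatively) and `dV_plus` (positively)
  in proportion to their variance contributions, replacing any component
  targets for that variable.
* Age and scan interval are patient-level (shared by a patient's two
  condyles), which slightly dilutes their correlation targets on the full
  table; the targets are defined on the one-condyle-per-patient analysis set
  where the correlation stage runs.
* One default target matrix carries the reported correlation structure; the
  pain-duration/NRS entry is read as -0.079 (the source prints a value
  outside [-1, 1] plausibility there, a misplaced decimal point). The
  printed group SDs are used verbatim even where both groups print the same
  SD.

What passing tests on this cohort do **not** show about real data: the
copula is a convenience dependence structure, marginals are parametric, and
clinical factor labels are independent of outcomes unless effects are
planted — real cohorts confound.

## The staged analysis plan

`run_analysis_plan()` follows the study design: (1) erosion vs no-erosion on
all condyles; (2) pain vs no-pain within erosion-positive condyles; (3) each
binary clinical factor within erosion-and-pain condyles after excluding
patients with bilateral erosion-and-pain — clinical factors are
patient-level, so the analysis set must hold exactly one condyle per
patient; (4) the Spearman correlation matrix on that set. Group comparisons
use the Mann-Whitney U (exact enumeration over all `choose(n1+n2, n1)`
labelings when `n1 + n2 <= 12` — valid under ties — else the tie-corrected
normal approximation with continuity correction), with Kruskal-Wallis for
k groups and a Shapiro-Wilk gate recorded as the rationale for rank-based
tests. Tests are two-sided; significance is 0.05 per test with **no
multiplicity correction**, matching the study design; the report counts the
tests run so readers can judge. Missing values are dropped per stage
(complete-case) and logged; an empty stratum skips its stage with a warning,
never a crash.

## Problem sizes and numerical choices

Default phantoms are 80 x 96 x 84 voxels at 0.3 mm; unit tests use the same
anatomy on a half-scale 0.5 mm grid. The degraded-recovery experiment uses
20 seeds; the cohort power simulation 200 replicates of 132 condyles; null
calibrations 200-1000 replicates. Tie-breaks: the threshold takes the middle
candidate of a tied criterion plateau (a well-separated bimodal histogram
ties across the whole inter-mode range, and an endpoint would sit
arbitrarily close to one mode); largest-component selection takes the
first-encountered component on ties; geometric comparisons use a 1e-6 mm
tolerance. Degenerate inputs (constant volumes, empty masks, all-identical
samples, rank-deficient designs) raise informative errors rather than
returning numbers.
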