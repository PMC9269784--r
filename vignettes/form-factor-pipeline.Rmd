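---
title: "Form factors as shape biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Form factors as shape biomarkers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionshape)
```

## The problem

Indeterminate lung nodules found on CT are common, and only a small
fraction are malignant. `lesionshape` implements a morphological
(radiomics) screening pipeline for this setting: given binary 3D
regions of interest (ROIs) of lesions with known voxel spacing, it asks
whether simple *form factors* — dimensionless ratios of the lesion's
three principal dimensions — separate benign from malignant lesions,
and whether adding them to conventional size features improves a linear
classifier. The clinically interesting signal the pipeline is built to
detect is that benign lesions tend to be *flat* (platy: thickness much
smaller than breadth) while malignant lesions tend to be *compact*
(equant: all three dimensions similar).

Because patient ROIs cannot ship with a package, every stage is exercised
on two kinds of synthetic input with known ground truth: geometric voxel
phantoms (closed-form feature oracles) and moment-matched synthetic
cohorts calibrated to the published group statistics of two real
datasets, named here `SSR1` (a PET/CT series with anisotropic voxels,
38 benign / 71 malignant) and `LUNGx` (a public challenge dataset,
42 benign / 41 malignant).

## The eleven features

All features derive from a lesion's voxel set and its rectangular
*axis-aligned* bounding box (AABB) in physical mm. With the AABB side
lengths sorted descending as length $l \ge$ breadth $b \ge$ thickness
$t$:

| feature | definition | range |
|---|---|---|
| `max3ddiam` | largest pairwise distance between surface points | mm |
| `surfarea` | isosurface mesh area | mm² |
| `volume` | foreground voxel count × voxel volume | mm³ |
| `ael` | Angelidakis elongation $(l-b)/(l+b+t)$ | [0, 1] |
| `afl` | Angelidakis flatness $2(b-t)/(l+b+t)$ | [0, 1] |
| `aco` | Angelidakis compactness $3t/(l+b+t)$ | [0, 1] |
| `kel` | Kong elongation $1 - b/l$ | [0, 1) |
| `kfl` | Kong flatness $1 - t/b$ | [0, 1) |
| `mps` | maximum projection sphericity $(t^2/(lb))^{1/3}$ | (0, 1] |
| `sphericity` | $\pi^{1/3} (6V)^{2/3} / A$ | (0, 1] |
| `vdn` | volume density $V/(lbt)$ | (0, 1] |

The Angelidakis triple decomposes overall form into rod-like, platy and
equant fractions that sum to 1 exactly — an identity the package
enforces per lesion and the tests verify on random box dimensions.

Conventions that matter:

* **Masks are analysed in their own voxel lattice.** No resampling and
  no reorientation: the AABB is defined in image space, and resampling
  anisotropic data (e.g. 1.37 × 1.37 × 3.27 mm voxels) would change it.
  The z extent of a voxel is the inter-slice spacing, not the slice
  thickness. A consequence, deliberately accepted and asserted by a
  test, is that the form factors are *not* rotation invariant.
* **Box sides use full voxel extents**, `(index range + 1) × spacing`,
  not center-to-center distances, so a single-voxel or single-slice ROI
  has nonzero thickness and every ratio stays defined without special
  cases.
* **Physical mm, not voxel indices**, everywhere: with anisotropic
  voxels an index-space box would order the sides wrongly.

## Surface meshing and its numerical choices

The surface area comes from a closed triangulated isosurface at level
0.5, built by marching the six Kuhn tetrahedra of each grid cell
(marching-cubes family; the Kuhn subdivision tiles the lattice
consistently, so the mesh always closes). Two numerical choices deserve
explanation:

* **Gaussian pre-smoothing (σ = 1 voxel, default).** The midpoint
  isosurface of a raw 0/1 volume carries a staircase bias: on a
  voxelized ball of radius 20 voxels it overestimates the area by
  roughly 8 % (and by more for tetrahedral marching), and the bias does
  not vanish with resolution. Smoothing the indicator with a one-voxel
  Gaussian before extraction removes the bias almost entirely (ball
  area error ≈ 0.03 % at radius 20 voxels, ≈ 0.3 % at radius 40) while
  leaving flat faces in place. `smoothing_sigma = 0` gives the raw
  binary mesh, and a voxel-face area mode (`surface_area(mask,
  method = "voxel")`, exact for axis-aligned solids) is available for
  sensitivity analysis. ROIs thinner than the smoothing kernel fall
  back to the raw binary mesh automatically.
* **The maximum 3D diameter uses the *unsmoothed* mesh.** Smoothing
  rounds corners inward and would bias the diameter low; on the raw
  mesh the diameter is exact for solid cuboids (a single voxel yields
  its diagonal) and carries a small positive, resolution-vanishing bias
  on curved shapes, because the voxelized solid genuinely extends up to
  half a voxel diagonal beyond the analytic surface. The pairwise
  search runs over the deduplicated vertex set in compiled code.
* **Sphericity clipping.** For small, nearly equant lesions the
  smoothed mesh can underestimate the area by 1–2 %, pushing sphericity
  marginally above 1; such values are clipped to 1 with a warning
  rather than silently retained.

## Univariate screening

Each feature is compared between groups with the two-sided
Mann–Whitney U test: exact permutation distribution when both groups
have ≤ 25 observations and no ties, tie-corrected normal approximation
with continuity correction otherwise (delegated to
`stats::wilcox.test`, cross-checked in the tests against full
enumeration for small samples). Group summaries report mean ± sample SD
(n − 1 denominator), the convention for cohort tables.

Multiplicity is controlled with the Benjamini–Hochberg step-up at
FDR = 0.05, applied across the 11 features of one dataset (m = 11, one
correction per analysis). Applied to the published SSR-1 p-values
(shipped under `inst/extdata/`, with printed `"<0.001"` entries mapped
to a configurable stand-in of 0.0005 — any value below the printing
precision yields the same flags), this reproduces the published
significance pattern exactly: seven features flagged, the largest
significant p-value being 0.010.

A known discrepancy, documented rather than matched: on the published
LUNGx p-values the same standard step-up flags eight features (largest
p = 0.036), whereas the published table marks only six, leaving the
maximum 3D diameter (p = 0.029) and sphericity (p = 0.036) unflagged.
The original correction arithmetic on unrounded p-values cannot be
recovered from rounded table entries, so the SSR-1 pattern is the
reproduction target and the LUNGx flags are left to the standard
procedure.

## Multivariate models

Two fixed feature sets are compared: *base* (maximum 3D diameter,
surface area, volume) and *extended* (base plus `afl`, `aco`, `kfl`,
`mps` — the four form factors that discriminate in both datasets). The
classifier is a soft-margin linear SVM (libsvm via `e1071`, tolerance
1e-6, no class weights, deterministic), with the penalty chosen by grid
search over C ∈ {0.01, 0.1, 1, 10}; ties break toward the smallest C
(strongest regularization), which makes the whole stage deterministic.

Features are Z-scored per dataset, each dataset blind to the other,
using the population-SD convention (the choice between n and n − 1
denominators rescales all features by a common factor and therefore
cannot change linear-SVM predictions beyond an equivalent rescaling of
C; it is fixed for determinism). Evaluation follows four train/test
combinations — each dataset on itself by leave-one-out, and each
dataset on the other as a holdout — and reports accuracy as
"percentage (correct/total)".

One fidelity-over-hygiene decision: in the default leave-one-out path
the Z-score parameters are fitted once on the whole dataset and reused
in every fold, replicating the described per-dataset normalization
protocol. This leaks a small amount of information into the folds;
`strict_normalization = TRUE` refits the normalization inside each
training fold for users who prefer textbook hygiene. If a fold's
training set collapses to a single class (possible only in tiny
cohorts), that fold predicts the remaining class.

## Cutoff estimation

For each of the four discriminative form factors the package estimates
the threshold that maximises overall classification accuracy, on each
dataset separately, on the pooled data, and as the average of the two
per-dataset thresholds. Candidate thresholds are the midpoints between
consecutive distinct sorted values plus two sentinels (the
classify-everything-one-way rules, which make the search total and
guarantee at least majority-class accuracy). Accuracy ties break toward
the lowest threshold for greater-implies-malignant features and the
highest for less-implies-malignant ones, making the rule symmetric
under value negation; the tie rule is an artifact decision, since no
selection rule is published. Directions are fixed per feature — `aco`
and `mps` call malignancy above the threshold, `afl` and `kfl` below —
with an inference mode (by comparison of group means) for new features.
The implementation is tested against exhaustive split-rule search.

## Synthetic data: what it emulates, and what it does not

Two generators cover complementary needs:

* **Moment-matched cohorts** (`simulate_cohort`): every feature is
  drawn independently within class from a distribution whose analytic
  mean and SD equal the published group statistics exactly — beta
  distributions for the dimensionless features (bounded support honors
  their [0, 1] range; feasibility `sd² < mean(1−mean)` is validated at
  calibration time) and lognormals for the size features (positive,
  right-skewed, able to represent the benign volume group whose SD
  exceeds its mean). The built-in `SSR1` and `LUNGx` calibrations live
  as CSV data files under `inst/extdata/`, not as code constants.
  Because only marginal moments are published, features are sampled
  independently within class: cross-feature identities (the Angelidakis
  sum, volume–area consistency) do *not* hold per synthetic lesion, and
  the unknown real inter-feature correlations mean cross-dataset SVM
  accuracies can only be mimicked directionally, never reproduced.
* **Geometric cohorts** (`simulate_geometric_cohort`): per-lesion box
  dimensions are sampled, an axis-aligned ellipsoid phantom is
  voxelized, and all features are extracted from the mask, so every
  identity holds per lesion. The defaults encode the study conditions:
  lognormal length (mean 24 mm, SD 5 mm) and breadth-to-length ratio
  Beta(6, 2) in both arms; thickness-to-breadth ratio Beta(2, 6) for
  the benign arm and Beta(6, 2) for the malignant arm, affine-mapped
  into [0.2, 0.95] so every lesion stays several voxels thick at the
  default 1 mm spacing. Sizes are drawn identically in both arms, so
  class signal enters through shape (flat benign vs equant malignant);
  size features inherit a secondary signal because flatter lesions of
  equal length enclose less volume, which mirrors the real data, where
  malignant lesions are also larger.

Phantom voxelization places voxel centers so that lattice-commensurate
solids voxelize exactly (per axis, an even ideal span gets a half-voxel
offset, an odd span a center voxel), keeping centers off the analytic
surface and making the phantom bounding boxes exact oracles.

What passing tests show — and what they do not: the pipeline provably
recovers closed-form geometry on phantoms, reproduces the published
SSR-1 significance arithmetic, recovers published calibration moments,
and detects the flat-vs-equant signal end to end. None of this
establishes performance on real CT delineations, whose margins,
spiculation, inter-observer variability and feature correlations no
generator here emulates.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: phantoms up to ~90³
voxels (sphere of radius 40 voxels); 1000 replicate cohorts per dataset
for moment recovery; geometric-cohort experiments with 15 + 15 lesions
per cohort over 20 seeds; brute-force oracle comparisons at 100 random
cutoff instances (n ≤ 200), full Mann–Whitney enumeration up to group
sizes of 7, and step-up verification up to m = 12. These sizes were
chosen so the full suite completes in a few minutes on one CPU while
keeping Monte-Carlo standard errors well below the tolerances asserted.

## Known limitations

* Axis-aligned boxes make all form factors orientation dependent;
  principal-axis boxes are out of scope by design.
* Surface area (hence sphericity) on ROIs only a few voxels thick is
  dominated by discretization; the voxel-face mode is the more honest
  estimate there.
* The independent-marginals cohort generator cannot reproduce
  multivariate structure; conclusions about classifier *gains* on real
  data rest on the geometric generator's construction, not on
  calibration.
* Delineation (segmentation) is upstream of this package: masks are
  inputs, and no hole-filling or smoothing is applied to them.
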