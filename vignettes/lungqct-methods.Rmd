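---
title: "Quantitative CT metrics of airway, parenchyma and vessel remodeling: models and conventions"
author: "lungqct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT metrics of airway, parenchyma and vessel remodeling: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`lungqct` implements a quantitative-CT (QCT) severity analysis for
dust-induced occupational lung disease such as coal workers'
pneumoconiosis (CWP), exercised end to end on synthetic data with known
ground truth.  The pipeline has three imaging stages and a cohort
statistics chain:

1. **Airway structure** — a 1-D centerline tree is extracted from an
   airway lumen mask, branches are labeled anatomically (trachea, main
   bronchi, bronchus intermedius, the four lobar trifurcations, and five
   lobe subgroups of segmental airways), and four structural variables
   are measured per branch: bifurcation angle θ, hydraulic diameter
   D~h~ = 4A/Pe, wall thickness WT, and circularity Cr = 4πA/Pe².
2. **Parenchyma** — lung voxels are classified by Hounsfield-unit (HU)
   density: emphysema (< −950 HU), normal (−950 to −701), ground-glass
   opacity (−700 to −501), semi consolidation (−500 to −201),
   consolidation (−200 to 60), and an overlapping report-only fibrosis
   class (−500 to 0).
3. **Vessels** — total blood vessel volume (TBV) and the volume in
   vessels with local cross-sectional area at or below 1, 5 and 10 mm²
   (BV1, BV5, BV10), expressed as BVx/TBV.
4. **Cohort statistics** — logistic propensity scores, two-stage greedy
   one-to-one matching with a caliper, standardized-mean-difference
   (SMD) balance tables, expectation–maximization (E–M) imputation of
   missing structural metrics, Kruskal–Wallis tests with Mann–Whitney
   post hocs under Bonferroni correction, and Pearson correlation maps.

Severity enters as an ILO-style category label (0–4) attached to each
subject; the package never computes the category itself.  Clinical
segmentation of real DICOM data is likewise out of scope: masks are
inputs, and the synthetic generators below provide them with ground
truth.

# Synthetic volumes

`phantom_spec()` / `generate_volume()` build CT-like volumes from a tube
tree description.  Tubes are flat-capped cylinders along arbitrary
directions; the airway tree contributes a lumen (air, −1000 HU) and a
wall annulus (soft tissue, 0 HU), vessels a solid tube (+100 HU), and
every remaining voxel is parenchyma.  Parenchymal classes are assigned
by a largest-remainder integer allocation of the requested mixture
followed by a seeded random placement, so a mixture of 0.2/0.8 on a grid
whose voxel count is divisible by five is recovered *exactly* by the
classifier at zero noise.  Gaussian HU noise (default SD 20 HU, a
realistic reconstruction-noise scale) is added per voxel.  One integer
seed drives the whole draw; the stream order (class placement, then
noise in storage order) is fixed, so volumes are bit-identical across
runs.

The default airway tree has 31 branches: 26 labeled ones — trachea,
LMB/RMB, Bronint, the four lobar trifurcations, and 18 segmental leaves
with the anatomical per-lobe counts (sRUL 3, sRML 2, sRLL 5, sLUL 4,
sLLL 4) — plus five unlabeled intermediate stems where the anatomy
requires an extra bifurcation.  It is sized for a 96 mm field of view,
so branch lengths (5–18 mm) and radii (0.95–3.5 mm) are roughly half
clinical scale; this keeps unit tests fast while exercising every
topological feature.  The `phantom_spec_table1()` preset mimics a
thick-slice acquisition (0.75 × 0.75 × 3 mm); `resample_isotropic()`
brings such volumes to isotropic voxels (HU trilinearly, masks by
nearest neighbor) before geometry, because perpendicular-plane sampling
is ill-posed on 3 mm slices.

What the phantoms deliberately do **not** model: lung texture, scanner
physics (beam hardening, dose, reconstruction kernels), breathing state,
curved or tapering branches, and real airway-segmentation failure modes.
Passing tests therefore demonstrate that the *operators* are correct on
resolvable geometry, not that clinical segmentations of this quality are
available.

# Centerline extraction

The deliverable of this stage is a rooted 1-D skeleton.  `skeletonize()`
grows it by **iterative farthest-point geodesic front propagation**
rather than topological thinning: from the current skeleton (initially
the root voxel, the centroid of the most superior occupied slab), a
multi-source shortest-path transform over the 26-connected voxel graph
finds the geodesically farthest mask voxel; its path back to the
skeleton is traced, recentered, and accepted as a branch if it is long
enough.  This construction yields a tree directly — there are no cycles
to remove and no spurs to prune afterwards — and it is markedly more
robust than thinning on anisotropic, blunt-ended tubes.  Design
parameters, all in physical units:

* **Spur suppression.** A candidate path must exceed
  `max(min_branch_mm, 2 × r_attach + voxel diagonal)`, where `r_attach`
  is the distance-transform radius at its attachment point.  Shorter
  candidates are radial excursions toward the wall; their voxels join
  the propagation sources (so the tracer moves on) but never the tree.
  Consequence: a daughter branch shorter than about twice its parent's
  radius is undetectable by design.
* **Blunt-end guards.** Near a flat tube end the distance transform is
  depressed and the centroid-based centerline is ill-defined, so
  attachments landing within ~1.5 local radii of a traced segment's
  distal tip (or of the root end) are rejected as cap-corner spurs, and
  leaf tails are trimmed where the local radius falls below 60% of the
  branch interior radius.
* **Recentering.** Each traced path point moves to the centroid of its
  perpendicular lumen contour (16 rays, boundary at the 0.5 crossing of
  the trilinearly interpolated mask), three passes with smoothing.
  Without this step the minimum-cost path hugs the inner wall of bends
  and radius estimates collapse.
* **Junction clustering.** Daughters cut the junction corner and attach
  up to about two local radii before the true junction; attachment nodes
  closer along a segment than `max(2.5 voxel diagonals, 2.2 × local
  radius)` are merged into one node, so trifurcations are reported as a
  single node with three daughters.  The flip side is a junction
  *resolution* limit of a few voxel diagonals: on the cramped default
  tree at 0.75 mm voxels one 5 mm stem fuses into its neighbor (30
  instead of 31 branches, labels unaffected); at 0.5 mm the recovered
  topology is exact.

Branch **directions** are principal directions (SVD) of the centerline
between 1.6 parent radii and ~5 mm past the junction — the flare region
next to the junction and the cap region at the tip both bend the
extreme points.  The whole-branch orientation (`direction_global`) uses
the trimmed interior of the path.  On well-resolved phantoms (branch
radius ≥ 3 voxels, length ≥ 10 voxels) bifurcation and trifurcation
angles are recovered within 2°; on the deliberately cramped default
tree, junction scatter of 3–13° remains and is treated as a documented
limitation rather than hidden by coarser assertions.

# Cross-sections and the four structural variables

`extract_cross_sections()` samples planes every voxel along the *middle
third* of each branch (both ends are junction- or cap-contaminated),
perpendicular to a finite-difference tangent taken over ±2 mm so that
voxel-scale zigzag of the centerline cannot tilt the plane.  In each
plane 64 radial HU profiles are cast:

* the **inner (lumen) radius** is the first crossing of −500 HU —
  halfway between air and soft tissue, hence sub-voxel accurate on the
  interpolated profile;
* the **outer wall radius** is the half-maximum descent of the wall
  attenuation peak (FWHM convention): the first fall below the midpoint
  of the peak value and the minimum beyond it.  This is a convention,
  not a published operator; the reference workflow's contour rule is not
  public.
* per-ray radii are smoothed by a circular 3-point moving average before
  the polygon is built; without this the voxel-scale jitter of 64
  independent crossings inflates the polygon perimeter by several
  percent and biases Cr low.

Area and perimeters come from the sub-voxel polygon through the per-ray
boundary points (never from voxel-edge counting, which biases Cr low
systematically).  WT is the mean of (outer − inner) over rays, with
negative rays discarded.  Per-branch metrics are arithmetic means over
valid sections; a branch with no valid section (e.g. an
opacity-occluded airway) keeps an `NA` row, feeding the imputation stage
rather than raising an error.  Lobe subgroups aggregate their member
branches by the mean of D~h~, WT and Cr; θ is reported only for
branches with two daughters (three for trifurcations, as the mean of
the three pairwise angles).

Accuracy on zero-noise cylinders at 0.5 mm voxels: D~h~ within ~1.5%,
luminal area within ~3.5%, Cr ≈ 0.99, WT within a quarter voxel.  Walls
thinner than about one voxel are reported near the effective
point-spread width instead of their true value — the same physics that
makes thick-slice clinical data drop small-airway measurements.

# Parenchymal classification

The printed integer HU intervals have 1-HU gaps; `hu_class_scheme()`
extends them to continuous HU with half-open intervals at the half-unit
((−∞,−950.5), [−950.5,−700.5), …, [−200.5,60.5); fibrosis
[−500.5,0.5)).  This reproduces the integer table exactly and leaves no
measure-zero gaps.  Voxels above 60 HU remain in the denominator and
are reported as "unclassified"; fibrosis is counted *alongside* (never
subtracted from) semi consolidation and consolidation because its range
overlaps both.  Airway lumen and wall voxels are excluded from the lung
mask when an airway mask is available.  All fractions are ratios of
integer voxel counts, so the exclusive fractions plus the unclassified
fraction sum to 1 exactly.  `hu_histogram()` counts voxels per 1-HU bin
over [−1024, 200], clamping outliers into the end bins, and always sums
to the lung voxel count.

# Vessel volumetry

`vessel_csa_map()` reduces the vessel mask (a forest; each connected
component is handled separately, rooted at its thickest point) to a
recentered centerline, reads the local radius from the Euclidean
distance transform and assigns CSA = πr² of the inscribed circle; every
vessel voxel inherits the CSA of its nearest centerline point (exact
Euclidean search, ties to the lower linear voxel index).  Two numerical
conventions matter:

* the radius read-out takes the *maximum* of the distance transform
  over the 27-voxel neighborhood of a centerline point **plus 0.2
  voxels** — a correction calibrated on digitized cylinders, where the
  raw transform under-reads the inscribed radius by 0–0.4 voxels
  depending on how the tube sits on the lattice;
* BVx thresholds are inclusive (CSA ≤ x mm²), which makes
  BV1 ≤ BV5 ≤ BV10 ≤ TBV a structural invariant that the report
  asserts on every input.

On digitized cylinders the median CSA is within 10% of πr² once the
radius spans ≳ 8 voxels; blunt tube ends retain a few percent of volume
at depressed radii, visible as a ≤5% misclassified share in the
single-cylinder checks.  The volume-per-CSA curve is binned at 1 mm²
over (0, 20] mm².  True perpendicular-plane areas were rejected in
favor of the inscribed-circle convention because they are unstable for
vessels a few voxels wide, which dominate BV1/BV5.

# The synthetic cohort

`cohort_spec()` / `generate_cohort()` emulate a five-category severity
cohort of 380 subjects (110/108/54/10/98).  Confounders mirror the
demographic structure of a real pre-matching CWP cohort: age means
rising 67.1 → 75.0 years, heights falling 166.4 → 164.4 cm, smoking
prevalence 0.83–0.92, COPD prevalence 0.42–1.0, and an almost entirely
male population.  Imaging effects follow the reported directions —
thicker tracheal and Bronint walls, narrower TriLUL bifurcation, lower
Bronint circularity, unchanged hydraulic diameters, more
emphysema/consolidation/fibrosis, flat GGO, smaller BVx/TBV, lower
spirometric indices — with effect sizes that are *plausible, not
calibrated*: the source material reports group differences only
graphically, so slopes were chosen once at scales a pulmonary QCT
researcher would consider realistic (e.g. +0.06 mm tracheal wall per
category, −2° TriLUL per category, +0.035 emphysema fraction per
category) and are not tuned thereafter.  Two couplings give the
correlation analyses their expected physiology: FEV~1~/FVC falls with
the emphysema fraction, and BV5/TBV falls with the fibrosis fraction.
Missingness is missing-at-random conditional on category (3% → 15% per
structural metric from category 0 to 4), emulating opacity-obscured
airway segments.  `effect_scale` and `confounding_scale` interpolate
every category effect toward the category-0 value, giving exact null
configurations for calibration tests.

# Matching, balance and imputation

The propensity model is a logistic regression of group membership on
age, height, smoking and COPD; sex is excluded because matching empties
the female cells in cohorts like this.  `two_stage_match()` follows the
two-stage protocol: the smallest category (2) is matched to the largest
(0) by greedy one-to-one nearest-score matching within a caliper of 0.4
SD of the pooled scores (score scale by default; a logit-scale flag is
provided), then the retained category-0 subjects are matched caliper-free
against categories 1 and 4, yielding four equal-sized groups.  Greedy
order is descending treatment score with ascending-id tie-break —
determinism over fidelity to unspecified tool internals.

SMDs use the pooled-variance pairwise form for continuous variables and
the binomial-variance form for binary ones, with 0/0 defined as 0; the
multi-group summary is the arithmetic mean of all pairwise SMDs (a
maximum summary is available).  This convention reproduces the three
reproducible worked examples from the published balance tables exactly
at three decimals (smoking after matching 0.085; smoking and female
proportion before matching 0.171 and 0.111), which is the package's
validation of the convention.

One honest caveat that the test suite surfaces rather than hides: with
four groups of ~43, the sampling noise floor of the mean pairwise |SMD|
is ≈ 0.17 per covariate even for *identically distributed* groups, so a
single matched realization is not guaranteed to put all four covariates
below the conventional 0.1 threshold — published tables that do so
reflect a favorable draw.  At the default seed the package's matched
cohort achieves 0.07–0.14 across the four covariates; balance of the
procedure is better judged in expectation across seeds.

`em_impute()` is a standard multivariate-normal E–M: the E-step fills
each row's missing block with its conditional expectation given the
observed block (accumulating the conditional covariance into the
sufficient statistics), the M-step re-estimates mean and covariance,
and iteration stops when the largest parameter change drops below 1e-6
(cap 500 iterations; non-convergence warns and flags).  The
observed-data log-likelihood is computed every iteration and checked to
be non-decreasing; a numerically singular covariance is
ridge-regularized on the diagonal.  Observed entries are never altered,
and only the structural metric columns are imputed — demographics and
functional variables are complete by construction.

# Group inference

`kruskal_wallis()` delegates to the standard tie-corrected rank test
(χ² approximation, k−1 df); all-identical input returns H = 0, p = 1
rather than an error.  Post hoc Mann–Whitney tests run only when the
Kruskal–Wallis gate passes (p ≤ 0.05); p-values are exact by
enumeration when both groups have at most 8 observations and otherwise
use the normal approximation with tie and continuity correction.  The
Bonferroni family is the set of pairwise comparisons *within one
variable* (6 for four groups), matching the per-panel significance
stars of figure-style reporting; a global family across variables was
rejected because the stars being reproduced are per variable.
Significance stars map the adjusted p at 0.05/0.01/0.001/0.0001.
Correlation maps use pairwise-complete Pearson r on the matched,
imputed table; zero-variance variables yield `NA` entries.  A null
calibration (2000 synthetic null cohorts of 4 × 43) keeps the
Kruskal–Wallis rejection rate within [0.035, 0.065] at α = 0.05.

# Problem sizes and reproducibility

Unit tests run phantoms at 0.5–1.0 mm voxels on 24–96 mm fields of
view, the full 31-branch tree at 0.75 mm (128³) and 0.5 mm (192³), 100
seeded random vessel trees at 0.5 mm, cohorts at the default 380
subjects, and 2000-replicate null calibrations — sizes chosen so the
whole suite completes in a few minutes while every claim is exercised
at a resolution where it is meaningful.  All randomness flows through
explicit integer seeds (`with_seed` isolation, so library calls never
disturb the caller's RNG), and `scripts/acceptance.R` regenerates the
reproducible balance statistics from scratch.

# Known limitations

* Junction localization is limited to a few voxel diagonals; branches
  shorter than ~2 parent radii are undetectable by design.
* Walls thinner than one voxel are reported near the PSF width, not
  their true thickness.
* The inscribed-circle CSA is a convention; for strongly non-circular
  vessels it underestimates the true perpendicular area.
* Cohort effect sizes are plausible rather than calibrated to data;
  conclusions about statistical power on real cohorts do not transfer.
* Masks are inputs everywhere; no clinical segmentation is provided
  beyond a demonstration HU threshold for vessels.
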