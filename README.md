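# lungqct

Quantitative CT (QCT) analysis of structural and functional lung
remodeling in dust-induced occupational lung disease (coal workers'
pneumoconiosis and kin), built to run end to end on synthetic CT
phantoms and synthetic cohorts with known ground truth.

Severity is an ILO-style category label (0–4) carried by each subject.
For every subject the package measures, and for every cohort it tests:

* **Airway structure** from a lumen mask: a 1-D centerline tree
  (geodesic front propagation, recentered onto the lumen axis),
  anatomical branch labels (Trachea, LMB/RMB, Bronint, the four lobar
  trifurcations TriRUL/TriRLL/TriLUL/TriLLB, and five lobe subgroups of
  segmental airways), and per branch the bifurcation angle θ, hydraulic
  diameter D_h = 4A/Pe, wall thickness WT, and circularity
  Cr = 4πA/Pe² (1 for a circle).
* **Parenchyma** by HU density mask: emphysema (< −950 HU), normal
  (−950…−701), ground-glass opacity (−700…−501), semi consolidation
  (−500…−201), consolidation (−200…60), plus an overlapping fibrosis
  class (−500…0), with exact count-based fractions and a per-HU
  histogram.
* **Vessels**: total blood vessel volume (TBV) and the small-vessel
  shares BV1/TBV, BV5/TBV, BV10/TBV, where BVx is the volume in vessels
  with local cross-sectional area ≤ x mm² (inscribed-circle convention
  on the vessel centerline).
* **Cohort statistics**: logistic propensity scores on age, height,
  smoking and COPD; two-stage greedy one-to-one matching (caliper 0.4 SD
  of the score, then caliper-free); standardized-mean-difference balance
  tables (mean of all pairwise SMDs, |SMD| < 0.1 = balanced);
  expectation–maximization imputation of missing structural metrics;
  Kruskal–Wallis tests with Mann–Whitney post hocs under per-variable
  Bonferroni correction; Pearson correlation maps.

The synthetic generators are first-class, tested code: `phantom_spec()`
→ `generate_volume()` builds CT-like volumes (tube trees for airways
and vessels, parenchymal HU mixtures, Gaussian noise, NIfTI I/O), and
`cohort_spec()` → `generate_cohort()` builds a confounded five-category
cohort (380 subjects by default) with category-dependent imaging
effects and missing-at-random structural metrics.

## Worked example

```r
library(lungqct)

spec <- phantom_spec(seed = 11)            # 128^3 voxels, 0.75 mm, 31-branch tree
vol  <- generate_volume(spec)
tree <- label_branches(skeletonize(vol))
metrics <- aggregate_lobes(branch_metrics(vol, tree))
metrics[metrics$label %in% c("Trachea", "Bronint", "sRUL"), ]
#>      label theta_deg Dh_mm WT_mm    Cr n_sections
#> 1  Trachea     102.8  6.68 1.048 0.923          8
#> 3  Bronint      76.3  3.84 0.895 0.817          6
#> 13    sRUL        NA  2.46 1.121 0.411          6
```

The trachea row shows the carinal angle (the phantom's LMB/RMB split is
built at ~102°), a hydraulic diameter close to the phantom's 7 mm
luminal diameter, and a near-circular lumen; the sRUL row averages the
three right-upper-lobe segmental leaves, whose sub-voxel walls are
reported near the resolution limit — exactly the behavior that makes
small airways unreliable on coarse clinical scans.

```r
classify_parenchyma(vol)
#> <parenchyma_report> 2089130 lung voxels
#>   emphysema          0.0497
#>   normal             0.8503
#>   ggo                0.0400
#>   semiconsolidation  0.0400
#>   consolidation      0.0200
#>   unclassified       0.0000
#>   fibrosis           0.0600
```

The recovered fractions match the generator mixture to three decimals;
fibrosis overlaps semi consolidation + consolidation and is reported
alongside them.

```r
cohort  <- generate_cohort(cohort_spec(seed = 1))
matched <- two_stage_match(cohort)
matched
#> <two_stage_match> groups: 2 = 45, 0 = 45, 1 = 45, 4 = 45
smd(matched$cohort, c("age", "height", "smoking", "copd"))
#>   variable        smd balanced
#> 1      age 0.12938329    FALSE
#> 2   height 0.07147684     TRUE
#> 3  smoking 0.13563526    FALSE
#> 4     copd 0.07137170     TRUE

imputed <- impute_structural(matched$cohort)
posthoc_mwu(imputed$WT_Trachea, imputed$category, variable = "WT_Trachea")
#> <group_test> WT_Trachea: H = 40.123, p = 1.003e-08
#>  group1 group2   U        p_raw        p_adj stars
#>       0      1 742 2.934511e-02 1.760706e-01    ns
#>       0      2 542 1.489826e-04 8.938956e-04   ***
#>       0      4 333 4.269476e-08 2.561686e-07  ****
#>       1      2 784 6.578414e-02 3.947048e-01    ns
#>       1      4 446 4.936923e-06 2.962154e-05  ****
#>       2      4 687 8.724818e-03 5.234891e-02    ns
```

Matching equalizes the four groups at n = 45 and removes most of the
built-in confounding (pre-matching age SMD is 0.54); with groups this
small the mean pairwise |SMD| has a sampling noise floor of ≈ 0.17, so
individual covariates can land above 0.1 in any single realization —
see the methods vignette for the honest discussion.  The wall-thickness
post hoc recovers the built-in severity gradient: category 4 differs
from category 0 at four-star adjusted significance.

## Package layout

* `R/` — phantom and cohort generators, centerline extraction and
  branch labeling, cross-section geometry, HU classification, vessel
  volumetry, matching/SMD/E–M, group inference.
* `src/` — Rcpp kernels: exact anisotropic Euclidean distance
  transform, multi-source geodesic shortest paths, nearest-point search.
* `vignettes/lungqct-methods.Rmd` — models, conventions, numerical
  choices and limitations.
* `tests/testthat/` — unit, property and acceptance suites; all
  fixtures are generated in code.
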