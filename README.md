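# morphodiverge

Geometric morphometrics and multivariate trait analysis of inter- and
intraspecific morphological divergence, built for studies of bilaterally
symmetric vertebrate structures — the motivating case being skull shape and
external body measurements of three closely related Seychelles day-gecko
species. The package covers the full inference chain:

* **Landmark I/O** — 3D Slicer markups (`.mrk.json`, FCSV), TPS files, and
  CSV metadata/trait tables, assembled into validated datasets with
  left/right pairing structure and missing-landmark masks.
* **Missing-landmark estimation** — exact thin-plate-spline interpolation
  from the within-species Procrustes mean shape onto each incomplete
  specimen (`estimate_missing()`).
* **Superimposition** — generalized Procrustes analysis (`gpa()`): centring,
  scaling to unit centroid size CS = √Σ‖xⱼ − x̄‖², and iterative SVD-based
  rotation with reflections forbidden.
* **Bilateral symmetry** — object-symmetry decomposition
  (`symmetry_decomposition()`): joint GPA of each configuration with its
  relabelled reflection; downstream statistics use the symmetric component.
* **Permutational statistics** — multivariate linear models with sequential
  sums of squares under the randomized residual permutation procedure
  (`fit_rrpp()`), with effect sizes Z and permutation p-values, and post hoc
  pairwise distances between least-squares group means tested against a
  null model without the grouping term (`pairwise_groups()`), reporting d,
  UCL95, Z and p.
* **Allometric size correction** — Z = Y·(mean SVL / SVL)^b with log–log OLS
  slopes b per trait, global or per-species (`size_correct()`), then
  z-score standardization into the response matrix.
* **Ordination** — deterministic SVD-based PCA with both loading
  conventions, PC-extreme shape reconstruction, and a replicate-digitisation
  error check.
* **µCT segmentation protocol** — half-maximum-height global threshold
  (a − b)/2 + b from eroded bone/background seeds (shrink 10/30 voxels),
  slice-wise local Otsu (radius 5) with reslicing and 2-of-3 voting, and
  voxel/boundary-distance comparison of the two segmentations.
* **Synthetic data** — generators for landmark datasets, trait tables and
  two-material CT phantoms with recorded ground truth, used throughout the
  tests for parameter-recovery and calibration checks.

## Worked example

Simulate a cranial-scale dataset (120 landmarks: 54 bilateral pairs + 12
midline; three groups of 17/16/9 specimens with mean-shape offsets on the
scale of real interspecific skull distances), then run the full 3D
pipeline — missing-landmark estimation, GPA, symmetry decomposition,
RRPP model `shape ~ log_cs + sex + species + sex:species`, pairwise
species contrasts, PCA:

```r
library(morphodiverge)

sim <- simulate_landmarks(landmark_sim_params(seed = 42))
report <- run_3d_analysis(sim$dataset, run_config("3d_species", iter = 9999, seed = 42))
print(report)
```

```
ANOVA (full model):
            Df      SS      MS     Rsq        F       Z Pr(>F)
log_cs       1 0.00998 0.00998 0.05176  6.49452 3.56925 0.0005
sex          1 0.00614 0.00614 0.03185  3.99578 2.61510 0.0097
species      2 0.11964 0.05982 0.62056 38.92943 7.62385 0.0001
sex:species  2 0.00325 0.00163 0.01687  1.05833 0.64658 0.2679
Residuals   35 0.05378 0.00154 0.27896      NA      NA     NA
Total       41 0.19280      NA 1.00000      NA      NA     NA

Pairwise LS-mean distances (9999 permutations)
  pair        d    UCL95       Z     p
1  A:B 0.068401 0.038770  5.8348 1e-04
2  A:C 0.104780 0.045238  8.5855 1e-04
3  B:C 0.126230 0.042799 11.7047 1e-04

PC1 + PC2 variance: 65.8%
```

Species explain 62% of symmetric shape variation after size and sex; all
three pairwise mean-shape distances are significant at the permutation
resolution (p = 1e-4 at 9999 permutations). The generating truth for this
seed puts the pairwise Procrustes distances at 0.0654 / 0.1062 / 0.1257 —
the pipeline recovers them within 5%.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate_data.R` writes the synthetic 3D and 2D datasets
(TPS + CSV) under `results/data/`, `02_shape_3d.R` and `03_traits_2d.R`
run the 3D shape and 2D trait analyses (ANOVA, pairwise and PCA tables as
CSV report bundles), and `04_ct_protocol.R` compares the two µCT
segmentation-threshold protocols on a 128³ phantom.

## Documentation

The methods vignette
(`vignettes/morphometric-divergence-methods.Rmd`) describes the models and
their assumptions, the permutation scheme, the segmentation protocol, what
the synthetic generators do and do not emulate, numerical tolerances, and
known limitations.
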