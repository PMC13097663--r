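---
title: "Morphometric divergence analysis: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric divergence analysis: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodiverge)
```

## The scientific problem

`morphodiverge` implements a complete inference pipeline for quantifying
inter- and intraspecific morphological divergence in bilaterally symmetric
vertebrate structures — in the motivating application, the crania and
mandibles of three closely related day-gecko species endemic to the
Seychelles, together with external body measurements from several hundred
field-measured animals. Two data streams are analysed with parallel logic:

* **3D landmark shape data.** Homologous landmarks digitised on µCT-derived
  skull models (a cranial template of 54 bilateral pairs plus 12 midline
  landmarks, 120 in total; 24 per side on the mandible). The questions are
  whether species — and, within species, northern versus southern island
  groups — differ in shape once size and sex are accounted for.
* **2D linear trait data.** Nine head/limb calliper measurements plus body
  mass, with snout–vent length (SVL) as the size metric, on hundreds of
  geckos across the island bank. The same questions are asked of the
  size-corrected multivariate trait vector.

A third, upstream component reproduces the µCT segmentation-threshold
protocol used to build the skull models in the first place.

Because the package is developed and validated without access to the
original specimens, a first-class synthetic-data module generates landmark
datasets, trait tables and CT phantoms with the statistical structure the
analyses assume, with recorded ground truth. Every claim the test suite
makes about the pipeline is a claim about recovery of known truth from
these generators.

## Shape analysis

### Superimposition

Centroid size is CS = sqrt(sum over landmarks of the squared distance to
the centroid); it is the size variable removed by superimposition and
re-enters the models as the covariate log(CS). Generalized Procrustes
analysis (`gpa()`) centres every configuration, scales it to unit CS, and
iteratively rotates each to the running consensus (itself rescaled to unit
CS each round) until the summed squared change of the consensus falls below
1e-10, with a 500-iteration cap. Rotations come from the singular value
decomposition of the cross-covariance matrix with the conventional sign
correction on the last singular vector, so reflections are never used:
mirror symmetry is handled explicitly by relabelling (below), never by an
improper rotation. The consensus is initialised from the first specimen
after centring and scaling; a brute-force rotation-grid oracle verifies the
2D optimum in the tests.

Two deliberate simplifications, both standard for small shape variation:
no sliding semilandmarks (the templates use fixed landmarks only), and no
separate orthogonal projection to tangent space — statistics run on the
Procrustes-aligned coordinates, which at the within-genus shape distances
involved (Procrustes distances of order 0.1) differ negligibly from
tangent-space coordinates.

### Bilateral (object) symmetry

Skulls are bisected by the mid-sagittal plane, so each configuration
carries a symmetric component (the biological signal used downstream) and
an asymmetric remainder. `symmetry_decomposition()` builds the doubled set
{originals} ∪ {relabelled reflections}, superimposes all 2n configurations
jointly, and takes the symmetric component of a specimen as the mean of its
two aligned copies; the asymmetric component is the aligned original minus
the symmetric part, so the decomposition is exact by construction. The
reflection negates the first coordinate axis and swaps left/right labels,
but because the joint GPA absorbs orientation the axis choice is immaterial
— this is tested as a property (axis 1 versus axis 2 agree to 1e-6 after
matching). Only object symmetry is implemented; matching symmetry (paired
separate structures) is out of scope. The asymmetric component is computed
and returned but no fluctuating-asymmetry ANOVA is built on it.

### Missing landmarks

Occasional landmarks are undigitisable (damage, obstruction). They are
flagged in a mask — never encoded as sentinel coordinates — and estimated
before GPA by `estimate_missing()`: within each species, the reference is
the Procrustes mean of the complete conspecifics; the incomplete specimen
is superimposed on the reference by its present landmarks (translation,
scale, rotation); an exact thin-plate spline (kernel U(r) = r in 3D,
r² log r in 2D) is fitted from the reference's present-landmark subset to
the specimen's present landmarks; the reference positions of the missing
landmarks are pushed through the warp and back-transformed into the
specimen's original frame. Superimposing first means the spline models
shape difference, not pose. One pass is made (no iterative re-estimation),
and the reference uses complete specimens only — with groups that have at
least one complete specimen as a precondition. TPS reproduces affine maps
exactly, which the tests exploit as an analytic oracle; recovery error on
noisy synthetic specimens stays below three noise standard deviations at
digitisation noise up to 0.5% of centroid size.

## Permutational statistics (RRPP)

All hypothesis tests use multivariate linear models with sequential
(type I) sums of squares evaluated by the randomized residual permutation
procedure: for each term, the reduced model contains all preceding terms;
its residuals are permuted, added back to its fitted values, and the term's
F statistic (trace-based, using the full-model residual mean square)
recomputed. The observed arrangement counts as one permutation, so with
`iter` random permutations the smallest attainable p-value is
1/(iter + 1) — 1e-4 at the study-scale 9999 permutations, consistent with
"p < 0.001" reporting. A single permutation-index matrix is drawn from the
seed and shared across terms, making every result bit-reproducible from
(data, terms, iter, seed). Effect sizes Z are standard deviates of the
observed statistic within its permutation distribution, computed on log(F)
for F-type statistics (floored at 1e-12 before the log) and on the raw
scale for distances.

Term order matters for sequential SS and the source analyses do not print
theirs; the presets put covariates first (log CS, sex), grouping factors
next, interactions last (`3d_species`: log_cs + sex + species +
sex:species), and for the intraspecific 2D models sex + region +
region:island. Island-within-region nesting is encoded as region +
region:island dummy columns with aliased columns dropped, so the island
term carries (number of islands − number of regions) degrees of freedom.
A term that contributes no independent columns beyond its predecessors is
an error naming the aliased columns.

Post hoc pairwise comparisons (`pairwise_groups()`) work on least-squares
group means: model predictions at the observed combinations of the other
factors with covariates at their means, averaged per group level (for
crossed designs with all cells observed this is the textbook LS mean; for
nested or incomplete designs it averages only over observed cells). The
test statistic per pair is the Euclidean distance between LS-mean vectors —
for shape data, the Procrustes distance between covariate-adjusted group
mean shapes. Permutations resample the residuals of a null model fitted
without the grouping terms, so covariate effects are excluded from the
null distribution; each pair reports the observed d, the 95th percentile
of permuted distances (UCL95), Z and the permutation p-value.

## Allometric size correction (2D traits)

Each trait is corrected to a common body size by
Z = Y · (mean SVL / SVL)^b, where b is the OLS slope of log Y on log SVL
(natural logs; b is log-base invariant) and mean SVL is the arithmetic mean
of the analysis subset — the full dataset for interspecific analyses, the
conspecific subset (with re-estimated slopes) for intraspecific analyses.
SVL itself is excluded from the corrected variable set. Weight is corrected
with the same formula; its slope (near 3 on length-mass grounds) absorbs
the cubic allometry. "Scaling" of the corrected responses is z-score
standardization per trait; subsequent R² and permutation p-values are
insensitive to this choice, but PCA loadings are not, so both loading
conventions are reported. On the eigenvalue-scaled convention
(eigenvector × sqrt(eigenvalue)) applied to a standardized matrix the
loadings are correlations and cannot exceed 1 in magnitude; loading
magnitudes above 1 can only arise on covariance-scale data, so both are
emitted and neither is treated as a reproduction target.

## Ordination and error checks

`pca()` is an SVD of the column-centred matrix; eigenvalues are squared
singular values over (n − 1), and each eigenvector's sign is fixed so its
largest-magnitude element is positive, making output deterministic.
`pc_extreme_shape()` reconstructs landmark configurations along a PC axis
(mean shape + score × reshaped eigenvector), typically at the observed
score extremes. `replicate_error_check()` quantifies digitisation error as
the ratio of mean pairwise Procrustes distance among replicate digitisations
of the same specimen to the mean distance among distinct conspecifics;
ratios far below 1 mean replicates cluster more tightly than biology, i.e.
negligible landmarking error.

## µCT segmentation-threshold protocol

Two threshold definitions are implemented and compared on phantoms:

* **Half-maximum-height global threshold.** Rough bone and background seed
  regions are shrunk by morphological erosion with a Euclidean ball —
  10 voxels for bone, 30 for background, implemented via the exact distance
  transform (a voxel survives iff its distance to the nearest background
  voxel exceeds the radius; volume borders count as background). The
  threshold is (a − b)/2 + b from the mean gray values a (bone) and b
  (background) of the eroded seeds, and voxels at or above it are bone.
* **Slice-wise local Otsu with reslicing and 2-of-3 voting.** Every pixel
  of every 2D slice is thresholded by the Otsu criterion (maximal
  between-class variance on a 256-bin histogram over the slice's intensity
  range) computed over its square neighborhood of half-width 5, clipped at
  the slice border; the volume is processed in its original orientation and
  in two reslicings (top-to-bottom and left-to-right, axis permutations
  that are their own inverses), and a voxel is bone iff at least two of the
  three segmentations agree.

A literal per-pixel Otsu splits *unimodal* neighborhoods — pure background
noise, or pure bone interior — roughly in half, which is useless. The
implementation therefore applies a bimodality cascade based on Otsu's
effectiveness metric η = between-class variance / total variance of the
optimal split: pure-Gaussian-noise neighborhoods reach η ≈ 0.64–0.71 while
genuinely two-material neighborhoods sit above ≈ 0.87, so a neighborhood
with η < 0.78 defers to the slice-global Otsu threshold, and a slice that
is itself unimodal defers to the volume-global threshold, which is always
used as the last resort (volumes in this protocol contain both materials,
and the Otsu split remains between the material means even when bone is a
small voxel fraction, where an η gate would misfire). Neighborhoods holding
a single exact gray level are background. The neighborhood is square rather
than circular; on phantoms the difference is far below the reported
accuracy margins.

On two-material phantoms (means 180/60, Gaussian noise sd 10 — a
signal-to-noise ratio of 6 in the sense that the half-max threshold sits
6 noise-sd from either material mean), both protocols reach ≥ 99% voxel
accuracy and disagree on far less than 1% of voxels, only within about
2 voxels of the true boundary — the property that justified using the less
labour-intensive global threshold for production segmentation.
`segmentation_compare()` reports disagreement counts, the Dice coefficient
and the discrete symmetric Hausdorff distance between voxelized surfaces.

## The synthetic-data generators

`simulate_landmarks()` builds a mirror-symmetric template (left block,
mirrored right block, midline at x = 0, scaled to unit CS) and, per
specimen, adds mirror-symmetric tangent-space offsets for group, sex and
allometry (allometry enters only through an allometry vector times
log-size, applied to the unit-size template, so shape effects are size-free
by construction), mirror-symmetric digitisation noise, independent
asymmetric noise, and finally a random rotation, translation and scaling by
a lognormal size. Defaults mirror the motivating 3D study: 54 pairs + 12
midline landmarks; groups of 17/16/9; group mean-shape offsets of 0.066 and
0.107 Procrustes units (the scale of the study's interspecific cranium
distances); digitisation noise 0.2% and fluctuating asymmetry 0.1% of CS;
missingness completely at random at 0.3% (about 15 coordinates across 42
specimens of 120 landmarks, matching the study's 14), capped at 20% per
specimen. The generator records the template, every effect vector, and the
pairwise Procrustes distances between true group mean shapes.

`simulate_traits()` draws log Y = log a + b log SVL + species + sex +
region + island + N(0, σ²) with per-trait slopes between 0.7 and 1.1
(Weight 2.9), intercepts placing typical gecko trait sizes at SVL = 60 mm,
σ = 0.05, and species sizes 246/206/115. Island effects are centred within
each region so that a zero region effect is exactly zero at the regional
level — without this, random island draws would leak into regional means
and the "island-level structure without regional structure" scenario could
not be generated cleanly. `simulate_phantom()` voxelizes ellipsoids and
tubes at the bone intensity over a uniform background and adds Gaussian
noise.

What the generators do *not* emulate — and hence what passing tests cannot
show about real data: realistic skull geometry and landmark covariance
structure (effects are isotropic random directions, real shape change is
highly structured), phylogenetic or spatial autocorrelation among islands,
measurement-device quirks (calliper rounding, scanner beam hardening),
observer-specific digitisation bias, and non-lognormal size distributions.
The tests establish that the algorithms are correct and calibrated, not
that the biological conclusions of any particular dataset are right.

## Numerical choices and degenerate inputs

* GPA tolerance 1e-10 on the consensus change, 500-iteration cap (real
  shape data converges in a handful of iterations; unstructured random
  configurations can approach the tolerance slowly); zero centroid size is
  a degeneracy error.
* Rotation ties (rank-deficient cross-covariance) resolve deterministically
  through the SVD sign convention, with a warning when the optimum is
  genuinely ambiguous.
* TPS systems are solved exactly (no smoothing); degenerate (collinear /
  coplanar) control configurations are errors, as are specimens with fewer
  than D + 2 present landmarks.
* Permutation p-values compare with a 1e-12 relative tolerance so exact
  ties in enumeration tests count as ties; constant response columns
  contribute zero SS; a degenerate permutation distribution (sd 0) yields
  Z = 0 with a warning.
* The trait slope-recovery checks run at the pooled interspecific SVL
  spread (lognormal sdlog 0.25, the scale of a 40–120 mm adult sample);
  at much narrower size ranges the OLS slope's sampling error alone
  exceeds the 0.02 recovery bound, which is a property of the design, not
  of the estimator.
* Problem sizes in the test suite and acceptance script are chosen for
  desk-scale runs: 200 random GPA datasets, 500 null RRPP simulations at
  199 permutations, 100-replicate TPS recovery, a 128³ phantom, and
  study-sized end-to-end runs (42 × 120 landmarks, 567 × 10 traits) at up
  to 9999 permutations.

## Known limitations

* Sequential SS means reported non-final terms depend on the preset term
  order; the order is configurable but results are only comparable across
  runs with the same order.
* LS means average over observed factor combinations; with severely
  unbalanced nested designs they are estimable but not identical to
  textbook population-marginal means.
* The half-max protocol needs seed regions that survive their erosion
  radii; on small volumes or thin objects the 30-voxel background shrink
  can empty the seed, which is reported as an error advising a smaller
  radius.
* Only object symmetry is supported; no mesh processing (surface
  extraction, simplification, mesh-based Hausdorff distances) is included.
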