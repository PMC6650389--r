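---
title: "morphoscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morphoscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`morphoscreen` turns phase-contrast frames of antibiotic-treated bacteria
into a ranked list of strains whose morphological dynamics deviate from
the wild type, and clusters those deviants into response archetypes. This
vignette explains the generative model behind the synthetic screens, the
statistical machinery of every stage, the tunable parameters, and the
choices we made where the design was genuinely open. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. What the synthetic-data generator emulates

Real screens image liquid cultures in 96-well glass-bottom plates at three
time-points after β-lactam addition. Under cefsulodin-like action, rod
cells elongate, develop mid-cell bulges ("deformed"), round up, and lyse
into low-contrast ghosts. The generator reproduces the *statistical
structure* of such data at two levels.

**Frame level.** Cells are drawn as spherocylinders (rods), ellipses
(round cells), rods with a circular mid-cell bulge (deformed), or
irregular low-contrast ghost outlines (lysed), painted dark on a bright,
gently shaded background with a bright halo rim around intact cells, plus
additive Gaussian noise, quantized to 16 bits. There is no optical
point-spread model: the dark-body/bright-halo convention is sufficient to
exercise enhancement, thresholding and pruning, which is its purpose.
Default geometry (pixels; about 0.16 µm/px at 40×): normal rods 24 ± 2.5
long and 9 ± 0.7 wide, small 14 ± 1.5, elongated 48 ± 6, round diameter
14 ± 1.5 with aspect at most 1.25, deformed bulges 1.6–2.2× cell width;
intact body contrast 0.45 ± 0.04 against background, lysed 0.10 ± 0.015.
No public per-class size distributions exist for the screens this design
follows — only example images — so these are declared package defaults,
chosen to give the classes overlapping but separable size distributions,
and are not claimed as measured values.

**Screen level.** Each well holds one strain at one time-point; its cells
are a multinomial draw over the six states from the strain's *trajectory*
(a 3 × 6 matrix of state proportions). The wild-type trajectory lyses on
schedule (intact 0.85 → 0.45 → 0.15); three deviant archetypes mirror the
qualitatively distinct responses seen in such screens: `slow_lysis`
(intact stays high, breaking the time–lysis correlation), `stable_bulge`
(deformed/round cells accumulate and resist lysis), `filamentous`
(elongation dominates before delayed lysis). Deviant strains draw a fixed
per-strain severity from U(0.7, 1) and follow the log-space interpolation
between the wild-type and archetype trajectories — deletion strains
plausibly differ in effect strength, and this also produces the graded
cloud structure that clustering must cope with.

Three noise layers sit on top of the trajectory, all on log class
fractions:

* **two latent biological factors per well** (lysis-timing and
  deformation-propensity, standard deviations `factor_sd = c(1, 1)`) with
  fixed loadings across time-points. These give wild-type replicate
  profiles their *correlated*, low-dimensional variability — the "main
  variability" a PCA reference model is meant to capture. Without them the
  18 profile variables are nearly independent multinomial noise, the PCA
  has nothing systematic to model, and the whole premise of T²/SPE
  monitoring collapses;
* **independent log-fraction noise** (`bio_noise_sd = 0.05`);
* **plate batch offsets** (`batch_sd = 0.30`), drawn once per
  plate × time-point × state — the nuisance the batch-correction stage
  must remove.

Counts per well are Poisson around 173/155/164 cells at the three
time-points, the per-well scale typical of such screens. Reproducibility:
every well derives its own seed from the screen seed (`seed + 7919·i mod
2³¹`), so partial re-simulations reproduce exactly; the documented
alternative (a single stream) would re-randomize everything downstream of
any change.

What the generator does **not** emulate: optics (defocus, point-spread,
shot noise), cell motion, crowding/aggregation, segmentation artifacts
correlated with morphology, plate spatial gradients (row/column effects),
or real biological pathway structure. Tests passing on synthetic screens
therefore validate the *pipeline logic and calibration*, not performance
on any particular microscope's data.

## 2. Segmentation

`enhance()` normalizes, applies CLAHE only when coarse-tile medians show
uneven illumination (on an already flat background CLAHE would just
amplify noise — this check also makes enhancement idempotent at the object
level), fixes polarity so cells are bright, and removes remaining
background with a top-hat filter (disc radius 15 px, larger than any cell
half-width). `binarize()` thresholds at the background median plus
`threshold_nsd = 4` robust standard deviations (MAD): deliberately
permissive, because lysed ghosts at contrast ~0.10 must survive; a
morphological closing (disc 5) and hole fill consolidate fragmented
ghosts. False structure is left to `prune()`: area within [40, 4000] px²,
solidity ≥ 0.6, aspect ≤ 12, and border-touching components discarded
(their shape descriptors would be truncated; configurable). Touching cells
are *not* split — cells in liquid media stay separated, and merged blobs
fail the aspect/solidity criteria instead. Contours are traced, lightly
smoothed to sub-pixel polygons (window 5) and pushed half a pixel outward
so the polygon encloses the mask area; orientation is counter-clockwise,
coordinates 0-based with origin top-left.

## 3. The 54-descriptor feature vector

The inventory is frozen (`feature_names()`): 22 shape values (area,
perimeter, length/width from the minimum-area enclosing rectangle, aspect
ratio, circularity 4πA/P², solidity, eccentricity, extent, equivalent
diameter, convexity, rectangularity, five radial statistics, three
curvature summaries, bending energy, elongation), 10 Fourier contour
harmonics (complex FFT of the arc-length-resampled contour, magnitudes of
harmonics −5…−1 and +2…+6 normalized by the first positive harmonic:
invariant to translation, rotation, scale and starting point), 12
intensity statistics of in-mask pixels, and 10 microenvironment contrasts
between the cell and a 3-px dilation annulus that excludes neighboring
cells' pixels. `env_contrast_norm` (difference over pooled SD) and
`env_local_snr` are invariant to affine intensity maps; the remaining
intensity features are covariant by design and documented as such. The
count, the four blocks and the invariances are the contract; the exact
per-descriptor formulas are this package's own definitions.

## 4. Classification

**PLS-DA** (lysed vs intact): single-response NIPALS with deflation,
features autoscaled on training statistics, response coded {0, 1},
3 components by default, decision threshold 0.5 with ties going to the
positive class. With all components the fit provably equals least squares
on autoscaled data — the test suite checks this and the equivalence of the
scores to an eigendecomposition-based oracle.

**SIMCA** (morphology): one PCA per class on class-autoscaled cells,
component counts elongated 1, normal 1, round 3, small 2. Class membership
uses the reduced combined distance d = T²/k + SPE/SPE̅ (score-space
Mahalanobis over its component count plus the orthogonal residual scaled
by the mean training residual); the acceptance limit is the empirical 95th
percentile of d over the class's training cells, so held-out in-class
acceptance is calibrated near 95%. Cells accepted by no class are
"deformed" — the rejection category is the whole point of using a class
model rather than a discriminant here, because bulging morphologies are
too heterogeneous to model as a fifth class. Multiple acceptance resolves
to the smallest distance/limit ratio, and the count of such ambiguous
cells is reported. Metrics come from stratified, seeded seven-fold
cross-validation.

## 5. Profiles, batch correction, QC

Proportions always use the whole population (intact + lysed) as
denominator, so the five morphology proportions sum exactly to the intact
proportion. The 18-vector order is frozen: (intact, normal, round,
elongated, small, deformed) within each time-point, time-points ascending.
Batch correction centers and scales each variable to unit SD *within each
plate*, using all wells on the plate (a controls-only variant is a config
option); zero-variance variables are centered with a warning. We
standardize each of the 18 variables independently per plate — the
alternative reading (standardizing profiles jointly) would not equalize
per-variable plate scales, which is what the plate-level nuisance
requires. No imputation anywhere: missing time-points fail loudly, because
the screen's remedy for bad wells is repetition, not interpolation. QC
fails a well iff total cells < 50 or any frame > 150 cells (inclusive
bounds pass).

## 6. The wild-type reference and control limits

The reference is a PCA of autoscaled wild-type profiles. Two places where
the obvious textbook default proved wrong during development, and what we
do instead:

* **Retained components k.** A cumulative-variance rule (90%) retains
  10–13 of 18 components on proportion profiles, because multinomial
  counting noise gives the autoscaled spectrum a long flat tail. The score
  space then absorbs most of the noise and resubstitution SPE limits
  become strongly anti-conservative (measured 4–5% null flag rate at a
  nominal 2%). The default is therefore the Kaiser rule — retain
  eigenvalues above the mean — which keeps the systematic factors and
  leaves counting noise to the residual; the variance rule remains
  available (`k_rule = "variance"`), and the k actually used is reported
  in every manifest.
* **Limit scores.** Limits from resubstitution scores (scoring the
  training replicates with the model they trained) are anti-conservative
  at n = 276, p = 18: out-of-sample scores are stochastically larger
  (measured 2.4–3.5% null flag rate). The default limit scores are
  therefore **leave-one-out**: each wild-type replicate is scored against
  a model refitted without it, which makes the wild-type score sample
  exchangeable with the scores of new wild-type-like profiles
  (`limit_scores = "resubstitution"` restores the plain variant).
  Percentiles use the rank (n+1)p convention (quantile type 6) — linear
  interpolation between order statistics, with the rank chosen so that
  the exceedance probability of the limit is exactly 1 − p for
  exchangeable scores. The measured null flag rate at the 99th-percentile
  either-statistic rule is then ≈ 1.8–2%, which `scripts/acceptance.R`
  recomputes on every run.

Flagging is strict (`>` the limit; a score exactly at the limit passes)
and categorized none / spe_only / t2_only / both. Parametric limits (the
scaled-F T² limit and the g·χ²ₕ SPE approximation from the residual
eigenvalue moments θᵢ = Σλʲ, j > k) are computed for diagnostics only; the
operative rule is the empirical percentile, matching screening practice.

## 7. Clustering and enrichment

Flagged strains' (batch-corrected) profiles are clustered by seeded
k-means, best of 50 restarts by within-cluster sum of squares
(Hartigan–Wong via `stats::kmeans`; a greedy spread-out initializer was
considered and dropped in favor of the established implementation with
restarts). k is selected by mean silhouette width over k = 2…8; if no k
achieves a positive mean silhouette the data are reported as unclustered
rather than forced into clusters. The profiles are autoscaled within the
clustered set first (`standardize = TRUE`): flagged outliers sit tens of
wild-type SDs out in some variables and one in others, and without
rescaling those few variables own the Euclidean metric — in development
this reliably merged the two intact-rich archetypes. The 2-D PCA embedding
fixes component signs (largest-magnitude loading positive) so plots are
reproducible.

Enrichment: per (cluster, category), a two-tailed Fisher's exact test on
the 2×2 table of in-/out-of-cluster strains with/without the category,
with the *flagged strain set* as background (the relevant question is
"what distinguishes this cluster among the hits", not "among the genome";
a genome-wide background is a config option). Two-tailed convention: the
sum of probabilities of all tables with the same margins no more probable
than the observed one — the test suite checks this against exhaustive
enumeration for every table with margins up to 30. Significance is raw
p < 0.05 by default, with `p_adjust` available but off, matching common
screening practice of treating enrichment as descriptive.

## 8. Problem sizes and determinism

The test suite and acceptance script run at deliberately chosen desk
scales: classifier training uses 40–60 rendered cells per class;
segmentation accuracy uses 12 frames of 14 non-overlapping cells; the
null-calibration experiment aggregates 20 independent screens of 500 null
strains (10,000 null profiles, each screen with its own 276-replicate
wild-type reference — aggregating over references is what makes a 1–2%
tail rate measurable at all); the recovery screen has 4,150 mutants (150
deviants at severity U(0.7, 1)) plus 276 wild-type replicates on 3 plates.
Every stochastic stage takes an explicit seed, and identical seeds
reproduce frames, screens, fits and hit lists bit for bit.

## 9. Known limitations

Frame-level simulation of thousands of strains is intentionally out of
reach (rendering and segmenting ~60,000 frames is not a desk-scale
operation); large screens are simulated at the count level, which is
exactly the granularity the profiling, outlier and clustering stages
consume. The segmentation makes no attempt to split touching cells, so
crowded fields lose merged cells to pruning — mirrored by the QC ceiling
of 150 cells per frame. SIMCA limits assume the training annotations are
clean; label noise would widen class regions. The theoretical SPE limit
assumes Gaussian residuals; it is provided for diagnostics, and decisions
rest on the empirical limits. COG category labels are taken as an input
table; no orthology assignment is performed.
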