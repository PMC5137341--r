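---
title: "Tree-centric carbon mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-centric carbon mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopycarbon)
```

`canopycarbon` estimates forest carbon the way a field crew would — one tree
at a time — but from airborne data. This vignette explains the models behind
each stage, the parameters that matter, what the synthetic stand generator
does and does not emulate, and the design decisions taken where the
methodology left genuine freedom.

## 1. Crown delineation

The delineation substrate is a canopy height model (CHM): each pixel holds
the maximum height of the laser returns falling in it. Gap pixels are filled
with the mean of their non-empty 8-neighbours (0 where isolated) so that
spurious pits cannot masquerade as crown boundaries. The CHM is then
low-pass filtered; smoothing is what keeps one tree from seeding several
crowns, because raw maxima are dominated by branch-level texture.

Parameters (all in `chm_params()` / `delineation_params()`, with defaults
chosen for spruce/larch-dominated Alpine stands):

| parameter | default | unit | role |
|---|---|---|---|
| `resolution` | 0.5 | m | CHM pixel size; ~48 pulses m⁻² supports sub-metre cells |
| `smoothing_kernel` | `mean3x3` | — | a single 3×3 mean pass; `gaussian` (σ in pixels, truncated at 3σ) as option |
| `window_diameter` | 2.5 | m | circular local-maxima window; about the smallest crown the method should resolve |
| `min_tree_height` | 2 | m | small-tree cut-off: no seed below it |
| `frac_threshold` | 0.45 | — | a pixel joins a crown while its drop below the apex is < 45% of apex height |
| `abs_threshold` | 6 | m | … and < 6 m absolutely |
| `low_point_cutoff` | 2 | m | returns at or below are discarded before hulling |

A pixel is a tree top when nothing within the window exceeds it *and* it
strictly exceeds at least one window pixel; among equal-valued candidates
sharing a window only the lexicographically smallest (row, col) survives.
The extra "strictly exceeds something" clause is what makes a perfectly
constant surface yield zero seeds while a two-pixel plateau peak still
yields exactly one — the pure "greater than all others" rule cannot deliver
both at once.

Regions grow from the seeds in synchronous rounds over the 4-neighbourhood.
The height-drop test is always taken against the *seed apex* (the literal
reading of the growth rule), not against a running region maximum, which
keeps the result independent of traversal order. When two regions could
claim a pixel in the same round, the taller apex wins and ties fall to the
smaller seed id — a deterministic rule the tests enforce against a
brute-force breadth-first oracle. Crown polygons are 2-D convex hulls of
each region's first returns above the low-point cut-off; crown height is the
99th percentile of those returns, computed with linear interpolation between
order statistics (R quantile type 7 — the percentile definition had to be
pinned for reproducibility).

Matching delineated crowns to field stems is containment-based: a stem
inside exactly one polygon pairs with it; with several stems inside, the one
closest in height wins (ties: larger diameter, then smaller id). Because two
overlapping crowns could claim the same stem, crowns are processed in
increasing id order and each stem pairs at most once. Accuracy is reported
as detection rate (DET), omission error (OE = 100 − DET), commission error
(CE, spurious crowns) and the accuracy index AI = 100 − (OE + CE), overall
and per diameter class (default class edges 10, 20, …, 80 cm).

## 2. Species recognition

Pixel spectra are divided by their band sum, which removes
illumination/strip brightness differences while preserving spectral shape.
Within each crown only *sunlit* pixels — those at or above the crown's
median pre-normalization brightness — are classified; shaded crown edges
carry a weaker signal. The median split is a transparent stand-in for more
elaborate sunlit-pixel models and the quantile is configurable
(`extract_sunlit_pixels(quantile = )`).

Band selection is sequential forward floating selection (SFFS): greedy adds
of the band that maximizes class separability, with conditional backward
removals whenever dropping a band improves the best criterion seen at the
smaller size. The criterion is the mean pairwise Jeffries–Matusita distance

$$JM = 2\,(1 - e^{-B}), \qquad
B = \tfrac18 (\mu_1-\mu_2)^\top \bar\Sigma^{-1} (\mu_1-\mu_2)
  + \tfrac12 \ln \frac{|\bar\Sigma|}{\sqrt{|\Sigma_1||\Sigma_2|}},$$

with $\bar\Sigma = (\Sigma_1+\Sigma_2)/2$; JM is bounded in [0, 2], and 1.9+
is the "almost separable" regime. The mean (rather than minimum) pairwise
criterion was chosen as the default because the minimum is hostage to the
single hardest pair; the minimum is available as an option. Covariances are
diagonally loaded by 10⁻⁶ of their mean diagonal before inversion, since
per-class pixel counts can be small.

Pixels are classified by a one-vs-one soft-margin RBF SVM (`kernlab`), with
the crown's 99th-percentile ALS height appended as a feature. When
cross-validation is enabled, C ∈ {10⁻¹…10³} and kernel width γ ∈ {10⁻³…10¹}
are tuned by stratified 5-fold CV with seed-fixed folds. Crowns take the
modal label of their pixels; vote ties break by the larger mean class
probability, then lexicographically. Accuracy is summarized by overall
accuracy, kappa, per-class producer's/user's accuracies and their unweighted
mean, from a confusion matrix oriented rows-predicted × columns-reference
(producer's accuracy is column-based).

## 3. Stem diameter and biomass allometry

The statistical core is the crown-to-stem model
$\widehat{DBH} = \varepsilon H^{\rho} (1 + \vartheta\,CA)$, fitted by
*median* quantile regression: the τ = 0.5 pinball loss is insensitive to the
heteroscedastic, right-skewed scatter of diameter data, and under
multiplicative symmetric-in-log noise the conditional median *is* the
allometry, so the estimator is consistent where least squares is biased by
outliers. The check loss is non-smooth, so `fit_dbh_model()` minimizes a
smoothed surrogate $\tau r + \eta \log(1+e^{-r/\eta})$ with η stepped down
1 → 0.1 → 0.01 (DBH is in cm, so the final kink width is hundredths of a
centimetre), using analytic-gradient BFGS from a log-scale least-squares
initialization plus up to 8 grid starts. Standard errors come from a
nonparametric bootstrap (200 resamples, warm-started, seed-fixed). Species
with ≥ 100 triples get their own fit (`fit_dbh_models(n_min = 100)`); a
pooled `"All"` fit is always produced and serves as the fallback. The
fitted object is a classed model with `print`, `summary`, `coef`,
`predict`, `fitted`, `residuals`, `simulate` (resampled relative residuals,
preserving the multiplicative error structure) and `plot` methods.

Biomass follows $AGB = \alpha\,WD^{\beta}(DBH-d_0)^{\gamma}H^{\delta}$ with
β = 1 (biomass linear in wood density) and δ between 0.83 and 1.34 across
species. The packaged diameter-model coefficients are a table calibrated
for Alpine conifer stands; the packaged *biomass* coefficients are a
clearly-labelled synthetic placeholder with realistic magnitudes (the
regional stem-volume tables they stand in for are not redistributable), so
real analyses must supply their own CSV — the `source` column exists to
force that discipline. Carbon is 0.50 × AGB for conifers, 0.48 for
angiosperms. Stems at or below the allometry offset $d_0$ get zero biomass
with a warning rather than a negative power.

## 4. Plots, the hidden-tree correction, and maps

Plot carbon density is $\sum$ carbon / plot area, reported in Mg C ha⁻¹
(kg→Mg and m²→ha conversions are asserted in tests). Crown delineation
cannot see understorey stems, so ARS plot carbon systematically
underestimates field carbon; the correction is the through-the-origin
least-squares multiplier $m = \sum f a / \sum a^2$ — the minimal faithful
estimator of a proportional relation — reported with the post-correction
RMSE and the adjusted R² of the field~ARS regression both with and without
intercept (the with-intercept fit answers "how linear is the relation", the
origin fit matches the proportional model actually applied).

Carbon rasters assign each crown's carbon wholly to the cell containing its
seed point: under the tree-centric principle the only edge error is whether
a tree centre falls inside or outside a cell, and conservation
($\sum$ cell value × cell area = scene carbon) is then exact by
construction at every grain. Area-weighted splitting across cells is
available as an option (approximated on a deterministic sub-pixel grid).
`rmse_vs_plot_size()` samples random square plots of increasing area and
reports relative RMSE between true and corrected estimated density; on an
uncorrelated landscape it reproduces the (plot area)^(−1/2) sampling-theory
decay, which the tests check.

## 5. The synthetic stand generator

`forest_scenario()` bundles every knob. `"alpine_default"` emulates a
conifer-dominated mountain stand: 350 overstorey stems ha⁻¹ placed by a
Poisson process with hard-core inhibition (minimum spacing half the sum of
crown radii), five species (Picea-dominated mixture), truncated-lognormal
diameters, crown area roughly 0.625 m² per cm of DBH with lognormal
scatter, and heights obtained by *inverting* the diameter allometry with 6%
lognormal scatter — so the generated (H, CA, DBH) triples refit to the
generating coefficients, which the parameter-recovery tests exploit. All
sizes are rejected into realistic Alpine ranges (DBH 3.5–121 cm, H
1.5–48.8 m, CA 1.5–55.4 m²). Understorey trees (20–45% of their host's
height, tucked under dominant crowns) are added until they hold a
configurable share of stand carbon — 19% by default, which puts the true
hidden-tree multiplier near 1/(1−0.19) ≈ 1.23. `"separable_stand"` spaces
60 stems ha⁻¹ so crowns never overlap and omits the understorey: every
crown is delineable and end-to-end detection should be perfect.
`"null_spectra"` collapses the spectral class means (JM ≈ 0) as the
chance-level control.

Point clouds sample a jittered pulse grid at 48 pulses m⁻²; first returns
sit on the paraboloid crown surface of the tallest intercepting tree
(depth 60% of apex height) plus Gaussian noise (σ = 0.2 m), 35% of canopy
pulses produce a second return and some a third/ground return (up to 4),
and crown-free pulses return from the ground. The paraboloid was chosen as
the simplest surface with a unique apex that region growing can segment.
Hyperspectral cubes place species' mean spectra at equal pairwise distances
in band space — the distance computed from the target JM and the
within-class σ — and darken crown-edge pixels (beyond 75% of the crown
radius) by a 0.6 shading factor to exercise sunlit extraction. Field
inventories support fixed-radius circles and Bitterlich angle-count plots
(a stem is tallied when `dbh_cm ≥ 100·√BAF·distance/50`), with 1.5% DBH and
5% height measurement noise.

What the generator does **not** emulate: radiative transfer (spectra are
Gaussian classes, not physics), within-crown spectral gradients other than
edge shading, terrain (ground is flat; heights are above-ground by
construction), waveform returns, occlusion between neighbouring crowns, and
species-dependent crown shapes beyond the paraboloid aspect ratio. Passing
tests therefore demonstrate algorithmic correctness and statistical
behaviour under the stated model, not performance on real scenes — the
delineation thresholds and the SVM grid in particular will need site tuning
on real data.

## 6. Numerical choices and degenerate inputs

* Quantile definition: linear interpolation between order statistics
  everywhere a percentile appears.
* Local-maxima ties: lexicographic keeper; growth conflicts: apex then id.
* Pinball smoothing: η continuation ending at 0.01 cm; non-convergence from
  every start is an error, never a silent fallback.
* Covariance inversion: Cholesky after relative diagonal loading (10⁻⁶).
* Zero-sum spectra become nodata with a warning; regions with < 3 first
  returns, collinear hull inputs, seeds below the cut-off, and classes with
  < 5 training pixels are dropped with warnings, not errors.
* LAS coordinates are stored at the finest int32-safe scale for the extent,
  so write→read round-trips are identity to well below a millimetre.
* Problem sizes in the shipped tests (stands of 50–100 m, 20 fitting seeds,
  1000-triple regressions, 100+ oracle grids) were chosen so the whole
  suite exercises every claim in under a minute on a single core.

## 7. Known limitations

Delineation is CHM-based: leaning stems, interlocking crowns and multi-stem
clumps violate its one-apex-per-tree assumption, and understorey trees are
invisible by construction — that is precisely what the hidden-tree
multiplier compensates at plot scale, and the multiplier is only as good as
the calibration plots' understorey share. The sunlit-pixel rule is a
brightness quantile, not an illumination model. The matching rule is
containment-first; a stem displaced outside its crown polygon (GPS error,
lean) cannot match. Coefficient tables are the user's responsibility on
real data; the packaged biomass table is synthetic by design.
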