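---
title: "Morpho-functional trade-off landscapes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morpho-functional trade-off landscapes: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tradescape)
```

## The problem

A skull that bites hard is usually not a skull that bites fast. When one
structure serves two competing functions, selection cannot optimise both at
once, and the compromise each species strikes — the *trade-off weight* —
may shape how morphological diversity accumulates across a clade.
`tradescape` implements a complete analysis pipeline for this question on
3D landmark data: it builds a shape space, models each function as a
*performance surface* over that space, combines the surfaces into a
functional landscape, estimates the weight that best explains each shape's
position on it, and asks whether the amount of shape space theoretically
available at a given weight predicts the morphological disparity real
species display there.

## From landmarks to morphospace

`gpa()` performs generalized Procrustes analysis: configurations are
centred, scaled to unit centroid size, and iteratively rotated onto the
evolving mean until the mean changes by less than `1e-10` (at most 100
iterations); rotations are proper unless reflections are explicitly
allowed. Aligned shapes are projected orthogonally onto the tangent space
at the mean, so Euclidean and Procrustes distances coincide to first
order. `pca_morphospace()` then decomposes the tangent coordinates;
every eigenvector is flipped so its largest-magnitude loading is positive,
which makes scores reproducible across platforms and linear-algebra
libraries.

`theoretical_grid()` places an evenly spaced `n x n` grid (default 8 x 8,
64 positions) over the first two component axes. The empirical score range
is extended by 10% per axis before gridding; because "extend by 10%" is
ambiguous, we adopt *total* extension of 10% split as 5% per end, and
expose the fraction as a parameter. `reconstruct_shape()` maps any grid
position back to a landmark configuration.

## Performance surfaces

Each functional metric is a scalar per theoretical shape. Raw
finite-element summaries can be prepared with `trim_top_fraction_mean()`
(drop the top 2% of element stresses, then average — boundary and loading
artefacts otherwise dominate) and `scale_unit_interval()` (min–max scaling
to [0, 1], making metrics comparable). Scaling happens *before* surface
fitting: the surfaces are fitted to the scaled values over the 64
theoretical shapes.

`fit_surface()` offers three families:

* **polynomial**, degree 1–5, ordinary least squares on bivariate
  monomials;
* **tps**, polyharmonic (thin-plate) splines of order 2–4, i.e. polynomial
  drift of degree order−1; the smoothing parameter is chosen by
  generalized cross-validation over a log-spaced grid scaled to the
  kernel's eigenvalues (pass `lambda = 0` for exact interpolation);
* **kriging**, ordinary kriging with a spherical, exponential or Gaussian
  variogram fitted by weighted least squares to the binned empirical
  variogram (weights `N/h^2`); order 0 picks the family automatically.

`crossvalidate_surfaces()` selects among candidates by seeded k-fold
(default 10) out-of-fold RMSE; ties break toward fewer parameters, and
candidates that fail on a fold are flagged rather than dropped.
Predictions are deliberately **not clipped** to [0, 1]: a fitted surface
may stray slightly below zero off-sample, and the landscape code must be
told explicitly (via `floor_eps`) how to handle that — see below.

## The combined landscape and the weight w

Two scaled surfaces \(F_1\) (force-like) and \(F_2\) (velocity-like)
combine at mixing weight \(w \in [0,1]\) into the landscape height
\(W(z; w) = w F_1(z) + (1-w) F_2(z)\). The log-fitness of a shape at
morphospace position \(\bar z\) under weight \(w\) is

\[
\ln \frac{w F_1[\bar z] + (1-w) F_2[\bar z]}
         {\max_{\text{grid}}\left[ w F_1 + (1-w) F_2 \right]},
\]

the log of the shape's height relative to the highest point the same
landscape reaches anywhere on a reference grid; the maximum is recomputed
for every \(w\). `estimate_w()` maximises this over an exhaustive grid
`w = 0, 0.001, ..., 1`. Grid search is used instead of smooth optimisation
because the inner maximum makes the objective piecewise: on any interval
where one grid cell holds the maximum the objective is a monotone Möbius
transform of \(w\), so local optima sit exactly at the weights where the
maximising cell switches, and a gradient method can stall on the wrong
piece. Weights within `1e-12` of the optimum form a tie set; the reported
`w` is its midpoint with `tied = TRUE`. In particular, a shape sitting
exactly on the landscape peak is tied over the whole interval for which
its cell tops the landscape, so its reported weight is that interval's
midpoint, not 1 — an intentional consequence of the midpoint convention.

Two practical choices deserve emphasis:

* **Reference grid.** The maximum defaults to the same 8 x 8 grid the
  surfaces were fitted on; the finer 40 x 40 grid is available
  (`reference = "cells"` in `w_surface()`). We found the coarse reference
  preferable: the fine-grid envelope has many more maximum-switch points,
  which fragments species weights into thinly populated values and
  destabilises the downstream window analysis.
* **Non-positive heights.** Because scaled surfaces are exactly 0 at their
  grid minimum (and unclipped predictions can dip below 0), the log ratio
  can be undefined. The default is a hard error; passing
  `floor_eps = 1e-9` floors the combined height instead. The pipeline and
  the synthetic studies use the floor, and record it.

`species_w()` estimates one weight per species from its PC1/PC2 position;
`w_surface()` maps the weight over a 40 x 40 grid (1600 cells).

## Weight volume versus observed disparity

`make_windows()` slides overlapping intervals (default width 0.011, step
0.0002) across the weight range of the 40 x 40 surface. Per window,
`windowed_disparity()` reports the *w volume* — the number of cells whose
weight falls in the half-open interval `[start, start + size)` — and, for
windows holding at least two species, the observed disparity: species are
first clustered on their 2D landscape positions (`cluster_positions()`,
Gaussian mixtures with full covariances, K chosen by BIC among
1..min(5, n−1)), then the multivariate variance (`multivariate_variance()`,
the trace of the covariance matrix) of the **full** shape variables is
computed per cluster and summed; clusters of one contribute 0. The
clustering step exists because similar weights occur in distant parts of
the landscape, and pooling distant species would overstate the disparity
available at that weight. Windows with fewer than two species report their
volume with disparity `NA`. Half-open membership means adjacent
non-overlapping windows never double-count a cell; overlapping windows do,
by construction.

`association()` relates the volume and disparity profiles with Pearson's
*r*, Spearman's *rho* and the rank-based xi coefficient (sensitive to
non-monotone dependence; ties in the conditioning variable are broken
uniformly at random under a recorded seed; its p-value uses the
right-tailed asymptotic normal null). Note that overlapping windows make
neighbouring profile points highly dependent, so these p-values are
anti-conservative and should be read descriptively, as association
strength on the profile scale.

## Transfer of the form–function map between clades

`fit_pls2b()` fits two-block partial least squares between the shape block
(centred tangent coordinates) and the functional block (centred, scaled to
unit variance): the first singular triplet of the cross-covariance matrix,
with the functional axis's first loading made positive. Only the first
axis pair is modelled. `major_axis_predict()` projects a specimen's score
pair onto the major axis of the *training* score cloud and back-transforms
the shape coordinate into a full shape. `transfer_assessment()` fits
nothing: given a model fitted on one clade, it reports per-specimen
residual distances (Euclidean in tangent space, which is the first-order
Procrustes distance) for both clades. A model fitted on clade A overfits
A, so same-mapping clades should show comparable residuals, and only a
genuinely different form–function mapping should inflate them; a
two-sided Wilcoxon rank-sum test accompanies the medians as a descriptive
summary, not a gate.

## Comparative phylogenetic layer

`model_vcv()` supplies trait covariances under Brownian motion, a
stationary Ornstein–Uhlenbeck process (ultrametric trees only — the
stationary formula is wrong off-ultrametric inputs, so they are rejected
rather than silently approximated) and early burst (via `expm1`, so the
\(r \to 0\) limit recovers BM to machine precision).
`fit_trait_model()` maximises the corresponding Gaussian likelihood with
the root state and rate concentrated out; the single remaining parameter
(OU's \(\alpha\) on `[1e-8, 50/depth]`, EB's \(r\) on `[-10/depth, 0]`)
is profiled by a 25-point deterministic grid followed by local
optimisation, which makes refits bit-reproducible. AICc uses
\(-2\mathrm{LL} + 2k + 2k(k+1)/(n-k-1)\) with \(k = 2\) (BM) or 3 (OU,
EB).

`pgls()` is exact GLS under the BM covariance with significance by seeded
permutation of phylogenetically whitened residuals; `pgls_polynomial()`
compares intercept-only, linear and quadratic designs by AICc (the shape
of the rates-versus-weight question). `pic_contrasts()`, `mantel()` (the
classical unnormalized cross-product Z statistic) and `ppca()`
(GLS-centred evolutionary covariance) wrap or implement the standard
machinery; `rate_association()` correlates externally produced
variable-rate tables on branches, tips, and PIC-transformed tips (with
the through-the-origin convention for contrasts). Multivariate
penalized-likelihood model fitting and the MCMC variable-rates estimation
itself are out of scope: rate tables are ingested, not computed.

## The synthetic study generator

Real functional values come from finite-element analysis, which this
package does not perform. `gen_study()` instead builds studies with known
truth: a pure-birth unit-depth tree (`gen_tree()`), landmark
configurations evolved as independent Brownian motions along it
(`gen_shapes_bm()`), and two analytic performance functions — sums of
isotropic Gaussian peaks over the PC plane (`surface_spec()`) — sampled
on the theoretical grid with seeded Gaussian noise and min–max scaling
(`gen_performance()`). The ground-truth weight of every species is
computed by `oracle_w()`, a deliberately plain brute-force scan of the
log-fitness objective on the noiseless surfaces at resolution `1e-4`,
written independently of `estimate_w()`.

The default configuration is a fixed set of study conditions sized like a
carnivoran cranial study: 132 species, 35 landmarks, BM rate 0.01,
measurement noise 0.01 on the scaled metrics, a 70/30 clade split sharing
one form–function mapping. The default
performance functions plant the asymmetry of interest — a dominant sharp
F1 peak with weaker secondaries against a broad multi-hill F2 plateau, so
that far fewer morphospace cells optimise F1 than F2. Two properties of
this design were deliberate:

* **Texture.** Smooth single-peak functions generate only two or three
  maximum-switch points, collapsing all species onto one or two weight
  values; several overlapping peaks per function emulate the mild
  wiggliness of surfaces fitted to measured data and spread the weights
  over four to six interior modes.
* **Grid-resolvability.** Every peak width is at or above the 8 x 8 grid
  spacing (~0.14 of the axis span). A peak narrower than the sampling
  grid cannot be interpolated from it by any surface family, which both
  misrepresents the published setting (where fitted surfaces achieve
  cross-validated RMSE of a few percent) and breaks exact weight recovery
  at zero noise.

What the generator does **not** emulate: mesh-level finite-element
behaviour, allometry, modular covariance among landmarks, measurement
error in the landmarks themselves, diversification-rate variation, or any
real carnivore data distribution. Tests passing on these studies show the
estimation machinery is correct and well-calibrated under the stated
model; they do not validate biological conclusions on real data.

Because species weights concentrate on a handful of modes (the same
clustering the method produces on real data), the windowed volume and
disparity profiles of one study effectively compare a small number of
mode-level points, and a single ~130-species draw has appreciable
probability of a weak or even negative profile correlation by sampling
accident — e.g. when one clumped clade lands near the sharp peak.
Study-level checks of this association therefore pool the populated
windows of several replicate studies and compute one correlation on the
pooled profile, which is the stable summary of the planted structure; per
replicate, only the direction of the theoretical asymmetry (far fewer
high-weight than low-weight cells) is asserted.

## Numerical choices and degenerate inputs

* GPA tolerance `1e-10` on the mean-shape RMS change, 100 iterations max;
  degenerate (zero-size) configurations are errors.
* Polyharmonic kernels are conditionally definite only up to sign; the
  reduced bending-energy matrix is orientation-checked and flipped once so
  smoothing is well-posed for every order.
* Weight-search resolution 0.001 (exposed); ties resolved to midpoints.
* Coincident points in per-window clustering collapse to one cluster;
  mixtures mclust cannot fit fall back to a single cluster rather than
  aborting the window.
* Polytomies are resolved to zero-length branches (with a message) before
  computing contrasts.
* Window geometry follows the half-open convention; the window range is
  data-driven (the observed range of the 40 x 40 weight surface), so
  window counts depend on the data, as they do in the published analyses.

## Problem sizes

The shipped tests and the acceptance script run studies of 40–132 species
with 12–35 landmarks, 64-point fitting grids, 1600-cell weight surfaces,
about five thousand sliding windows, 1000-position brute-force weight
scans, 100-replicate model-selection sweeps and 50-replicate transfer
simulations. These sizes were chosen so a full run completes in a few
minutes on one core while leaving every estimate far from its asymptotic
regime only where the test explicitly targets small-sample behaviour.

## Known limitations

* OU fitting and covariances require ultrametric trees.
* Only two competing functions are supported (the general multi-function
  landscape reduces to the two-function case used throughout).
* PGLS uses plain permutation inference, not robust MM estimation.
* The weight's likelihood surface is explored by grid search; resolutions
  finer than 1e-4 on large grids cost memory proportionally.
* Profile-level p-values ignore window overlap (see above).
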