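---
title: "Density surface modelling for strip-transect aerial surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density surface modelling for strip-transect aerial surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripdsm)
```

## The problem

Aerial strip-transect surveys count animals (here, guanaco-like social
ungulates photographed from a helicopter) inside a strip of fixed width
around the flight line, assuming every group inside the strip is detected
and none outside it. Counts referenced to space can then be modelled as
smooth functions of environmental covariates and the fitted density
surface integrated over a prediction grid — two-stage *density surface
modelling* (DSM). `stripdsm` implements the full chain: segmentation of
flight paths, covariate summaries and screening, a Tweedie penalized-spline
abundance model selected by REML, an AR(1) correction for residual
autocorrelation along transects, and grid prediction with delta-method
coefficients of variation. A synthetic-data module generates landscapes,
populations and surveys with exactly the statistical structure the
analysis assumes, so every stage is testable at desk scale.

## The abundance model

The sampling unit is the *segment*: the strip is cut every 1400 m along
the flight line, the same distance as the strip bandwidth, so a full
segment is an approximately square 1.96 km² quadrat. Segment $i$ carries a
count $y_i$ (summed group sizes of the records assigned to its strip), an
effort area $A_i$ (km²), and covariates: average elevation (AA), distance
from the segment centroid to the coast (DC), and geographic location
(GL; projected x, y in meters).

Counts are modelled with a Tweedie response and logarithmic link,

$$ \mathbb{E}(y_i) = \mu_i = A_i \exp\{\beta_0 + f_{AA}(AA_i) + f_{GL}(x_i, y_i) + \dots\},
\qquad \mathrm{Var}(y_i) = \phi\, \mu_i^{p}, \quad 1 < p < 2, $$

where the $\log A_i$ offset puts the intercept on the log
individuals-per-km² scale, so partial terminal segments (kept when at
least half a bandwidth long, configurable) contribute valid effort. The
Tweedie family is a compound Poisson–gamma: it handles the many zero
segments and the overdispersed positive counts in one response
distribution. The unit deviance used throughout is

$$ d(y, \mu) = 2\left[ \frac{y^{2-p}}{(1-p)(2-p)} - \frac{y\,\mu^{1-p}}{1-p}
   + \frac{\mu^{2-p}}{2-p} \right], $$

which converges to the Poisson deviance as $p \to 1$ and the gamma
deviance as $p \to 2$ (the boundary $p = 1$ is available and reproduces
penalized Poisson IRLS). The survey this design follows never states the
power it used, so the default is $p = 1.5$ with an optional profile over
$p \in \{1.1, \dots, 1.9\}$ under the same selection score
(`fit_dsm(..., profile_p = TRUE)`); the choice is recorded in the model
file.

### Smooths and penalties

Univariate smooths (`AA`, `DC`) use a cubic regression spline in the
value–second-derivative parameterization with knots at data quantiles and
the exact integrated squared second derivative as penalty, so a straight
line is never penalized and evaluation outside the knot range continues
linearly. The geographic smooth (`GL`) is a knot-based thin-plate-style
radial basis ($r^2 \log r$) on standardized coordinates, knots chosen by
deterministic farthest-point selection, with the radial bending energy as
penalty; a plane lies in its null space, and standardization makes the
basis invariant to 90° rotations of the map. Basis dimensions follow the
k = 4–20 range; "k" is interpreted as basis dimension (the source
phrasing "between 3 and 19 knots (k = 4–20)" is ambiguous between interior
knots and basis dimension — basis dimension is used, as in the common GAM
software convention). Every smooth is centered by a sum-to-zero constraint
over the fitting data, absorbed by a QR reparameterization.

The labels `AA:GL` and `DC:GL` denote a *joint* smooth of location and the
covariate, implemented as a 3-input radial basis ($-r$) on standardized
(x, y, covariate); this is one reading of an ambiguous notation (the other
being a varying-coefficient term) and can simply be left out of the
candidate list.

### Fitting and smoothing selection

Coefficients minimize the penalized deviance
$D(\beta) + \sum_j \lambda_j \beta^\top S_j \beta$ by penalized IRLS on
the log link (working weights $\mu^{2-p}$, offset $\log A$), converged at
a relative penalized-deviance change below 1e-8 (at most 200 iterations).
The dispersion $\phi$ is estimated from the Pearson statistic at
convergence, and the conditional coefficient covariance is
$\phi (X^\top W X + \sum_j \lambda_j S_j)^{-1}$.

Smoothing parameters minimize a Laplace-approximate negative restricted
marginal likelihood ("REML score"): the deviance-based Gaussian
approximation at the penalized optimum plus
$\tfrac12 \log|X^\top WX + S_\lambda| - \tfrac12 \log|S_\lambda|_+$, with
$\phi$ profiled as $D_{pen}/(n - M)$ ($M$ = total penalty null-space
dimension). Lower is better. The optimizer is deterministic: a 7-point
log-spaced multistart common to all terms followed by Nelder–Mead (Brent
for a single term) on $\log \lambda$. When `select_k = TRUE` the basis
dimension of each term is additionally chosen over a grid within [4, 20]
by a greedy per-term scan of the same score. This is an authored
approximation, not a re-implementation of any particular GAM package's
REML machinery; its tests are oracle-based (brute-force optimizers,
holdout deviance, simulation recovery) rather than score-identical
comparisons.

### Candidate set and selection

Seven candidate structures are fitted per season — `AA+GL`, `DC+GL`, `GL`,
`AA:GL`, `DC:GL`, `AA`, `DC` — and ranked by REML score (ascending); the
best model is the lowest score, with ties (within 1e-10) broken by fewer
effective degrees of freedom. Average elevation and distance to coast are
never placed in one additive model because they are collinear in this
study system: `collinearity_screen()` applies the rule that
$|r| \ge 0.4$ forces separate models.

## Residual autocorrelation and the AR(1) correction

Segments adjacent along a transect share unmodelled structure, so deviance
residuals are correlated at lag 1 (1400 m) and lag 2 (2800 m) within
transects, pooled across transects. If any lag correlation exceeds 0.15,
the model is refitted with an AR(1) working correlation among consecutive
segments of a transect: at each IRLS step, the square-root-weighted
design and working response are whitened by the Prais–Winsten transform
within each run of consecutive order indices ($\rho = 0$ is exactly the
identity; cross-transect pairs are never correlated). The phrase
"correlation structure of order one until the second segment" is read as
plain AR(1), whose geometric decay covers lag 2 automatically. $\rho$ is
estimated by method of moments from the lag-1 pooled correlation of
deviance residuals, iterated to convergence (at most 10 iterations).
Smoothing parameters are re-optimized in the corrected fit by default
(hold them by passing `lambda`). After correction, a Wald-type test of
each smooth term (its coefficients against their conditional covariance
block, $\chi^2$ with the term's effective degrees of freedom) drops terms
with $p \ge 0.05$ and refits — mirroring the elimination of a location
term that loses significance once autocorrelation is absorbed.
`compare_gam_gamm()` reports the total-abundance CV of the independence
fit and the corrected fit side by side without making a decision.

## Prediction, totals and uncertainty

The prediction grid tiles the landscape with square 1.96 km² cells
anchored at the landscape origin; partial edge cells are dropped so all
areas are equal, and cells with forest cover at or above 0.95 are excluded
— the same threshold applied to segments. Cell covariates are computed by
the very sampler used for segment strips, so a cell that coincides with a
segment strip gets identical summaries. Per retained cell,
$\hat N_c = A_c \exp(\hat\eta_c)$; totals add cells and the mean density
divides by the summed retained area. Uncertainty is by the delta method on
the log link, conditional on the selected smoothing parameters:
$\mathrm{CV}_c = \sqrt{x_c^\top V x_c}$ per cell and
$\mathrm{Var}(\hat N) = a^\top X_p V X_p^\top a$ for the total (with $a$
the vector of cell abundances), retaining all between-cell covariance.
Smoothing-parameter uncertainty is deliberately ignored, matching common
DSM practice; a posterior-simulation option (coefficients drawn from their
conditional Gaussian under a fixed seed) is provided as a cross-check.
Cells whose covariates lie outside the fitted range are flagged as
extrapolated, never clipped: the CV map is the honest place where
extrapolation shows.

## The synthetic-data generator

The generator replaces the field data with simulations that have the
structure the analysis assumes:

* **Landscape** — a raster of elevation built as a coast-distance trend
  plus a Gaussian random field (white noise smoothed by a separable
  Gaussian kernel, residualized against the trend), mixed so the
  elevation/coast-distance correlation equals a configurable target
  (default 0.65, the regime observed in the study area); forest cover is a
  logistic transform of a second smoothed field, giving patchy values in
  [0, 1] with a few percent of cells above the 0.95 exclusion threshold.
  The coastline is one straight edge of the rectangle, making distance to
  coast analytic and testable.
* **Population** — an inhomogeneous Poisson process of groups with
  per-cell expectation $\lambda(\text{cell}) \times$ cell area, where
  $\log \lambda$ is an intercept plus optional elevation, coast and
  location effects (the inverse of the model the fitter estimates). Group
  sizes are zero-truncated negative binomial (the "mean" parameter is the
  mean of the untruncated NB; a point mass at 1 is available for tests) —
  a convention, since the source reports no group-size distribution.
* **Survey** — systematic parallel transects; every group within 700 m
  perpendicular distance of a flight line is detected with certainty,
  none outside (flat strip caps), and timestamps increase monotonically
  along the path. Detection is deliberately deterministic: the strip
  assumption *is* the observation model.

All randomness flows from explicit integer seeds; pipeline stages derive
sub-seeds by fixed small offsets from the root seed, so identical seeds
give bit-identical outputs. What the generator does **not** emulate:
animal movement and the daily forest/pasture cycle (so no availability
bias), distance-dependent detection, terrain-driven flight-path curvature,
and real covariate maps. Passing tests therefore demonstrate the
correctness and calibration of the *method* under its own assumptions,
not the accuracy of any field estimate.

### Problem sizes used in checks

Desk-scale fixtures use a 28 × 21 km landscape with five transects
(roughly 70 segments). Design-scale recovery runs use a 68.6 × 103.6 km
landscape (49 × 74 cells of 1.4 km, ~7,107 km², 3,626 grid cells) with
eight transects — 592 segments per season — and 50 replicate surveys for
abundance recovery, 20 for smooth-band coverage and AR(1) recovery, and
10,000 posterior draws for the CV cross-check. The acceptance script runs
the full two-season pipeline at this design scale, with seasonal
intensities calibrated so realized densities sit at the study's reported
seasonal levels (about 3.5 and 5.1 individuals/km²).

## Numerical choices and edge cases

* IRLS: relative tolerance 1e-8, 200 iterations, linear predictor capped
  at 35 on the log scale; an all-zero count vector is an error (the
  intercept would diverge).
* $\lambda$ search bounds $[e^{-8}, e^{12}]$ on the log scale for Brent;
  multistart grid $10^{-3} \dots 10^{6}$.
* Terminal remainders: dropped below `min_fraction = 0.5` of a bandwidth,
  else kept with true length and proportionally smaller area (the offset
  absorbs the difference). Whether the original analysis kept partial
  segments is unstated; the rule is exposed as configuration.
* Along-track ties: a record exactly on the boundary between consecutive
  segments goes to the lower order index; overlap of consecutive strips at
  path bends is resolved by along-track position, deterministically.
* Records are matched by photo position, not platform position.
* With the default analytic coastline (a straight western edge), distance
  to coast is numerically identical to the x coordinate. `DC+GL` then
  aliases DC's unpenalized linear part with the location smooth's plane
  term; a minimal ridge (1e-8 of the mean Hessian diagonal) is added only
  when the penalized Hessian is exactly singular, so the fit stays
  defined. `DC:GL` is unidentifiable in that geometry — its (x, y, DC)
  sites are coplanar — and fails with a typed rank error that
  `run_candidates()` records per candidate while ranking the rest. Both
  degeneracies disappear with an irregular real coastline.
* Degenerate inputs error with typed conditions: single-vertex paths,
  zero-variance covariates in the collinearity screen, strips fully
  outside the landscape, all-forest grids, collinear sites for the
  location smooth.

## Known limitations

The REML score is a Laplace approximation on the deviance scale and will
not numerically equal other implementations' restricted likelihoods (model
*rankings* are what the tests pin down). Uncertainty is conditional on
$\lambda$ and on the detection model; no availability or perception bias
enters. The AR(1) working correlation is within-transect only — no
spatial covariance across transects. Tensor-product anisotropic smooths,
soap-film boundaries and negative-binomial responses are out of scope.
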