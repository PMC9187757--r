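---
title: "Population-based motion analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based motion analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackpop)
```

## Why classify before quantifying

Mean-squared-displacement (MSD) analysis of a single short trajectory is
noisy and biased: successive displacements of one track are correlated, so
the time-averaged curve (T-MSD) wanders far from its expectation, and
fitted diffusion constants from 5–15-point tracks scatter over orders of
magnitude even when the underlying mobility is uniform. Pooling tracks
restores power — but only if the pool is homogeneous. Transient trapping,
ubiquitous for molecules in nanoporous hosts and common in cells, produces
three phenomenologically distinct track types from a single pair of
diffusion states: *immobile* tracks (apparent motion is pure localization
error), *mobile* tracks (free diffusion, usually short because the emitter
rapidly defocuses), and *hybrid* tracks containing both. trackpop therefore
classifies tracks into such populations first, using per-track descriptors
and a hierarchical threshold tree, and then estimates diffusion parameters
per population with the time–ensemble-averaged MSD (TE-MSD), which averages
per-track T-MSD curves with equal weight over the $J_n$ tracks that are
long enough to contribute at each delay.

## The observation model

For free 2-D normal diffusion sampled at frame interval $\Delta t$ with
per-coordinate localization error $\sigma$ and motion-blur coefficient $R$,

$$\mathrm{MSD}(t_n) = 4 D t_n + 4(\sigma^2 - 2 R D \Delta t), \qquad n \ge 1 .$$

The slope carries $D$; the delay-independent offset mixes the inflation by
localization error ($+4\sigma^2$) with the deflation by intra-frame motion
averaging ($-8 R D \Delta t$). $R$ depends only on the normalized cumulative
illumination profile $S$ of one frame, $R = \frac{1}{\Delta t}\int_0^{\Delta t}
S(\tau)\,(1 - S(\tau))\,d\tau \in [0, 1/4]$: 0 for a strobe, $1/6$ for
continuous full-frame exposure (`motion_blur_coefficient()` integrates
arbitrary monotone profiles by adaptive quadrature to ~1e-12 relative
error). $R$ and $\sigma$ cannot be separated from a single intercept, so
`fit_msd()` takes $R$ as an input (default $1/6$) and reports $\sigma$,
with `NA` when the implied $\sigma^2$ is negative — which legitimately
happens in noise-dominated fits.

### Fitting conventions

* Window: the `max(min_points, ceiling(fraction * n))` shortest delays,
  defaults `fraction = 0.25`, `min_points = 3`. Short delays are where
  single-track MSD values are least biased; the "at least three points"
  floor keeps the line fit overdetermined.
* Weights: TE-MSD points are weighted by the number of contributing tracks
  $J_n$ (long-delay points average few, long tracks); single-track T-MSD
  fits are unweighted. The paper-style alternative of fitting unweighted
  TE-MSD curves changes little at the default window, which rarely reaches
  delays where $J_n$ decays.
* Uncertainties: for ensemble curves, the per-point standard error from the
  track-to-track scatter is propagated through a sandwich covariance.
  Residual-based ordinary-least-squares errors would understate the
  uncertainty badly, because neighbouring delays share trajectories and the
  curve is smooth. For single-track fits the OLS errors are reported as-is;
  they should be read as descriptive.
* Negative fitted $D$ values are reported, never clipped: for immobile
  tracks the fitted slope scatters around zero and its sign is noise.
* Lags are defined on frame indices, not row offsets, so tracking gaps are
  handled; a lag with no displacement pair is simply absent from the curve.

## Trajectory descriptors

Eight scalars per track (xy projection for the shape descriptors): number
of points; path length $\sum_i |x_{i+1} - x_i|$; tortuosity (path length /
end-to-end distance, $\ge 1$, $\infty$ for closed paths); elongation
$1 - \lambda_2/\lambda_1$ from the gyration-tensor eigenvalues
($0$ isotropic, $1$ collinear) and the orientation of its major axis in
$(-\pi/2, \pi/2]$; Shannon entropy (bits) of localization counts on a
square grid of physical cell size `entropy_bin` (default 100 nm, the scale
of a localization-error footprint, so immobile tracks score near zero);
the minimum bounding circle radius (MBCR); and the distance between the
bounding-circle centre and the centre of mass (MBCC–CoM). Degenerate
descriptors (e.g. elongation of a two-point track) are `NaN`, not errors,
and such columns are simply unavailable to tree training.

The bounding circle is computed exactly by Welzl's randomized incremental
algorithm (C++ core), with the working permutation drawn from a fixed
internal generator so results are deterministic and independent of R's RNG
state; the test suite checks it against an $O(n^4)$ exhaustive oracle.

The MBCR is the natural immobile/mobile discriminator: for a stationary
emitter, localizations scatter around the true position by the localization
error only. `immobile_containment_probability()` quantifies this by Monte
Carlo: the probability that the MBCR of $n$ isotropic Gaussian localizations
stays within a threshold radius. At the defaults of the simulated study
(17 localizations, 118 nm threshold) the probability exceeds 99.99% at the
12 nm in-focus error and stays above 99.9% even at the 28 nm defocused
error — so an MBCR threshold safely captures immobile tracks including
defocused ones. We treat the estimator as Monte-Carlo by construction; an
analytic form for the bounding-circle radius distribution of a finite
Gaussian sample is not available, and the per-coordinate interpretation of
the quoted errors is a declared convention.

## Classification trees

Trees are binary threshold trees over the descriptors ("$\le$ goes left"),
either authored manually (`tree_split()` / `tree_leaf()`, JSON on disk with
17-significant-digit thresholds for bit-identical reload) or trained by
CART-style greedy induction: best-first growth, Gini impurity, candidate
thresholds at midpoints between consecutive distinct values, at most
`max_splits = 5` internal nodes, no pruning, no surrogate splits, equal
class weights. Determinism is guaranteed by explicit tie-breaks
(lexicographic property name, then smaller threshold; leaf labels by
majority with ties to the lexicographically smallest label). The split cap
is the only complexity control — with 100-track training sets, deeper trees
overfit without improving the classification, and the resubstitution loss
plus visual inspection of the classified set are the recommended checks.
Training sets of this size carry real sampling variance: different
training draws can yield trees of different shape (and occasionally a poor
one), which is inherent to the approach, not to this implementation.

## The transient-trapping simulator

`sim_config()` / `simulate_ground_truth()` / `render_observed()` generate
the validation data. The hidden process is a two-state random walk: state 1
trapped ($D_1 = 0$), state 2 free ($D_2 = 10^{-12}\,\mathrm{m^2 s^{-1}}$),
state redrawn at every frame boundary with switching probability 0.02 per
frame (equivalently $0.4\,\mathrm{s^{-1}}$ at $\Delta t = 0.05$ s), start
states uniform. Positions advance in 5 sub-frame steps per frame in a
periodic 3-D box; observation emulates a tracking experiment:

* a frame is observed iff the emitter is within 400 nm of the focal plane
  (the box mid-plane);
* the observed xy position is the average of the 5 substep positions
  (motion blur; `"last-substep"` disables it) plus isotropic Gaussian
  localization error interpolating linearly from 12 nm in focus to 28 nm at
  the edge of visibility;
* maximal runs of observed frames become separate track fragments, and a
  frame in which the walker crossed a periodic boundary in x or y breaks
  the run — a linker would lose an emitter that jumps across the field.

Ground-truth labels (immobile / mobile / hybrid by the frame states
underlying each fragment) ride along for validation.

Defaults the physics does not pin down were set as follows. The box is
$20 \times 20 \times 4\ \mu\mathrm{m}$: the xy extent matches a typical
single-molecule-microscopy field of view and keeps boundary-crossing
censoring rare (with a small xy box, breaking runs at wraps preferentially
censors large displacements and becomes the dominant downward bias on the
mobile-class $D$ — an artifact regime rather than the
immobile-contamination mechanism that actually governs these data sets);
the 4 µm z extent makes the 0.8 µm visible slab a 20% cross-section, so
trajectories fragment realistically. 450 walkers over 600 frames yield
roughly 10,000 observed fragments of which roughly 2,000 survive the
five-localization filter, reproducing the scale of the reference analysis.
What the simulator deliberately does *not* model: PSF rendering and
localization fitting (replaced by direct Gaussian localization noise),
camera noise artifacts, photophysics (blinking, bleaching), and
linking errors between different walkers. Passing validation here
therefore demonstrates correct estimator behaviour under noise,
fragmentation and blur — not robustness to detection or linking failures
of real pipelines.

## Squared-displacement survival analysis

At fixed lag (default 1 frame), squared displacements pooled over a
population are exponentially distributed for a single normal-diffusion
state, with mean equal to the MSD at that lag; `empirical_survival()` gives
the $1-\mathrm{CDF}$ curve (straight in semi-log), and
`fit_exponential_mixture()` fits a 1- or 2-component exponential mixture by
EM — maximum likelihood on the displacements themselves rather than a
least-squares fit of the plotted curve, which is statistically better
behaved in the tail. Multi-start (5 seeded starts: one quantile-based,
the rest randomized) guards against local optima; scales are floored at
$10^{-12}$ of the sample mean to keep the likelihood bounded; convergence
is declared at a relative log-likelihood change below $10^{-10}$, and
non-convergence raises an error carrying the best iterate. With $k = 1$
the MLE is the sample mean, returned in closed form. The two-component fit
on the classified mobile population is how the residual fraction of
immobile steps (misclassified hybrid segments) is measured — a few percent
at the study conditions, which quantitatively explains the mobile
population's $D$ sitting a few percent below the simulated $D_2$.

## Numerical and interface choices

* Internal units are SI throughout (metres, seconds); import converts from
  pixels once, via `pixel_size`.
* Degenerate inputs follow one rule: per-track descriptor pathologies
  yield `NaN`s recorded in tables; malformed files, invalid configurations
  and non-finite values at a tested tree property raise errors naming the
  offending column, row or trajectory.
* Every stochastic routine (simulator, Monte-Carlo containment, EM starts)
  takes an explicit seed and restores the caller's RNG state, so pipelines
  are reproducible end to end; the command-line driver threads one seed
  through all steps and stamps outputs with the package version and a hash
  of the analysis configuration.
* Problem sizes in the validation suite (e.g. $10^6$ Monte-Carlo
  replicates for containment probabilities, $10^6$ frame boundaries for
  switching-rate recovery, 450-walker end-to-end runs) were chosen so each
  check resolves its target at the stated tolerance with comfortable
  margin.

## Known limitations

Only the normal-diffusion MSD model is fitted; confined, directed and
anomalous models, and covariance-based estimators, are out of scope.
Mixtures are limited to two exponential components. 3-D data are carried
through import and MSD analysis, but shape descriptors use the xy
projection (no bounding spheres). The trained tree is a deliberately small,
interpretable model: it will not match flexible classifiers on hard
boundaries, and with 100-track training sets its quality varies with the
training draw.
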