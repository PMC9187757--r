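# trackpop

Population-based motion analysis of single-particle tracking (SPT) data.

Single-molecule trajectories recorded in porous materials, on surfaces, or
in cells mix qualitatively different motion behaviours: emitters adsorb and
sit still, escape and diffuse freely, or alternate between the two
(transient trapping). Individual tracks are typically short (5–15
localizations) and carry too little information for a reliable model fit on
their own. trackpop follows a *classify-then-quantify* workflow: compute
per-trajectory shape descriptors, sort trajectories into populations with a
hierarchical threshold tree (hand-built or trained), and only then quantify
diffusion per population, where pooling restores statistical power.

## The estimators

For a track with positions $x_0, x_1, \ldots, x_N$ at frame interval
$\Delta t$, the time-averaged mean squared displacement at delay
$t_n = n\Delta t$ is

$$\mathrm{T\text{-}MSD}(t_n) = \frac{1}{N-n+1}\sum_{i=0}^{N-n} |x_{i+n}-x_i|^2 ,$$

and the time–ensemble average pools the per-track curves over the $J_n$
tracks long enough to contribute at each delay, each track weighted
equally. For free 2-D normal diffusion observed with localization error
$\sigma$ and motion-blur coefficient $R \in [0, 1/4]$,

$$\mathrm{MSD}(t_n) = 4 D t_n + 4(\sigma^2 - 2 R D \Delta t),$$

so a weighted linear fit over the shortest 25% of delays (at least three
points) yields the diffusion constant $D$ from the slope and $\sigma$ from
the intercept, given $R$ ($R = 1/6$ for full-frame exposure,
`motion_blur_coefficient()` for arbitrary illumination profiles). At fixed
lag, the survival function of squared displacements for a single diffusive
state is exponential,
$1 - \mathrm{CDF}(r^2, t_n) = \exp\!\left(-r^2/\mathrm{MSD}(t_n)\right)$;
multiple decays reveal mixed populations, quantified here by an
expectation-maximization fit of an exponential mixture.

Classification uses eight per-track descriptors (number of points, path
length, tortuosity, gyration-tensor elongation and orientation, spatial
entropy, minimum bounding circle radius, and the distance between the
bounding-circle centre and the centre of mass). Trees are trained by greedy
Gini induction with at most five splits, and evaluated by resubstitution
loss.

A built-in simulator generates two-state transient-trapping trajectories
(trapped state $D_1 = 0$, free state $D_2 = 10^{-12}\,\mathrm{m^2 s^{-1}}$,
switching probability 0.02 per frame) in a periodic box, observed through a
focal slice with defocus-dependent localization error — so the full
workflow can be validated against known ground truth.

## Worked example

```r
library(trackpop)
library(dplyr)

tracks <- simulate_tracks(sim_config(seed = 101)) |>
  filter_min_localizations(5)
#> # track_set: 42421 localizations in 2249 trajectories, dt = 0.05 s

props <- compute_properties(tracks)
truth <- distinct(as_tibble(tracks), id, label)   # ground-truth labels

set.seed(202)
training <- truth[sample(nrow(truth), 100), ]     # a 100-track training set
tree <- train_tree(props, training)
tree
#> # motion_tree: 5 split(s), labels: hybrid, immobile, mobile
#> n_points <= 19.5
#>   entropy <= 0.961
#>     * immobile
#>     ...
resubstitution_loss(tree, props, training)
#> [1] 0.03

classified <- classify_tracks(
  track_set(select(as_tibble(tracks), -label), dt = 0.05), tree, props
)
count(distinct(as_tibble(classified), id, label), label)
#>   hybrid 372 | immobile 67 | mobile 1810

mobile <- as_tibble(classified) |>
  filter(label == "mobile") |>
  track_set(dt = 0.05)
fit_msd(te_msd(mobile), R = 1/6)
#> # msd_fit (time-ensemble-averaged, 5 points):
#> #   D = 9.348e-13 +/- 2.1e-14 m^2/s

fit_exponential_mixture(squared_displacements(mobile, 1), k = 2, seed = 3)
#> # expmix_fit: k = 2, n = 12151
#>   component 1: fraction 0.9602, scale 1.357e-13 m^2
#>   component 2: fraction 0.0398, scale 1.464e-15 m^2
```

The mobile population's diffusion constant comes out a few percent below
the simulated $D_2 = 10^{-12}\,\mathrm{m^2 s^{-1}}$: the mixture fit shows
why — about 4% of its lag-1 displacements are near-immobile steps from
imperfectly separated hybrid segments, which dilute the population average.
The large-scale mixture component matches the lag-1 MSD of the mobile
state after motion-blur deflation ($4 D \Delta t (1 - 2R) \approx 1.36
\times 10^{-13}\,\mathrm{m^2}$).

Classified trajectory tables, property tables, trees (JSON) and curves all
read and write through plain-text formats; `?trackpop_cli` documents the
command-line pipeline (`inst/cli/trackpop`) wrapping the same functions.

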