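---
title: "Methods: PERIL scoring, clade volatility, and vulnerability mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PERIL scoring, clade volatility, and vulnerability mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perilscore)
```

## The model

PERIL expresses a species' *intrinsic* extinction vulnerability — its
sensitivity to perturbation as implied by its own traits and its clade's
fossil history — as a relative score within an analyzed species pool:

$$\mathrm{PERIL}_i = \tfrac{1}{3}\left[s(\hat q_i) + s(1/\ln r_i) + s(1/T_i)\right]$$

with $\hat q$ the per-capita Cenozoic extinction rate of the species' family
(per Myr), $r$ the geographic range area (km²) and $T$ the realized thermal
range (°C), and $s(\cdot)$ min–max rescaling to $[0,1]$ across the pool.
Inversion of $r$ and $T$ encodes the empirical regularity that wide
geographic and thermal ranges confer extinction resistance; both matter
separately because widespread species are not necessarily eurythermal — many
track a narrow temperature band across a large area.

Three assumptions are worth keeping in view. First, the score is *relative*:
rescaling ties every component to the pool being analyzed, so a species'
score changes if the pool does, and scores are not absolute extinction
probabilities. Second, family-level volatility is inherited unchanged by
every species in the family; within-family variation in extinction proneness
is not modelled. Third, combining components with equal weight is a
deliberate neutral choice, not an estimated weighting.

### Combination rule

The printed form of the metric is a sum of the three rescaled components,
but a sum ranges over $[0,3]$ while published per-species values of the
metric lie in $[0,1]$ with maxima near 0.9 — consistent with the mean of the
three components. We therefore default to the mean (`combine = "mean"`),
which also keeps a score of 1 interpretable as "extreme in every component",
and provide `combine = "sum"` for the literal reading; the two differ only
by the constant factor 3 and give identical rankings and classifications.

### Species with zero thermal range

A species occupying a single grid cell has $T = 0$ and an undefined $1/T$.
Such species are maximally thermally restricted, so before rescaling they
are assigned the largest *finite* raw $1/T$ observed among $T > 0$ species,
mapping them to the top of the inverse-thermal component. The alternative —
dropping them — would systematically remove exactly the most
geographically restricted species from a vulnerability analysis.

### Thresholds

"Vulnerable" species are those *strictly above* a quantile of a reference
pool (`classify()`, `vulnerable()`): ties fall below, quantiles use R's
default linear-interpolation convention (type 7), and the convention is
recorded in the output attributes because threshold counts near the median
are sensitive to it. When a subset is classified (e.g. FAO-listed species
against the global median), the reference pool stays the full analyzed set:
rescaling and thresholds are properties of the whole analysis, not of the
subset.

## Clade volatility from fossil ranges

`family_qhat()` uses the boundary-crosser protocol on genus-level first/last
stratigraphic occurrences. For a stage of duration $\Delta t$, $N_b$ genera
cross its bottom boundary (first occurrence strictly older, last occurrence
in the stage or younger) and $N_{bt}$ of those also cross its top; the
per-capita rate is $q = -\ln(N_{bt}/N_b)/\Delta t$. Conventions:

* **Singletons** (genera confined to one stage) cross no boundary and enter
  neither count — the standard protocol, robust to uneven sampling.
* **Complete-extinction stages** ($N_{bt}=0$) have no finite rate and are
  dropped from aggregation, with a message; capping them at an arbitrary
  finite rate would let one stage dominate the mean.
* **Aggregation** across the Cenozoic is the duration-weighted mean of
  defined stage rates, $\sum q_i \Delta t_i / \sum \Delta t_i$, which is
  algebraically the pooled survivorship estimator over the usable stages.
  An unweighted mean (`method = "mean"`) is provided; it upweights short
  stages and is noisier.
* The packaged `cenozoic_stages()` table uses standard ICS boundary ages
  (22 stages, 66–0 Ma); any contiguous `stage_scale()` is accepted.

Under time-homogeneous extinction with exponential genus lifetimes the
estimator is consistent; on simulated records it recovers a generating rate
of 0.15/Myr to within ±0.02 at 1000 genera (verified in the test suite and
the acceptance script).

## Trait assembly

* **Body size** is the geometric mean of shell length and height (mm).
* **Geographic range** is the convex-hull area of projected point
  occurrences, computed in an equal-area plane (Lambert cylindrical
  equal-area on a spherical datum for real data; all package geometry is in
  km). Species known from a single point take a nominal 100 km² floor
  (a 10 × 10 km footprint). Degenerate hulls — two points, collinear
  occurrences — also take the floor: a zero-area range is biologically
  meaningless and would put $\ln r \le 0$ in the score. A documented
  `override` (e.g. a single-estuary endemic's known range) bypasses the
  hull.
* **Grid occupancy** intersects the hull with the grid cells. A
  positive-area hull claims the cells whose *interiors* it intersects
  (separating-axis test), so a hull lying exactly on a block of cells
  claims that block and not its boundary neighbours; degenerate hulls use
  closed intersection so isolated points still land in a cell. Species
  crossing the antimeridian should be split at ±180° before projection —
  an approximation inherited from computing hulls in a single projected
  plane.
* **Thermal range** is max − min of per-cell mean SST across occupied
  cells. One mean-annual value per cell is assumed; whether a monthly
  extreme envelope would be preferable is left to the caller, who supplies
  the per-cell value in the grid (`sst_mean`).
* **Minimum bathymetry** descriptors "subtidal"/"sublittoral" impute 5 m
  and "shallow water" 10 m; imputed values carry a flag so sensitivity
  analyses can exclude them. Zero is a legal (intertidal) value, which is
  why missing values are empty fields, never 0.

## Phylogenetic signal

`phylo_d()` implements the D statistic for a binary trait. Nodal values are
estimated by a Felsenstein-style weighted-average downpass (weights inverse
to working branch lengths, which grow as information is combined), and the
observed sum of daughter differences is standardized between two simulated
nulls: tips shuffled at random (D calibrated to 1) and Brownian traits
rank-thresholded to the observed prevalence (D calibrated to 0).
Rank-thresholding keeps prevalence fixed as an ancillary rather than letting
it drift across simulations. Polytomies contribute the sum of
|daughter − nodal mean|. The calibration itself — mean D within 1 ± 0.1
under shuffling and 0 ± 0.1 under Brownian thresholding at 200 replicates on
a 64-tip tree — is the acceptance surface, since different nodal estimators
give slightly different raw d sums but the same standardized behaviour.
`p_random` is the fraction of random-null d values ≤ observed (small when
the trait is more clumped than random); `p_brownian` the fraction of
Brownian-null d values ≥ observed.

`pagel_lambda()` maximizes the multivariate-normal likelihood with
off-diagonal covariance multiplied by λ, bounded on [0, 1]; λ > 1 would
require shrinking tip branches and is not meaningful for proportions data.
`blomberg_k()` uses the standard variance-ratio form with a tip-shuffling
permutation p-value; a star phylogeny is rejected because its
phylogenetically corrected variance carries no information. Both are
cross-checked against an independent reference implementation in the test
suite.

## Exploitation–trait association

`fit_exploitation_model()` is a deterministic maximum-likelihood analogue of
a Bayesian hierarchical regression: logistic regression of exploitation on
standardized traits with a family-level Gaussian random intercept, the
integral over intercepts handled by Laplace approximation (`lme4::glmer`).
Shell size and range area are log10-transformed and bathymetry
log10(x+1)-transformed before z-standardization — these traits span orders
of magnitude, and coefficients then read as log-odds per SD on comparable
scales; a `transform = "none"` switch is provided. A phylogenetic
variance-covariance random effect is deliberately omitted: at the family
level, membership alone absorbs nearly all the group-level variance, and the
phylogenetic extension is not separately identifiable in practice here.
With `random_intercept = FALSE` the model collapses to plain logistic
regression and matches an independent IRLS fit to 1e-6 (tested).

For distribution comparisons the KS direction is always an explicit
argument, never inferred from the data; ties in bathymetry (many species at
0 m) are handled by the ECDF/midrank conventions of the underlying tests and
noted in the output. Binomial intervals are exact Clopper–Pearson via the
beta-quantile identity.

## Biogeography

Regions are data, not geometry: the default scheme crosses latitudinal
climate bands (|lat| ≤ 23.44° tropical, ≤ 66.56° temperate, else polar,
from equal-area `y = R\sin(\mathrm{lat})`) with an optional coastline label,
and any cell→region table overrides it. A species spanning several regions
is assigned to the region holding the most of its occupied cells, ties
broken alphabetically — a documented convention, since no standard exists.
A species contributes to every cell its hull-derived occupancy covers,
regardless of where it is actually fished: the layer maps the broadest
possible spatial footprint of exploitation. `vulnerability_layer()` reports
counts and both Fig.-style proportions (exploited among vulnerable,
vulnerable among exploited) per cell, with the threshold rule and quantile
convention in attributes and in the GeoJSON sidecar.

## The synthetic generator

`simulate_fauna()` emulates the statistical structure of the study system:
a birth–death family tree rescaled to 500 Myr; lognormal family sizes; an
equatorially symmetric SST gradient (28 °C to −2 °C) with cell noise;
rectangular occupancy footprints sized to lognormal range areas (median
near 10⁴ km²), of which a fraction `p_iso` (default 0.25) follow isotherms
— wide ranges with narrow thermal breadth — so thermal range is *derived*
from the footprint rather than drawn, giving a realistic but imperfect
range–thermal correlation (~0.8); and exploitation labels drawn from the
logistic model with default effects +0.8 (size), −0.5 (bathymetry), +0.5
(geographic range), +0.5 (thermal range), +0.5 (attached), intercept −2.2
(≈13% exploited) and family-intercept SD 1.

`simulate_s1_table()` produces a table shaped like the compiled trait
dataset, reproducing its *structural* composition exactly by construction:
6127 species in 80 families, 801 exploited (81 FAO-listed, 720 literature
additions) confined to 44 families, a volatile scallop-analog family with
62 exploited species and an oyster-analog with 38, and 580
single-occurrence species at the 100 km² floor. Continuous traits are drawn
with exploited-species shifts in the established directions. Statistics
that depend on the real trait values — the KS distance between exploited
and non-exploited score distributions, quantile exceedance counts, top
scores — are therefore *emulated*, not reproduced: passing tests on this
table show the pipeline computes the right quantities under the right
structure, not that it recovers the published values, which require the
deposited dataset itself.

Neither generator attempts real coastline geometry, spatially autocorrelated
sampling effort, taxonomic error, or dispersal/niche processes; conclusions
about robustness to those features cannot be drawn from these tests.

## Numerical choices and problem sizes

Quantiles are type 7 everywhere, recorded in outputs. Zero-length branches
are guarded at 1e-8 Myr in the D-statistic downpass; singular phylogenetic
covariances raise an error suggesting jittering rather than being silently
regularized. Constant vectors rescale to all zeros with a warning.
Hull/occupancy geometry is exact (separating-axis), not rasterized; the
test suite checks it against a 1-km rasterization oracle.

The validation suites run at sizes chosen to make calibration targets sharp
but cheap: fossil-rate recovery at 1000 genera, phylo-D calibration at 200
replicates × 100 simulations on 64 tips, λ recovery at 100 replicates on
128 tips, and hierarchical-model recovery at 5000 species × 60 families ×
50 replicates (10 in the acceptance script). The whole suite completes in a
few minutes on one CPU.

## Known limitations

* Scores are pool-relative; cross-study comparison requires rescoring in a
  common pool.
* Family-level $\hat q$ ignores within-family heterogeneity, and the
  boundary-crosser estimator is biased where stages are so short that
  counts are tiny (the weighted mean damps but does not remove this).
* The ML hierarchical model reports point estimates; it does not replace a
  full posterior treatment when uncertainty in the trait effects is itself
  of interest.
* Antimeridian-spanning ranges are handled by splitting before projection —
  adequate at 50-km resolution but still an approximation.
* The regional threshold depends on the single-region species assignment;
  for species with truly balanced multi-region ranges the majority rule is
  arbitrary (ties alphabetical) and flagged as a convention.
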