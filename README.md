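# perilscore

Trait-based intrinsic extinction-vulnerability assessment for exploited
marine bivalves (and other shallow-marine benthos with a usable fossil
record).

Most marine invertebrates harvested for food have never had a formal
conservation assessment. For data-poor groups, a species' own traits and its
clade's fossil history are the most accessible predictors of how sensitive it
is to perturbation. This package implements that assessment end to end: it
assembles the four continuous traits that predict extinction resistance in
bivalves (shell size, minimum bathymetry, geographic range area, realized
thermal range), estimates each family's Cenozoic extinction rate from genus
stratigraphic ranges, combines them into the **PERIL** score (Paleontological
Extinction Risk In Lineages), tests whether exploitation is phylogenetically
structured and which traits predict it, and maps where intrinsically
vulnerable exploited species concentrate on an equal-area shelf grid.

## The score

For species *i* with family per-capita extinction rate ("clade volatility")
q̂, geographic range *r* (km², the convex-hull area of its point occurrences,
floored at 100 km² for single-occurrence species) and realized thermal range
*T* (°C, the spread of sea-surface temperature across its occupied 50 × 50 km
grid cells):

    PERIL_i = [ s(q̂_i) + s(1 / ln r_i) + s(1 / T_i) ] / 3

where s(·) is min–max rescaling to [0, 1] across the analyzed species pool.
Ranges enter inverted so that wide-ranging, eurythermal species in stable
clades score near 0 and narrow-ranged, stenothermal species in volatile
clades score near 1. Single-cell species (T = 0) take the largest observed
raw 1/T — they are maximally thermally restricted. Averaging (rather than
summing) the three rescaled components keeps the score itself in [0, 1]; a
`combine = "sum"` switch is provided.

Clade volatility comes from boundary-crosser counts on a stage scale: for an
interval of duration Δt with N_b genera crossing its bottom boundary and
N_bt crossing both boundaries, q = −ln(N_bt/N_b)/Δt, aggregated across the
Cenozoic as a duration-weighted mean (`family_qhat()`).

Around the score the package provides the phylo-D statistic (binary trait;
in-package implementation calibrated so D ≈ 1 for a phylogenetically random
trait and D ≈ 0 under Brownian-threshold evolution), Pagel's λ (bounded ML)
and Blomberg's K with a permutation test; one-sided two-sample
Kolmogorov–Smirnov and Wilcoxon rank-sum comparisons and Clopper–Pearson
binomial intervals; a family random-intercept logistic regression of
exploitation on standardized traits (`lme4` under the hood); and per-cell
vulnerability layers under global or region-specific quantile thresholds.
A synthetic-data generator (`simulate_fauna()`, `simulate_s1_table()`,
`simulate_fossil_record()`, `simulate_tree()`) produces every input with
known ground truth.

## Worked example

```r
library(perilscore)

cfg   <- sim_config(seed = 42, n_species = 500, n_families = 20)
fauna <- simulate_fauna(cfg)

# clade volatility from a simulated fossil record
fossil <- simulate_fossil_record(fauna$tree$tip.label,
                                 q_true = fauna$truth$qhat,
                                 n_genera = 40, seed = 43)
head(family_qhat_table(fossil), 3)
#>   family      qhat n_genera n_intervals
#> 1  fam01 0.1732099       40          17
#> 2  fam02 0.1188730       40          20
#> 3  fam03 0.0698412       40          20

scores <- peril(fauna$records)
summary(scores)
#> PERIL score summary (500 species, combine = mean)
#>    0%   25%   50%   75%   80%  100%
#> 0.031 0.224 0.335 0.604 0.704 1.000
#> median by exploitation:
#>     exploited non-exploited
#>         0.193         0.369
#> KS exploited vs non-exploited: D = 0.400, p = 1.27e-11

fit <- fit_exploitation_model(fauna$records)
fit
#> Exploitation ~ traits + (1 | family)
#>   n = 500 species, 20 families; transform = log10; converged: TRUE
#>   intercept -1.934; family intercept SD 1.208
#>     size_mm min_bathy_m     gra_km2        tr_c
#>       0.755      -0.449       0.738       0.488
```

The exploited species score *lower* (median 0.193 vs 0.369) because the
generator, like the real fauna, makes exploited species larger, shallower and
wider-ranging — and wide ranges confer extinction resistance. The model
coefficients (log-odds per SD) recover that generating structure: positive
for size, geographic and thermal range, negative for minimum bathymetry.

Mapping the intrinsically vulnerable exploited species:

```r
rec <- cbind(fauna$records[c("species_id", "exploited")],
             peril = peril_scores(scores))
v <- vulnerability_layer(rec, fauna$occupancy, quantile = 0.5,
                         scope = "global")
head(v[order(-v$n_vulnerable_exploited),
       c("cell_id", "n_species", "n_exploited", "n_vulnerable_exploited")], 3)
#>        cell_id n_species n_exploited n_vulnerable_exploited
#> 1219 c024_r044         8           5                      2
#> 1277 c025_r044         8           5                      2
#> 3309 c061_r045         6           4                      2
```

`classify(scores, quantile = 0.8)` flags the top-20% species; with
`scope = "regional"` thresholds are computed within climate-band × coastline
regions (`assign_regions()`, `species_region()`).

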