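Package: perilscore
Title: Intrinsic Extinction Vulnerability of Exploited Marine Bivalves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trait-based intrinsic extinction-vulnerability assessment for
    shallow-marine bivalves and other benthic faunas. Assembles continuous
    species traits (shell size, minimum bathymetry, convex-hull geographic
    range, sea-surface-temperature range) from point occurrences on an
    equal-area shelf grid, estimates per-capita genus extinction rates of
    families from fossil stratigraphic ranges (clade volatility), and combines
    clade volatility with inverted geographic and thermal range into the PERIL
    composite score. Provides phylogenetic-signal tests of exploitation
    (phylo-D for a binary trait, Pagel's lambda and Blomberg's K for
    continuous traits), exploitation-trait association statistics
    (Kolmogorov-Smirnov, Wilcoxon rank-sum, Clopper-Pearson intervals, and a
    family random-intercept logistic model), equal-area-grid biogeographic
    mapping of vulnerable exploited species under global or regional quantile
    thresholds, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    phytools,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
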