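Package: gutdrift
Title: Transmission Bottlenecks and Colonization Heterogeneity in
    Two-Strain Gut Symbioses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how transmission bottleneck size shapes
    between-host and within-host heterogeneity when two labelled bacterial
    strains compete to colonize a host organ. Provides a neutral and
    fitness-asymmetric founder-sampling simulator of co-inoculation trials
    (Poisson ingestion, binomial strain split, deterministic within-host
    expansion, Poisson/binomial plating), the between-host heterogeneity
    statistics used in such trials (sample bimodality coefficient with
    leave-one-out jackknife, Hartigan's dip statistic with a Monte-Carlo
    p-value, population variance, and a two-strain fixation index), a
    spatial model of an ordered crypt array colonized under an
    anterior-posterior founder-budget gradient, and the
    fluorescence-transect quantification pipeline (background
    normalization with clamping, log intensity ratio, sliding-window
    variance). Synthetic-data generators emulate complete co-inoculation
    experiments so every pipeline stage is testable without laboratory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
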