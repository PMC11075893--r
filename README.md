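# gutdrift

Transmission bottlenecks and colonization heterogeneity in two-strain gut
symbioses.

Many insects acquire their bacterial symbiont from the environment every
generation, and only a handful of cells survive the transfer into the
symbiotic organ. When the founding population is that small, ecological
drift — not host control or competition — can decide which strain wins in
each host. `gutdrift` implements the analysis toolkit for the standard
two-strain co-inoculation design that probes this: a green- and a
red-labelled strain are mixed at a fixed ratio and fed to host cohorts
across a ladder of inoculum densities (a proxy for bottleneck size), and the
per-host strain proportions recovered by plating are tested for
between-host heterogeneity.

The package provides:

* **Trial data handling** — colony-count tables (CSV/TSV, one row per
  host), strain proportions, half-open decade binning of inoculum densities
  with optional pooled low-density groups, colonization success rates.
* **Heterogeneity statistics** — the sample bimodality coefficient
  `BC = (G1² + 1) / (G2 + 3(n−1)²/((n−2)(n−3)))` (bias-corrected skewness
  `G1` and excess kurtosis `G2`), whose uniform-distribution reference value
  is `1/1.8 ≈ 0.556`; leave-one-out jackknife replicates; Hartigan's dip
  statistic `min_G sup |F_n − G|` over unimodal distribution functions
  (compiled modal-interval GCM/LCM algorithm, plus an independent exhaustive
  oracle used for validation); seeded Monte-Carlo dip p-values; population
  variance; and the two-strain fixation index `Var(x) / (p̄(1−p̄))`.
* **A generative drift model** — founders `N ~ Poisson(λ)` with
  `λ = density × ingestion volume × establishment probability`, binomial
  strain split, deterministic within-host expansion with optional fitness
  asymmetry `q = k·wᵗ / (k·wᵗ + N − k)`, Poisson/binomial plating; plus the
  closed forms `P(colonized) = 1 − e^(−λ)` and the monoclonal-infection
  probability used to verify it.
* **A crypt-array spatial model and transect pipeline** — an ordered
  anterior→posterior array of crypts colonized under a decaying founder
  budget, rendered to two-channel fluorescence transects; quantification by
  background subtraction with a clamp floor, per-pixel log RFP/GFP ratio,
  and a sliding-window (10% of transect length) variance profile.
* **Synthetic experiments and a CLI** — seed-stable generators that emit
  complete experiments (treatment CSVs, transects, hashed manifest) and
  subcommands `simulate`, `analyze-trials`, `analyze-transect`, `fixtures`.

## Worked example

Simulate a neutral isogenic experiment across densities 10¹–10⁶ CFU/µL,
pool the hosts below 100 CFU/µL, and test the pooled group for
heterogeneity:

```r
library(gutdrift)

spec <- experiment_spec("neutral_isogenic", hosts_per_treatment = 30, seed = 7)
out <- tempfile()
generate_experiment(spec, out)

oc <- read_trials(file.path(out, "treatments", "pooled_all.csv"))
groups <- bin_by_decade(oc, pool_below = 100)

heterogeneity_report(groups[["<1e2"]], n_null = 999, seed = 7)
#> <heterogeneity_report '<1e2': n=13>
#>   bimodality coefficient: 0.6106 (jackknife mean 0.5921)
#>   dip: 0.2308 (Monte-Carlo p = 0.001, 999 null draws)
#>   population variance: 0.2317   fixation index: 0.9273
#>   colonization success: 13/30 (0.43)

heterogeneity_report(groups[["1e6"]], n_null = 999, seed = 7)
#> <heterogeneity_report '1e6': n=30>
#>   bimodality coefficient: 0.4803 (jackknife mean 0.4782)
#>   dip: 0.0574 (Monte-Carlo p = 0.647, 999 null draws)
#>   population variance: 0.0037   fixation index: 0.0149
#>   colonization success: 30/30 (1.00)
```

Under the tight bottleneck (pooled < 100 CFU/µL, mean founder number below
~5) the 13 colonized hosts are dominated by one strain or the other: the
bimodality coefficient exceeds the 0.555 uniform threshold, the dip test
rejects unimodality (p = 0.001), and the fixation index is near 1 (hosts
close to fixation for opposite strains). Under the loosest bottleneck
(10⁶ CFU/µL) every host is colonized, proportions concentrate near the 1:1
inoculum ratio, and all heterogeneity measures collapse.

The whole density ladder in one call:

```r
bc_vs_bottleneck_curve(sim_params(), densities = 10^(1:6),
                       n_hosts = 30, n_reps = 20, seed = 7)
#>   density lambda_eff mean_bc  sd_bc mean_success mean_red_fraction
#> 1   1e+01      5e-01   0.587 0.1049        0.415             0.410
#> 2   1e+02      5e+00   0.377 0.0739        0.993             0.507
#> 3   1e+03      5e+01   0.386 0.0646        1.000             0.500
#> ...
```

Mean bimodality falls and colonization success rises as the bottleneck
loosens — the drift signature this design exists to detect.

The command-line launcher wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("exec", "gutdrift", package = "gutdrift"))') \
  simulate --out sim_out --seed 7 --hosts 30
```

## Data format

Trial CSVs carry the header `host_id, trial_id, inoculum_density_cfu_per_ul,
green_count, red_count` (UTF-8, `.` decimal separator); the column mapping is
configurable in `read_trials()`, so supplementary XLSX tables from published
experiments can be used after a one-off export to CSV with these columns.
Transect CSVs carry `position_px, gfp_raw, rfp_raw, gfp_background,
rfp_background`.

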