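---
title: "Transmission bottlenecks and colonization heterogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission bottlenecks and colonization heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutdrift)
```

## The experimental system

Many animals acquire a specific bacterial symbiont from the environment each
generation. In squash bugs (*Anasa tristis*), nymphs ingest *Caballeronia*
cells while feeding, and the survivors of that transfer found the population
of a dedicated posterior midgut organ composed of hundreds of sac-like
crypts. The number of cells that make it through this step — the
transmission bottleneck — is small and variable, so ecological drift can
dominate the outcome: with few founders, otherwise identical hosts end up
carrying very different communities.

A clean way to study this is a two-strain co-inoculation: mix a
green-labelled and a red-labelled strain at a fixed ratio, dilute the
mixture across several orders of magnitude of density (CFU/µL), feed it to
cohorts of nymphs, and later plate each gut and count colonies of each
colour. Inoculum density then serves as a proxy for bottleneck size while
the strain ratio is held constant. `gutdrift` packages three things around
this design:

1. a generative model of the experiment (`sim_params()`,
   `simulate_cohort()`) with closed-form checks;
2. the between-host heterogeneity statistics used to analyze it
   (`bimodality_coefficient()`, `dip_statistic()`, `strain_fst()`,
   `heterogeneity_report()`);
3. a within-host spatial model of crypt colonization and the
   fluorescence-transect quantification used to detect it
   (`simulate_crypts()`, `render_transect()`, `analyze_transect()`).

## The drift model

One host is simulated in four stages:

* **Founding.** The number of establishing cells is
  $N \sim \mathrm{Poisson}(\lambda)$ with
  $\lambda = \text{density} \times \text{ingestion volume} \times
  \text{establishment probability}$.
  Ingestion events are rare and independent at feeding densities, which is
  what makes the Poisson law (rather than a fixed-volume multinomial) the
  natural choice; it also yields the closed forms below. A host with $N = 0$
  is uncolonized.
* **Strain split.** Red founders $k \sim \mathrm{Binomial}(N, p)$ with $p$
  the red fraction of the inoculum (default 0.5, matching a nominal 1:1
  mix).
* **Within-host expansion.** The final red proportion is deterministic given
  the founders: $q = k w^t / (k w^t + N - k)$, with fitness ratio $w$ and
  $t$ effective rounds of competition ($w = 1$ recovers the neutral model
  exactly). Post-founding demographic drift is omitted because crypt
  populations grow to $10^4$–$10^7$ cells, where drift is negligible
  relative to the founding bottleneck; a Pólya-urn variant
  (`polya_drift = TRUE`) is available to check sensitivity to that
  assumption (it widens outcome distributions without biasing them).
* **Plating.** Colonies scored $m \sim \mathrm{Poisson}(\text{mean colonies
  counted})$, conditioned on $m \ge 1$ because a dissected colonized gut
  always yields colonies; red colonies $\sim \mathrm{Binomial}(m, q)$ —
  colonies are a small sample of a huge population, so binomial rather than
  hypergeometric.

Two closed forms make the model testable without reference to its own code:
the colonization probability $1 - e^{-\lambda}$, and the probability that a
colonized host's founders are monoclonal,

$$
P(\text{pure} \mid \text{colonized}) =
\frac{e^{-\lambda(1-p)} + e^{-\lambda p} - 2e^{-\lambda}}{1 - e^{-\lambda}},
$$

which the test suite re-derives by direct numerical summation over founder
counts and compares against simulations of $10^5$ hosts at
$\lambda \in \{0.5, 1, 2, 4\}$ within three binomial standard errors.

**Calibration.** Density, ingestion volume and establishment probability
enter only through $\lambda$, and no measurement of the latter two exists
for this system, so the pair is a free composite. The defaults
(`ingestion_volume = 1` µL, `establishment_prob = 0.05`) were chosen once so
that the transition from bimodal to unimodal outcomes falls below roughly
100 CFU/µL on the experimental ladder $10^1$–$10^6$ CFU/µL — the regime the
insect experiments identify — and are not otherwise tuned. No claim is made
about their field values. `mean_colonies_counted = 50` reflects typical
per-gut colony counts in such assays.

**Reproducibility.** Every cohort draws per-host sub-seeds from its seed, so
results are independent of evaluation order and byte-stable across runs.

## Heterogeneity statistics

All statistics operate on the red-strain proportions of the *colonized*
hosts of a treatment group; uncolonized hosts are retained for success rates
but excluded from proportion-based statistics (they carry no composition
information).

**Bimodality coefficient.** $BC = (G_1^2 + 1) / (G_2 + 3(n-1)^2 /
((n-2)(n-3)))$ with bias-corrected sample skewness $G_1$ and excess kurtosis
$G_2$ (the SAS convention used by the coefficient's standard
implementations). The large-sample value for any uniform distribution is
$1/1.8 \approx 0.556$ (`bc_uniform_limit()`), the conventional threshold
above which a sample is called bimodal; equal-mass two-point data approach
1. A constant input has undefined moments and returns flagged `NaN` rather
than an error, so screens over many groups can proceed. Because the
coefficient is sensitive at small $n$, `jackknife_bc()` provides
leave-one-out replicates (the standard jackknife; the alternative grouped
jackknife is not implemented).

**Hartigan's dip.** The minimum over all unimodal distribution functions $G$
of $\sup_x |F_n(x) - G(x)|$, computed in compiled code by the iterative
greatest-convex-minorant / least-concave-majorant algorithm on the sorted
sample. One definitional subtlety matters for colony-count data: a unimodal
cdf may carry an atom *at its mode* (it is continuous everywhere else), so a
sample with one large tie group — common when many hosts are pure for one
strain — can be nearly unimodal even though a continuous fit would be far
away. The package also ships `dip_statistic_exhaustive()`, an independent
oracle that re-derives the dip by bisection over band-threading feasibility
checked exhaustively over every candidate modal knot; the test suite asserts
agreement to $10^{-12}$, along with the analytic anchors
$\mathrm{dip}(\{0,0,1,1\}) = 1/4$ (the global maximum) and the universal
lower bound $1/(2n)$.

**Dip p-value.** Monte-Carlo calibration against the uniform null (the
asymptotically least favourable unimodal distribution): `n_null` seeded
uniform samples of the observed size, add-one estimator
$(1 + \#\{D_0 \ge D\}) / (n_\text{null} + 1)$. This is exact at any sample
size and reproducible, unlike interpolation in published quantile tables;
the add-one rule keeps p-values strictly positive. Calibration is itself
tested (p-values of uniform samples are uniform to Kolmogorov distance
< 0.1 over 400 replicates).

**Fixation index.** $F_{st} = \mathrm{Var}(x) / (\bar p (1 - \bar p))$ with
the population (divide-by-$n$) variance, consistent with reporting
population variances alongside it; no sample-size correction is applied and
none is claimed. All-zero or all-one inputs have no defined index and error
explicitly (reports record `NA` with a note). Weir–Cockerham-style weighting
would be an alternative reading; it is noted but not implemented.

**Multiple testing.** Per-treatment dip tests are *not* corrected by
default, mirroring the per-treatment 0.05 convention of the source analyses;
`--bonferroni` enables the correction for users who want it.

## The crypt-array model

The within-host model is an explicit parameterization of a *hypothesis* —
that each crypt admits only a limited number of founder cells, with a
declining founder budget (or continued local reseeding) along the
anterior-posterior axis — not a measured mechanism. Crypt $j$ receives

$$K_j = 1 + \mathrm{Poisson}\!\big(\max(0,\; \mu_j - 1)\big),
\qquad \mu_j = \text{anterior budget} \times \text{decay}^{\,j-1},$$

so every crypt holds at least one founder and $E[K_j] = \max(1, \mu_j)$
exactly; the plain clamped-Poisson alternative would inflate the mean and
would not make the single-founder limit (`anterior_budget = 1`) exactly
pure. With probability `reseed_prob` a crypt is instead seeded clonally from
its anterior neighbour's majority strain. `budget_decay = 1, reseed_prob =
0` switches the gradient off entirely (the null model). The two crypt rows
of the real organ are collapsed into one ordered array, because transect
quantification follows a single complete row. The data cannot distinguish
budget gradients from temporal seeding order; both knobs are exposed and
neither is privileged.

Rendering (`render_transect()`) maps crypt proportions to two intensity
channels (`scale * p + background + noise` per pixel and its green
complement), truncated at zero, in arbitrary units — no camera model,
tile-stitching artifacts, or 2-D geometry.

## Transect quantification

`analyze_transect()` composes three steps, each with the decisions recorded
in its output:

1. `normalize_channel()`: background subtraction with a clamp floor
   (default 1 intensity unit). The floor is applied to **both** channels;
   the empirical rule that motivated it was stated for the red channel,
   where subtraction occasionally went negative, but symmetric clamping is
   required to keep the log ratio defined in either direction and is
   recorded in the options.
2. `log_ratio()`: per-pixel $\log(\text{RFP}/\text{GFP})$, base 10 by
   default ("log-transformed" admits either reading; the base is an explicit
   option).
3. `sliding_variance()`: stride-1 sample variance (the $n-1$ denominator;
   the source analysis does not state one) in windows of 10% of the transect
   length (`max(2, round(0.10 n))` pixels), emitting only fully interior
   windows, so the output length is exactly $n - w + 1$. "Iteratively
   sampling pixels within a sliding interval" is read as a full-window
   sliding variance; a random-subsampling variant is out of scope.

Rising sliding-window variance along the axis is the quantitative signature
of crypt-scale patchiness: anterior crypts co-colonized (log ratio near 0,
low local variance), posterior crypts pure (log ratio saturated at either
sign, high local variance). In the noiseless case the pipeline inverts the
renderer exactly up to the clamp floor, which the tests assert.

## The synthetic-data generator

`experiment_spec()` + `generate_experiment()` emit complete experiments —
one colony-count CSV per density on the default ladder $10^1$–$10^6$ CFU/µL
with 30 hosts per treatment, a pooled table, optional rendered transects,
and a manifest with per-file md5 hashes — so the whole pipeline is testable
offline. The generator emulates the *structure* and the stochastic
mechanisms of the insect experiments (founder sampling, plating noise,
density ladder, per-treatment cohort sizes), not their biology: there is no
host mortality, no fluorophore toxicity (the observed slight green bias at
high density is representable only through the fitness-ratio parameter), no
inoculum-density measurement error, and real colony counts are not Poisson
with a common mean across hosts. Passing tests therefore demonstrate that
the statistics and pipeline behave correctly on data with the designed
generating process, not that the biological parameter values are correct.

## Numerical choices and test scale

* Decade bins are half-open $[10^k, 10^{k+1})$ on density; treatment labels
  name the lower edge. The pooled below-threshold group *duplicates* its
  members (flagged `pooled`), it does not remove them from decade groups.
* Dip bisection oracle tolerance $10^{-14}$; equality with the compiled
  algorithm asserted at $10^{-12}$.
* Sliding variance uses centered cumulative sums (numerically stable for
  log-ratio magnitudes) and floors tiny negative roundoff at zero.
* Monte-Carlo problem sizes in the shipped tests: 200 cohorts × 30 hosts
  per density on a six-point $\lambda$ grid spanning three orders of
  magnitude for the drift-monotonicity property; $10^5$ hosts per $\lambda$
  for the closed-form checks; 999 null draws per dip p-value. These sizes
  put Monte-Carlo error comfortably inside the asserted tolerances while
  keeping the full suite under a minute.

## Known limitations

* $\lambda$ is identifiable only as a composite; inference about ingestion
  volume or establishment probability separately is out of scope.
* The dip p-value's uniform null is conventional but conservative for some
  unimodal alternatives.
* The crypt model is a caricature for hypothesis exploration; its gradient
  parameters are not fitted to images.
* XLSX supplements are supported via external conversion to the documented
  CSV dialect, not parsed natively.
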