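#' Between-host heterogeneity statistics
#'
#' Statistics quantifying how strongly a set of per-host strain proportions
#' splits into distinct colonization outcomes: the sample bimodality
#' coefficient (with its leave-one-out jackknife), Hartigan's dip statistic
#' with a Monte-Carlo p-value, the population variance, and a two-strain
#' fixation index.
#'
#' @name heterogeneity_stats
#' @keywords internal
NULL

# central moments about the mean, divide-by-n
.moments <- function(x) {
  n <- length(x)
  d <- x - mean(x)
  list(n = n, m2 = sum(d^2) / n, m3 = sum(d^3) / n, m4 = sum(d^4) / n)
}

#' Sample bimodality coefficient
#'
#' `BC = (G1^2 + 1) / (G2 + 3 (n-1)^2 / ((n-2)(n-3)))` with `G1` the
#' bias-corrected sample skewness and `G2` the bias-corrected sample excess
#' kurtosis (the SAS convention). Values above the uniform-distribution limit
#' [bc_uniform_limit()] (about 0.556) conventionally indicate bimodality; the
#' coefficient approaches 1 for equal-mass two-point data.
#'
#' A constant input has undefined moments; it yields `NaN` carrying a
#' `"reason"` attribute rather than an error, so screens over many treatment
#' groups can proceed and flag the degenerate group.
#'
#' @param x numeric vector, `length(x) >= 4` (the kurtosis bias correction
#'   needs it).
#' @return the coefficient, or flagged `NaN` for constant input.
#' @export
bimodality_coefficient <- function(x) {
  n <- length(x)
  gd_check(n >= 4, "bimodality coefficient requires n >= 4 (got %d)", n,
           class = "gutdrift_underpowered")
  gd_check(all(is.finite(x)), "non-finite values", class = "gutdrift_bad_input")
  mo <- .moments(x)
  if (mo$m2 == 0) {
    return(structure(NaN, reason = "constant input: moments degenerate"))
  }
  g1 <- mo$m3 / mo$m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- mo$m4 / mo$m2^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  (G1^2 + 1) / (G2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Large-sample bimodality coefficient of the uniform distribution
#'
#' In the large-sample limit the bias corrections vanish and
#' `BC -> (g1^2 + 1) / (g2 + 3)` with population skewness `g1 = 0` and
#' population excess kurtosis `g2 = -6/5` for any uniform distribution,
#' giving `1 / 1.8`. This is the conventional reference threshold drawn
#' alongside empirical bimodality coefficients.
#'
#' @return `1/1.8` (about 0.5556), evaluated from the uniform moments.
#' @export
bc_uniform_limit <- function() {
  g1 <- 0
  g2 <- -6 / 5
  (g1^2 + 1) / (g2 + 3)
}

#' Leave-one-out jackknife of the bimodality coefficient
#'
#' @param x numeric vector, `length(x) >= 5` so every leave-one-out sample
#'   still satisfies the `n >= 4` requirement.
#' @return numeric vector of `length(x)` coefficients; entry `i` is the
#'   coefficient of `x[-i]`, in input order.
#' @export
jackknife_bc <- function(x) {
  n <- length(x)
  gd_check(n >= 5, "jackknife requires n >= 5 (got %d)", n,
           class = "gutdrift_underpowered")
  vapply(seq_len(n), function(i) as.numeric(bimodality_coefficient(x[-i])),
         numeric(1))
}

#' Hartigan's dip statistic
#'
#' The minimum over all unimodal distribution functions G of the supremum
#' distance between G and the empirical distribution function of `x`,
#' computed via greatest-convex-minorant / least-concave-majorant fits on the
#' sorted sample. Bounded below by `1/(2n)` and above by 0.25 (attained by
#' equal-mass two-point data).
#'
#' @param x numeric vector, `length(x) >= 2`, finite.
#' @return the dip statistic.
#' @seealso [dip_statistic_exhaustive()] for the independent small-sample
#'   oracle used to validate this implementation.
#' @export
dip_statistic <- function(x) {
  gd_check(length(x) >= 2, "dip statistic requires n >= 2",
           class = "gutdrift_underpowered")
  gd_check(all(is.finite(x)), "non-finite values", class = "gutdrift_bad_input")
  .dip_cpp(as.numeric(x))
}

#' Monte-Carlo p-value for Hartigan's dip test
#'
#' The null distribution is calibrated by simulation: `n_null` samples of
#' `length(x)` observations are drawn from Uniform(0, 1) (the asymptotically
#' least favourable unimodal null) and the add-one estimator
#' `(1 + #\{null dips >= observed\}) / (n_null + 1)` is returned, so the
#' p-value is never exactly zero and is exact for any sample size given
#' enough null draws.
#'
#' @param x numeric vector, `length(x) >= 4`.
#' @param n_null number of null samples, at least 999.
#' @param seed integer seed governing the null draws.
#' @return p-value in (0, 1\].
#' @export
dip_pvalue <- function(x, n_null = 999L, seed = 1L) {
  n <- length(x)
  gd_check(n >= 4, "dip p-value requires n >= 4", class = "gutdrift_underpowered")
  gd_check(n_null >= 999, "n_null must be >= 999", class = "gutdrift_bad_input")
  obs <- dip_statistic(x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nulls <- .dip_null_cpp(as.integer(n), as.integer(n_null))
  (1 + sum(nulls >= obs)) / (n_null + 1)
}

#' Two-strain fixation index across hosts
#'
#' Population (divide-by-n) variance of the per-host red-strain proportions
#' divided by `pbar * (1 - pbar)`, where `pbar` is their mean: 0 when all
#' hosts carry the same mixed community, 1 when every host is fixed for one
#' strain. Undefined when the mean proportion is 0 or 1 (no polymorphism).
#'
#' @param x proportions in \[0, 1\], `length(x) >= 2`.
#' @return fixation index in \[0, 1\].
#' @export
strain_fst <- function(x) {
  gd_check(length(x) >= 2, "fixation index requires n >= 2",
           class = "gutdrift_underpowered")
  gd_check(all(is.finite(x) & x >= 0 & x <= 1), "proportions must lie in [0,1]",
           class = "gutdrift_bad_input")
  p <- mean(x)
  gd_check(p > 0 && p < 1,
           "fixation index undefined: mean proportion is %g (all hosts pure for one strain)",
           p, class = "gutdrift_degenerate")
  mean((x - p)^2) / (p * (1 - p))
}

#' Population variance (divide-by-n)
#' @param x numeric vector.
#' @return `sum((x - mean(x))^2) / length(x)`.
#' @export
population_variance <- function(x) {
  mean((x - mean(x))^2)
}

#' Heterogeneity report for one treatment group
#'
#' Computes every between-host statistic on the red-strain proportions of the
#' *colonized* hosts of a treatment group: bimodality coefficient and its
#' jackknife, dip statistic and Monte-Carlo p-value, population variance, and
#' fixation index, plus the colonization success rate over all hosts.
#'
#' @param g a [treatment_group] with at least 5 colonized hosts.
#' @param n_null,seed passed to [dip_pvalue()].
#' @return object of class `heterogeneity_report`: list with `label`, `n`
#'   (colonized hosts used), `bc`, `bc_jackknife`, `dip`, `dip_pvalue`,
#'   `variance`, `fst` (`NA` when undefined, with `fst_note`), `success`,
#'   `n_null`, `seed`.
#' @export
heterogeneity_report <- function(g, n_null = 999L, seed = 1L) {
  gd_check(inherits(g, "treatment_group"), "expected a treatment_group",
           class = "gutdrift_bad_input")
  colz <- g$outcomes[g$outcomes$colonized, , drop = FALSE]
  gd_check(nrow(colz) >= 5,
           "group '%s' underpowered: %d colonized hosts (need >= 5)",
           g$label, nrow(colz), class = "gutdrift_underpowered")
  p <- red_fraction(colz)
  fst <- tryCatch(strain_fst(p), gutdrift_degenerate = function(e) NA_real_)
  structure(list(
    label = g$label,
    n = length(p),
    bc = bimodality_coefficient(p),
    bc_jackknife = jackknife_bc(p),
    dip = dip_statistic(p),
    dip_pvalue = dip_pvalue(p, n_null = n_null, seed = seed),
    variance = population_variance(p),
    fst = fst,
    fst_note = if (is.na(fst)) "undefined: all hosts pure for one strain" else NULL,
    success = success_rate(g),
    n_null = as.integer(n_null),
    seed = as.integer(seed)
  ), class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("<heterogeneity_report '%s': n=%d>\n", x$label, x$n))
  cat(sprintf("  bimodality coefficient: %.4f (jackknife mean %.4f)\n",
              x$bc, mean(x$bc_jackknife)))
  cat(sprintf("  dip: %.4f (Monte-Carlo p = %.4g, %d null draws)\n",
              x$dip, x$dip_pvalue, x$n_null))
  cat(sprintf("  population variance: %.4f   fixation index: %s\n",
              x$variance, if (is.na(x$fst)) "NA" else sprintf("%.4f", x$fst)))
  cat(sprintf("  colonization success: %s (%.2f)\n",
              x$success$ratio, x$success$fraction))
  invisible(x)
}

#' Tabulate heterogeneity reports
#'
#' One row per treatment: the column set mirrors the summary tables reported
#' for co-inoculation trials (bimodality coefficient, population variance,
#' fixation index, dip statistic, dip p-value, n, success rate).
#'
#' @param reports list of [heterogeneity_report] objects.
#' @return data.frame with one row per report.
#' @export
report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(label = r$label, n = r$n,
               bimodality_coefficient = as.numeric(r$bc),
               population_variance = r$variance,
               fst = r$fst, dip = r$dip, dip_pvalue = r$dip_pvalue,
               colonized = r$success$colonized, total = r$success$total,
               success_rate = r$success$fraction,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Serialize heterogeneity reports
#'
#' Writes the one-row-per-treatment CSV of [report_table()] and, optionally,
#' a JSON file retaining the full reports (including jackknife vectors and
#' the seeds used).
#'
#' @param reports list of [heterogeneity_report] objects.
#' @param csv_path,json_path output paths (`NULL` to skip one of them).
#' @return invisibly, the report table.
#' @export
write_reports <- function(reports, csv_path = NULL, json_path = NULL) {
  tab <- report_table(reports)
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(reports, unclass), json_path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(tab)
}
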