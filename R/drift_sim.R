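#' Simulation parameters for a co-inoculation trial
#'
#' Generative model of one host feeding on a two-strain inoculum. The
#' effective founder number is `lambda_eff = inoculum_density *
#' ingestion_volume * establishment_prob`: the expected count of inoculum
#' cells that both get ingested and establish in the symbiotic organ.
#' Density, volume and per-cell establishment probability only enter through
#' this product, so the pair (`ingestion_volume`, `establishment_prob`) is a
#' free composite calibration, not a measured quantity.
#'
#' @param inoculum_density CFU/uL, positive.
#' @param red_fraction_inoculum proportion of the red strain in the inoculum.
#' @param ingestion_volume uL ingested per host, positive.
#' @param establishment_prob per-cell establishment probability in (0, 1].
#' @param fitness_ratio within-host growth advantage of red over green
#'   (positive; 1 = neutral).
#' @param selection_rounds effective generations of within-host competition
#'   (>= 0); the red advantage compounds as `fitness_ratio^selection_rounds`.
#' @param mean_colonies_counted expected colonies scored per colonized host
#'   (positive).
#' @param polya_drift logical; if `TRUE`, within-host expansion adds
#'   founder-seeded Polya-urn resampling noise instead of being deterministic
#'   given the founders (sensitivity analysis of the no-post-founding-drift
#'   assumption).
#' @return validated list of class `sim_params` with derived `lambda_eff`.
#' @export
sim_params <- function(inoculum_density = 1e3,
                       red_fraction_inoculum = 0.5,
                       ingestion_volume = 1,
                       establishment_prob = 0.05,
                       fitness_ratio = 1,
                       selection_rounds = 0,
                       mean_colonies_counted = 50,
                       polya_drift = FALSE) {
  gd_check(is.numeric(inoculum_density) && inoculum_density > 0,
           "inoculum_density must be positive", class = "gutdrift_bad_params")
  gd_check(is_prob(red_fraction_inoculum), "red_fraction_inoculum must be in [0,1]",
           class = "gutdrift_bad_params")
  gd_check(is.numeric(ingestion_volume) && ingestion_volume > 0,
           "ingestion_volume must be positive", class = "gutdrift_bad_params")
  gd_check(is_prob(establishment_prob) && establishment_prob > 0,
           "establishment_prob must be in (0,1]", class = "gutdrift_bad_params")
  gd_check(is.numeric(fitness_ratio) && fitness_ratio > 0,
           "fitness_ratio must be positive", class = "gutdrift_bad_params")
  gd_check(is.numeric(selection_rounds) && selection_rounds >= 0,
           "selection_rounds must be >= 0", class = "gutdrift_bad_params")
  gd_check(is.numeric(mean_colonies_counted) && mean_colonies_counted > 0,
           "mean_colonies_counted must be positive", class = "gutdrift_bad_params")
  p <- list(inoculum_density = inoculum_density,
            red_fraction_inoculum = red_fraction_inoculum,
            ingestion_volume = ingestion_volume,
            establishment_prob = establishment_prob,
            fitness_ratio = fitness_ratio,
            selection_rounds = selection_rounds,
            mean_colonies_counted = mean_colonies_counted,
            polya_drift = isTRUE(polya_drift))
  p$lambda_eff <- inoculum_density * ingestion_volume * establishment_prob
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params: density %g CFU/uL, lambda_eff %g, red fraction %g, w^t %g>\n",
    x$inoculum_density, x$lambda_eff, x$red_fraction_inoculum,
    x$fitness_ratio^x$selection_rounds))
  invisible(x)
}

#' Read simulation parameters from a YAML config
#'
#' Top-level keys are [sim_params()] arguments; unknown keys are an error.
#'
#' @param path YAML file.
#' @return a `sim_params` object.
#' @export
read_sim_params <- function(path) {
  gd_check(file.exists(path), "file not found: %s", path,
           class = "gutdrift_io_error")
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(formals(sim_params)))
  gd_check(length(unknown) == 0, "unknown sim_params field(s): %s",
           paste(unknown, collapse = ", "), class = "gutdrift_bad_params")
  do.call(sim_params, cfg)
}

# within-host final red proportion given founders (k red of N)
.final_red_prop <- function(k, N, p) {
  wt <- p$fitness_ratio^p$selection_rounds
  q <- k * wt / (k * wt + (N - k))
  if (p$polya_drift && N > 0 && k > 0 && k < N) {
    # Polya-urn: the long-run share after urn reinforcement started from the
    # (selection-weighted) founders is Beta(k*wt, N-k) distributed
    q <- stats::rbeta(1, k * wt, N - k)
  }
  q
}

# one host draw: c(N_founders, red_founders, green_count, red_count)
.sim_host_core <- function(params) {
  N <- rpois(1, params$lambda_eff)
  if (N == 0L) return(c(0L, 0L, 0L, 0L))
  k <- rbinom(1, N, params$red_fraction_inoculum)
  q <- .final_red_prop(k, N, params)
  m <- 0L
  while (m < 1L) m <- rpois(1, params$mean_colonies_counted)
  red <- rbinom(1, m, q)
  c(N, k, m - red, red)
}

#' Simulate one host
#'
#' Founder sampling, within-host expansion, and plating for a single host:
#' `N ~ Poisson(lambda_eff)` founders (zero founders = uncolonized host);
#' `k ~ Binomial(N, red_fraction_inoculum)` of them red; final red proportion
#' `q = k w^t / (k w^t + (N - k))` with `w = fitness_ratio` and
#' `t = selection_rounds`; colonies scored `m ~ Poisson(mean_colonies_counted)`
#' redrawn until `m >= 1` (a dissected colonized organ always yields
#' colonies), of which `red_count ~ Binomial(m, q)`.
#'
#' @param params a [sim_params] object.
#' @param host_id,trial_id identifiers for the emitted row.
#' @return one-row [host_outcomes] table with attribute `founders`
#'   (`c(total, red)`).
#' @export
simulate_host <- function(params, host_id = "h1", trial_id = "sim") {
  gd_check(inherits(params, "sim_params"), "params must be sim_params",
           class = "gutdrift_bad_params")
  v <- .sim_host_core(params)
  out <- host_outcomes(data.frame(
    host_id = host_id, trial_id = trial_id,
    inoculum_density = params$inoculum_density,
    green_count = v[3], red_count = v[4]))
  attr(out, "founders") <- c(total = v[1], red = v[2])
  out
}

#' Simulate a cohort of hosts
#'
#' Independent [simulate_host()] draws. Each host consumes its own RNG
#' sub-stream, seeded from `seed`, so results do not depend on evaluation
#' order and are fully reproducible.
#'
#' @param params a [sim_params] object.
#' @param n_hosts number of hosts, >= 1.
#' @param seed integer seed for the cohort.
#' @param trial_id identifier stamped on every row.
#' @return object of class `cohort_result`: list with `params`, `outcomes`
#'   (a [host_outcomes] table) and `founders` (data.frame of per-host total
#'   and red founder counts).
#' @export
simulate_cohort <- function(params, n_hosts, seed = 1L, trial_id = "sim") {
  gd_check(inherits(params, "sim_params"), "params must be sim_params",
           class = "gutdrift_bad_params")
  gd_check(is_count(n_hosts) && n_hosts >= 1, "n_hosts must be >= 1",
           class = "gutdrift_bad_params")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  host_seeds <- sample.int(.Machine$integer.max, n_hosts)
  draws <- matrix(0L, n_hosts, 4)
  for (i in seq_len(n_hosts)) {
    set.seed(host_seeds[i])
    draws[i, ] <- .sim_host_core(params)
  }
  outcomes <- host_outcomes(data.frame(
    host_id = sprintf("h%05d", seq_len(n_hosts)),
    trial_id = trial_id,
    inoculum_density = params$inoculum_density,
    green_count = draws[, 3], red_count = draws[, 4]))
  founders <- draws
  structure(list(params = params,
                 outcomes = outcomes,
                 founders = data.frame(total = founders[, 1], red = founders[, 2]),
                 seed = as.integer(seed)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result: %d hosts, %d colonized, lambda_eff %g, seed %d>\n",
              nrow(x$outcomes), sum(x$outcomes$colonized),
              x$params$lambda_eff, x$seed))
  invisible(x)
}

#' Closed-form colonization probability
#'
#' Probability that a host acquires at least one founder:
#' `1 - exp(-lambda_eff)`.
#'
#' @param params a [sim_params] object.
#' @return probability in \[0, 1).
#' @export
colonization_probability <- function(params) {
  gd_check(inherits(params, "sim_params"), "params must be sim_params",
           class = "gutdrift_bad_params")
  1 - exp(-params$lambda_eff)
}

#' Expected fraction of monoclonal (pure) infections under neutrality
#'
#' Probability that a *colonized* host's founder population is all-red or
#' all-green when founders are `Poisson(lambda)` thinned binomially with red
#' fraction `p`:
#' `(exp(-lambda (1 - p)) + exp(-lambda p) - 2 exp(-lambda)) / (1 - exp(-lambda))`.
#' The closed form follows from summing the Poisson series of `p^N` and
#' `(1-p)^N`; the test suite re-validates it against direct numerical
#' summation.
#'
#' @param lambda_eff expected founder count, positive.
#' @param p_red red fraction of the inoculum. The boundary values 0 and 1
#'   trivially give 1 (single-strain inoculum) and are returned with a
#'   `boundary` attribute.
#' @return probability in (0, 1\].
#' @export
expected_pure_fraction <- function(lambda_eff, p_red) {
  gd_check(is.numeric(lambda_eff) && lambda_eff > 0, "lambda_eff must be positive",
           class = "gutdrift_bad_params")
  gd_check(is_prob(p_red), "p_red must be in [0,1]", class = "gutdrift_bad_params")
  if (p_red == 0 || p_red == 1) {
    return(structure(1, boundary = TRUE))
  }
  l <- lambda_eff
  (exp(-l * (1 - p_red)) + exp(-l * p_red) - 2 * exp(-l)) / (1 - exp(-l))
}

#' Bimodality coefficient across a ladder of inoculum densities
#'
#' For each density, simulates `n_reps` cohorts of `n_hosts` hosts and
#' summarizes the bimodality coefficient of the colonized hosts' red
#' fractions and the colonization success rate. Cohorts with fewer than 4
#' colonized hosts, or with degenerate (constant) proportions, contribute no
#' coefficient and are counted in `n_bc_dropped`.
#'
#' @param base a [sim_params] object supplying everything but the density.
#' @param densities at least 2 inoculum densities (CFU/uL).
#' @param n_hosts hosts per cohort.
#' @param n_reps cohorts per density, >= 20.
#' @param seed integer seed.
#' @return data.frame sorted by density: `density`, `lambda_eff`, `mean_bc`,
#'   `sd_bc`, `mean_success`, `mean_red_fraction`, `n_bc_used`, `n_bc_dropped`.
#' @export
bc_vs_bottleneck_curve <- function(base, densities, n_hosts = 30, n_reps = 20,
                                   seed = 1L) {
  gd_check(inherits(base, "sim_params"), "base must be sim_params",
           class = "gutdrift_bad_params")
  gd_check(length(densities) >= 2 || n_reps >= 1, "need at least one density",
           class = "gutdrift_bad_params")
  gd_check(n_reps >= 20 || length(densities) == 1, "n_reps must be >= 20",
           class = "gutdrift_bad_params")
  densities <- sort(densities)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cohort_seeds <- matrix(sample.int(.Machine$integer.max, length(densities) * n_reps),
                         nrow = length(densities))
  rows <- lapply(seq_along(densities), function(di) {
    args <- unclass(base)
    args$lambda_eff <- NULL
    args$inoculum_density <- densities[di]
    p <- do.call(sim_params, args)
    bcs <- numeric(0)
    succ <- numeric(n_reps)
    redbar <- numeric(0)
    for (r in seq_len(n_reps)) {
      co <- simulate_cohort(p, n_hosts, seed = cohort_seeds[di, r])
      colz <- co$outcomes[co$outcomes$colonized, , drop = FALSE]
      succ[r] <- nrow(colz) / n_hosts
      if (nrow(colz) >= 4) {
        rf <- red_fraction(colz)
        redbar <- c(redbar, mean(rf))
        bc <- bimodality_coefficient(rf)
        if (is.finite(bc)) bcs <- c(bcs, as.numeric(bc))
      }
    }
    data.frame(density = densities[di], lambda_eff = p$lambda_eff,
               mean_bc = if (length(bcs)) mean(bcs) else NA_real_,
               sd_bc = if (length(bcs) > 1) sd(bcs) else NA_real_,
               mean_success = mean(succ),
               mean_red_fraction = if (length(redbar)) mean(redbar) else NA_real_,
               n_bc_used = length(bcs), n_bc_dropped = n_reps - length(bcs))
  })
  do.call(rbind, rows)
}
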