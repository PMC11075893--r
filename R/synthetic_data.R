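#' Specification of a complete synthetic co-inoculation experiment
#'
#' Bundles everything needed to emit a reproducible synthetic experiment:
#' a scenario (`"neutral_isogenic"`: two marker-swapped isogenic strains,
#' fitness ratio forced to 1; `"interspecific"`: two species with a
#' within-host competitive asymmetry), a ladder of inoculum densities, the
#' number of hosts per treatment, and parameter overrides for the host-level
#' and crypt-level simulators. The default ladder spans `10^1` to `10^6`
#' CFU/uL in decade steps, the density range used in the co-inoculation
#' trials this package models.
#'
#' @param scenario `"neutral_isogenic"` or `"interspecific"`.
#' @param density_ladder strictly positive densities (CFU/uL).
#' @param hosts_per_treatment hosts per density.
#' @param sim named list of [sim_params()] overrides. `fitness_ratio` and
#'   `selection_rounds` may not be overridden in the neutral scenario.
#' @param crypt named list of [crypt_params()] overrides.
#' @param n_transects number of co-colonized hosts for which synthetic
#'   crypt-array transects are also emitted.
#' @param seed integer master seed.
#' @return validated list of class `experiment_spec`.
#' @export
experiment_spec <- function(scenario = c("neutral_isogenic", "interspecific"),
                            density_ladder = 10^(1:6),
                            hosts_per_treatment = 30,
                            sim = list(), crypt = list(),
                            n_transects = 0, seed = 1L) {
  scenario <- match.arg(scenario)
  gd_check(all(density_ladder > 0), "density ladder must be strictly positive",
           class = "gutdrift_bad_params")
  gd_check(is_count(hosts_per_treatment) && hosts_per_treatment >= 1,
           "hosts_per_treatment must be a positive integer",
           class = "gutdrift_bad_params")
  if (scenario == "neutral_isogenic") {
    gd_check(is.null(sim$fitness_ratio) || sim$fitness_ratio == 1,
             "neutral_isogenic scenario forces fitness_ratio = 1",
             class = "gutdrift_bad_params")
    sim$fitness_ratio <- 1
    sim$selection_rounds <- 0
  } else if (is.null(sim$fitness_ratio)) {
    # default competitive asymmetry: modest per-round advantage compounded
    # over within-host growth, so mixed founder sets resolve in favour of red
    sim$fitness_ratio <- 2
    if (is.null(sim$selection_rounds)) sim$selection_rounds <- 10
  }
  structure(list(scenario = scenario,
                 density_ladder = sort(density_ladder),
                 hosts_per_treatment = as.integer(hosts_per_treatment),
                 sim = sim, crypt = crypt,
                 n_transects = as.integer(n_transects),
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

.sim_params_for_density <- function(spec, density) {
  args <- spec$sim
  args$inoculum_density <- density
  do.call(sim_params, args)
}

#' Generate and write a complete synthetic experiment
#'
#' Emits one trial CSV per treatment density
#' (`treatments/<label>.csv`), a pooled CSV of all hosts
#' (`treatments/pooled_all.csv`), optional crypt transects
#' (`transects/<host_id>.csv`), and a `manifest.json` recording the spec,
#' seeds, and an md5 hash per file so regeneration is verifiable. The same
#' spec and seed always produce byte-identical files.
#'
#' @param spec an [experiment_spec].
#' @param out_dir output directory (created if needed; must be writable).
#' @return the manifest, invisibly.
#' @export
generate_experiment <- function(spec, out_dir) {
  gd_check(inherits(spec, "experiment_spec"), "expected an experiment_spec",
           class = "gutdrift_bad_params")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gd_check(ok && file.access(out_dir, 2) == 0, "cannot write to %s", out_dir,
           class = "gutdrift_io_error")
  dir.create(file.path(out_dir, "treatments"), showWarnings = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  cohort_seeds <- sample.int(.Machine$integer.max, length(spec$density_ladder))
  transect_seeds <- sample.int(.Machine$integer.max, max(1L, spec$n_transects))

  files <- list()
  all_rows <- list()
  for (i in seq_along(spec$density_ladder)) {
    d <- spec$density_ladder[i]
    label <- sprintf("1e%d", .decade(d))
    p <- .sim_params_for_density(spec, d)
    co <- simulate_cohort(p, spec$hosts_per_treatment, seed = cohort_seeds[i],
                          trial_id = label)
    path <- file.path(out_dir, "treatments", paste0(label, ".csv"))
    write_trials(co$outcomes, path)
    files[[length(files) + 1L]] <- list(path = file.path("treatments", paste0(label, ".csv")),
                                        rows = nrow(co$outcomes), seed = cohort_seeds[i])
    all_rows[[i]] <- as.data.frame(co$outcomes)
  }
  pooled <- host_outcomes(do.call(rbind, all_rows))
  pooled_path <- file.path(out_dir, "treatments", "pooled_all.csv")
  write_trials(pooled, pooled_path)
  files[[length(files) + 1L]] <- list(path = "treatments/pooled_all.csv",
                                      rows = nrow(pooled), seed = NA)

  if (spec$n_transects > 0) {
    dir.create(file.path(out_dir, "transects"), showWarnings = FALSE)
    cp <- do.call(crypt_params, spec$crypt)
    for (t in seq_len(spec$n_transects)) {
      ca <- simulate_crypts(cp, seed = transect_seeds[t])
      tr <- render_transect(ca, seed = transect_seeds[t])
      rel <- file.path("transects", sprintf("host%03d.csv", t))
      write_transect_profile(tr, file.path(out_dir, rel))
      files[[length(files) + 1L]] <- list(path = rel, rows = nrow(tr),
                                          seed = transect_seeds[t])
    }
  }

  for (i in seq_along(files)) {
    files[[i]]$md5 <- unname(tools::md5sum(file.path(out_dir, files[[i]]$path)))
  }
  manifest <- list(
    package = "gutdrift",
    version = as.character(packageVersion("gutdrift")),
    spec = unclass(spec),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Hand-checkable worked-example fixtures
#'
#' Small input/expected pairs whose expectations were computed by independent
#' means (exhaustive dip minimization, direct variance and proportion
#' arithmetic); used in documentation and asserted in the test suite. A copy
#' is committed under `inst/extdata/worked_examples.json`.
#'
#' @return named list of fixtures, each with `input`, `expected`, and `note`.
#' @export
worked_example_fixtures <- function() {
  list(
    dip4 = list(input = c(0, 0, 1, 1), expected = 0.25,
                note = "dip of equal-mass two-point data attains the 0.25 upper bound"),
    dip_spread = list(input = c(1, 2, 3, 4, 5), expected = 0.1,
                      note = "equally spaced sample: dip at its 1/(2n) lower bound"),
    fst_extreme = list(input = c(0, 1), expected = 1,
                       note = "one pure host of each strain: complete differentiation"),
    fst_mixed = list(input = c(0.2, 0.8, 0.5, 0.5), expected = 0.18,
                     note = "population variance 0.045 over pbar(1-pbar) = 0.25"),
    slide4 = list(input = c(0, 0, 3, 3), expected = c(0, 4.5, 0),
                  note = "window-2 sliding sample variance",
                  window_frac = 0.5),
    red_fraction = list(input = c(green = 120, red = 40), expected = 0.25,
                        note = "40 red of 160 total colonies")
  )
}
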