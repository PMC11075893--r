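#' Parameters of the ordered crypt-array colonization model
#'
#' A model of the *limited founders per crypt* hypothesis for within-organ
#' spatial structure: the symbiotic organ is an ordered anterior-to-posterior
#' array of crypts, each seeded by a small founder budget drawn from a
#' common propagule pool. An anterior-posterior budget gradient
#' (`budget_decay < 1`) gives anterior crypts many founders (mixed
#' communities) and posterior crypts few (pure communities); optional clonal
#' reseeding from the previous crypt models continued local inoculation.
#' This is an explicit parameterization of a hypothesis, not a measured
#' mechanism; `budget_decay = 1`, `reseed_prob = 0` is the gradient-free
#' null model.
#'
#' @param n_crypts number of crypts (order: hundreds).
#' @param pool_red_fraction red-strain proportion of the propagule pool.
#' @param anterior_budget expected founders in the anterior-most crypt, >= 1.
#' @param budget_decay per-crypt geometric decay of the expected budget,
#'   in (0, 1].
#' @param reseed_prob probability a crypt is seeded clonally from the
#'   previous crypt's majority strain instead of from the pool.
#' @return validated list of class `crypt_params`.
#' @export
crypt_params <- function(n_crypts = 200,
                         pool_red_fraction = 0.5,
                         anterior_budget = 10,
                         budget_decay = 0.98,
                         reseed_prob = 0.1) {
  gd_check(is_count(n_crypts) && n_crypts >= 1, "n_crypts must be a positive integer",
           class = "gutdrift_bad_params")
  gd_check(is_prob(pool_red_fraction), "pool_red_fraction must be in [0,1]",
           class = "gutdrift_bad_params")
  gd_check(is.numeric(anterior_budget) && anterior_budget >= 1,
           "anterior_budget must be >= 1", class = "gutdrift_bad_params")
  gd_check(is.numeric(budget_decay) && budget_decay > 0 && budget_decay <= 1,
           "budget_decay must be in (0,1]", class = "gutdrift_bad_params")
  gd_check(is_prob(reseed_prob), "reseed_prob must be in [0,1]",
           class = "gutdrift_bad_params")
  structure(list(n_crypts = as.integer(n_crypts),
                 pool_red_fraction = pool_red_fraction,
                 anterior_budget = anterior_budget,
                 budget_decay = budget_decay,
                 reseed_prob = reseed_prob),
            class = "crypt_params")
}

#' Simulate an ordered crypt array
#'
#' Crypt `j` (anterior = 1) receives a founder budget
#' `K_j = 1 + Poisson(max(0, mu_j - 1))` with
#' `mu_j = anterior_budget * budget_decay^(j-1)`, so every crypt holds at
#' least one founder and `E[K_j] = max(1, mu_j)` exactly. With probability
#' `reseed_prob` the founders are drawn clonally from the previous crypt's
#' majority strain (ties broken at random); otherwise the red founder count
#' is `Binomial(K_j, pool_red_fraction)`.
#'
#' @param params a [crypt_params] object.
#' @param seed integer seed.
#' @return object of class `crypt_array`: list with `founder_counts`,
#'   `red_proportions` (both length `n_crypts`, anterior to posterior) and
#'   `params`.
#' @export
simulate_crypts <- function(params, seed = 1L) {
  gd_check(inherits(params, "crypt_params"), "params must be crypt_params",
           class = "gutdrift_bad_params")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- params$n_crypts
  mu <- params$anterior_budget * params$budget_decay^(seq_len(n) - 1)
  K <- 1L + rpois(n, pmax(0, mu - 1))
  prop <- numeric(n)
  for (j in seq_len(n)) {
    if (j > 1 && runif(1) < params$reseed_prob) {
      prev <- prop[j - 1]
      maj <- if (prev == 0.5) runif(1) < 0.5 else prev > 0.5
      prop[j] <- as.numeric(maj)
    } else {
      prop[j] <- rbinom(1, K[j], params$pool_red_fraction) / K[j]
    }
  }
  structure(list(founder_counts = K, red_proportions = prop, params = params),
            class = "crypt_array")
}

#' @export
print.crypt_array <- function(x, ...) {
  cat(sprintf("<crypt_array: %d crypts, %.0f%% pure, mean red proportion %.3f>\n",
              length(x$red_proportions),
              100 * mean(x$red_proportions %in% c(0, 1)),
              mean(x$red_proportions)))
  invisible(x)
}

#' Render a crypt array into a two-channel fluorescence transect
#'
#' Each crypt spans `pixels_per_crypt` pixels. Per pixel,
#' `gfp_raw = intensity_scale * (1 - p) + background_level + noise` and
#' `rfp_raw = intensity_scale * p + background_level + noise` with crypt red
#' proportion `p` and Gaussian noise of sd `noise_sd`, truncated at 0.
#' Background channels are emitted as `background_level + noise`. Intensities
#' are arbitrary units; no camera model is simulated.
#'
#' @param crypts a [crypt_array].
#' @param intensity_scale signal units per unit proportion, positive.
#' @param background_level constant background, >= 0.
#' @param noise_sd Gaussian noise sd, >= 0.
#' @param pixels_per_crypt pixels rendered per crypt, positive integer.
#' @param seed integer seed for the noise.
#' @return a [transect_profile]: positions in pixels, anterior to posterior.
#' @export
render_transect <- function(crypts, intensity_scale = 1000,
                            background_level = 100, noise_sd = 20,
                            pixels_per_crypt = 10, seed = 1L) {
  gd_check(inherits(crypts, "crypt_array"), "crypts must be a crypt_array",
           class = "gutdrift_bad_params")
  gd_check(intensity_scale > 0, "intensity_scale must be positive",
           class = "gutdrift_bad_params")
  gd_check(is_count(pixels_per_crypt) && pixels_per_crypt >= 1,
           "pixels_per_crypt must be a positive integer",
           class = "gutdrift_bad_params")
  gd_check(background_level >= 0 && noise_sd >= 0,
           "background_level and noise_sd must be >= 0",
           class = "gutdrift_bad_params")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- rep(crypts$red_proportions, each = pixels_per_crypt)
  npx <- length(p)
  noise <- function() stats::rnorm(npx, 0, noise_sd)
  transect_profile(data.frame(
    position = seq_len(npx),
    gfp_raw = pmax(0, intensity_scale * (1 - p) + background_level + noise()),
    rfp_raw = pmax(0, intensity_scale * p + background_level + noise()),
    gfp_background = pmax(0, background_level + noise()),
    rfp_background = pmax(0, background_level + noise())
  ))
}
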