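noiseless_profile <- function(props = c(rep(0.5, 10), rep(1, 10), rep(0, 10)),
                              scale = 1000, bg = 100) {
  transect_profile(data.frame(
    position = seq_along(props),
    gfp_raw = scale * (1 - props) + bg,
    rfp_raw = scale * props + bg,
    gfp_background = rep(bg, length(props)),
    rfp_background = rep(bg, length(props))))
}

test_that("normalization subtracts background and clamps at the floor", {
  expect_equal(normalize_channel(500, 100), 400)
  expect_equal(normalize_channel(90, 100), 1)
  expect_equal(normalize_channel(rep(7, 5), rep(7, 5)), rep(1, 5))
  expect_error(normalize_channel(1:3, 1:2), "lengths differ",
               class = "gutdrift_bad_input")
  # clamping only acts below background + floor
  set.seed(40)
  raw <- runif(100, 0, 500); bg <- runif(100, 0, 200)
  out <- normalize_channel(raw, bg)
  above <- raw > bg + 1
  expect_equal(out[above], (raw - bg)[above])
  expect_true(all(out >= 1))
})

test_that("log ratio is zero at balance, antisymmetric under channel swap", {
  v <- c(1, 10, 100)
  expect_equal(log_ratio(v, v), rep(0, 3))
  expect_equal(log_ratio(10 * v, v), rep(1, 3))
  expect_equal(log_ratio(v, 10 * v), -rep(1, 3))
  set.seed(41)
  a <- runif(50, 1, 100); b <- runif(50, 1, 100)
  expect_equal(log_ratio(a, b), -log_ratio(b, a))
  expect_equal(log_ratio(a, b, base = exp(1)), log(a / b))
  expect_error(log_ratio(c(1, 0), c(1, 1)), "positive",
               class = "gutdrift_bad_input")
})

test_that("sliding variance matches hand-computed windows and bookkeeping", {
  sv <- sliding_variance(c(0, 0, 3, 3), window_frac = 0.5)
  expect_equal(sv$window_length, 2L)
  expect_equal(sv$variance, c(0, 4.5, 0))
  expect_equal(sliding_variance(rep(2, 30))$variance, rep(0, 28))
  # degenerate window covering everything equals the global variance
  set.seed(42)
  x <- rnorm(40)
  expect_equal(sliding_variance(x, window_frac = 1)$variance, var(x))
  # output length is n - w + 1 and matches direct var() per window
  sv2 <- sliding_variance(x, window_frac = 0.25)
  w <- sv2$window_length
  expect_equal(w, 10L)
  expect_length(sv2$variance, 40 - w + 1)
  direct <- vapply(seq_len(40 - w + 1), function(i) var(x[i:(i + w - 1)]),
                   numeric(1))
  expect_equal(sv2$variance, direct, tolerance = 1e-10)
  expect_error(sliding_variance(1, window_frac = 1), "shorter",
               class = "gutdrift_bad_input")
})

test_that("analyze_transect composes the stages and records its options", {
  prof <- noiseless_profile()
  res <- analyze_transect(prof)
  n <- nrow(prof)
  w <- max(2, round(0.1 * n))
  expect_equal(res$window_length, w)
  expect_length(res$log_ratio, n)
  expect_length(res$sliding_variance, n - w + 1)
  expect_length(res$window_positions, n - w + 1)
  expect_equal(res$options$log_base, 10)
  # exact expected log ratios: mixed 0; pure crypts have the empty channel
  # clamped at the floor, so |log ratio| = log10(1000 / 1) = 3
  expect_equal(res$log_ratio, c(rep(0, 10), rep(3, 10), rep(-3, 10)))
})

test_that("channel swap negates the log ratio and preserves the variance", {
  set.seed(43)
  p <- crypt_params(n_crypts = 25)
  tr <- render_transect(simulate_crypts(p, seed = 8), seed = 9)
  swapped <- transect_profile(data.frame(
    position = tr$position,
    gfp_raw = tr$rfp_raw, rfp_raw = tr$gfp_raw,
    gfp_background = tr$rfp_background, rfp_background = tr$gfp_background))
  a <- analyze_transect(tr)
  b <- analyze_transect(swapped)
  expect_equal(a$log_ratio, -b$log_ratio)
  expect_equal(a$sliding_variance, b$sliding_variance, tolerance = 1e-9)
})

test_that("the variance series is invariant to a constant log-ratio shift", {
  set.seed(44)
  x <- rnorm(60)
  expect_equal(sliding_variance(x + 5)$variance, sliding_variance(x)$variance,
               tolerance = 1e-9)
})

test_that("profiles round-trip through CSV and reject malformed input", {
  prof <- noiseless_profile()
  path <- tempfile(fileext = ".csv")
  write_transect_profile(prof, path)
  back <- read_transect_profile(path)
  expect_equal(as.data.frame(back), as.data.frame(prof))
  expect_error(transect_profile(data.frame(position = 1:25, gfp_raw = 1,
                                           rfp_raw = 1, gfp_background = 1)),
               "missing columns", class = "gutdrift_bad_input")
  expect_error(noiseless_profile(props = rep(0.5, 10)), ">= 20",
               class = "gutdrift_bad_input")
})

test_that("gradient crypt arrays produce a rising variance profile end to end", {
  p <- crypt_params(n_crypts = 120, anterior_budget = 20, budget_decay = 0.96,
                    reseed_prob = 0)
  ca <- simulate_crypts(p, seed = 10)
  tr <- render_transect(ca, noise_sd = 0, background_level = 0,
                        pixels_per_crypt = 4, seed = 11)
  res <- analyze_transect(tr)
  rho <- cor(res$window_positions, res$sliding_variance, method = "spearman")
  expect_gt(rho, 0.3)
  # noiseless analysis recovers per-crypt log ratios exactly (up to the clamp)
  expected <- log10(pmax(1000 * ca$red_proportions, 1) /
                    pmax(1000 * (1 - ca$red_proportions), 1))
  expect_equal(res$log_ratio, rep(expected, each = 4), tolerance = 1e-12)
})

test_that("results serialize with their options sidecar", {
  res <- analyze_transect(noiseless_profile())
  path <- tempfile(fileext = ".csv")
  write_transect_result(res, path)
  back <- read.csv(path)
  expect_equal(nrow(back), length(res$sliding_variance))
  expect_equal(back$sliding_variance, res$sliding_variance)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$window_frac, 0.1)
  expect_equal(side$window_length, res$window_length)
})
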