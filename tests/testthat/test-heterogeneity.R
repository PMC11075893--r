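# independent scratch route for the bimodality coefficient, built on the
# bias-corrected skewness/kurtosis estimators of e1071
bc_scratch <- function(x) {
  n <- length(x)
  s <- e1071::skewness(x, type = 2)
  k <- e1071::kurtosis(x, type = 2)
  (s^2 + 1) / (k + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

test_that("bimodality coefficient matches an independent moment computation", {
  set.seed(10)
  x10 <- round(runif(10), 3)
  expect_equal(bimodality_coefficient(x10), bc_scratch(x10), tolerance = 1e-12)
  for (r in 1:20) {
    x <- rbeta(sample(5:60, 1), 0.4, 0.6)
    expect_equal(bimodality_coefficient(x), bc_scratch(x), tolerance = 1e-10)
  }
})

test_that("bimodality coefficient approaches its two-point and uniform limits", {
  set.seed(11)
  # equal-mass two-point data: BC -> 1
  two <- rep(c(0, 1), each = 5e4)
  expect_equal(as.numeric(bimodality_coefficient(two)), 1, tolerance = 1e-3)
  # uniform data: BC -> 5/9; averaged over replicates per the sampling error
  bcs <- vapply(1:20, function(i) as.numeric(bimodality_coefficient(runif(1e5))),
                numeric(1))
  expect_lt(abs(mean(bcs) - 0.5556), 0.01)
  expect_equal(bc_uniform_limit(), 1 / 1.8)
})

test_that("degenerate and underpowered inputs are flagged, not silently computed", {
  expect_error(bimodality_coefficient(c(0.1, 0.2, 0.3)), "n >= 4",
               class = "gutdrift_underpowered")
  bc <- bimodality_coefficient(rep(0.5, 10))
  expect_true(is.nan(bc))
  expect_match(attr(bc, "reason"), "constant")
})

test_that("jackknife returns one leave-one-out coefficient per observation", {
  set.seed(12)
  x <- round(runif(8), 3)
  jk <- jackknife_bc(x)
  expect_length(jk, 8)
  direct <- vapply(1:8, function(i) as.numeric(bimodality_coefficient(x[-i])),
                   numeric(1))
  expect_equal(jk, direct, tolerance = 1e-12)
  # duplicated values give identical leave-one-out coefficients
  xd <- c(0.3, 0.3, runif(4))
  jkd <- jackknife_bc(xd)
  expect_equal(jkd[1], jkd[2])
  expect_error(jackknife_bc(runif(4)), "n >= 5", class = "gutdrift_underpowered")
  expect_length(jackknife_bc(runif(5)), 5)
})

test_that("jackknife mean tracks the full-sample coefficient on smooth input", {
  set.seed(13)
  x <- runif(200)
  expect_lt(abs(mean(jackknife_bc(x)) - as.numeric(bimodality_coefficient(x))),
            0.005)
})

test_that("fixation index covers its closed-form anchor cases", {
  expect_equal(strain_fst(c(0, 1)), 1)
  expect_equal(strain_fst(rep(0.5, 6)), 0)
  # pbar = 0.5, population variance = (0.09 + 0.09 + 0 + 0) / 4 = 0.045
  expect_equal(strain_fst(c(0.2, 0.8, 0.5, 0.5)), 0.045 / 0.25)
  expect_error(strain_fst(c(0, 0, 0)), "undefined", class = "gutdrift_degenerate")
  expect_error(strain_fst(c(1, 1)), "undefined", class = "gutdrift_degenerate")
  set.seed(14)
  for (r in 1:25) {
    x <- rbeta(sample(2:30, 1), 0.5, 0.5)
    f <- strain_fst(x)
    expect_gte(f, 0)
    expect_lte(f, 1)
    expect_equal(f, population_variance(x) / (mean(x) * (1 - mean(x))))
  }
})

test_that("every statistic is invariant to input order", {
  set.seed(15)
  x <- rbeta(24, 0.3, 0.3)
  xp <- sample(x)
  expect_equal(as.numeric(bimodality_coefficient(x)),
               as.numeric(bimodality_coefficient(xp)))
  expect_equal(dip_statistic(x), dip_statistic(xp))
  expect_equal(strain_fst(x), strain_fst(xp))
  expect_equal(population_variance(x), population_variance(xp))
  expect_equal(sort(jackknife_bc(x)), sort(jackknife_bc(xp)))
})

test_that("dip Monte-Carlo p-value is reproducible, bounded away from zero, and powerful", {
  set.seed(16)
  x <- c(rbeta(25, 20, 1), rbeta(25, 1, 20))  # strongly two-point
  p1 <- dip_pvalue(x, n_null = 999, seed = 5)
  p2 <- dip_pvalue(x, n_null = 999, seed = 5)
  expect_identical(p1, p2)
  expect_lte(p1, 0.01)
  expect_gte(p1, 1 / 1000)  # add-one rule: never exactly zero
  expect_error(dip_pvalue(x, n_null = 500), "999", class = "gutdrift_bad_input")
})

test_that("dip p-values are calibrated under their own uniform null", {
  set.seed(17)
  pvals <- vapply(1:400, function(i) dip_pvalue(runif(20), n_null = 999, seed = i),
                  numeric(1))
  ks <- max(abs(sort(pvals) - seq_along(pvals) / length(pvals)))
  expect_lt(ks, 0.1)
})

test_that("heterogeneity report equals direct recomputation of each statistic", {
  p <- sim_params(inoculum_density = 40)  # lambda_eff = 2
  co <- simulate_cohort(p, 60, seed = 21)
  g <- treatment_group("1e1", co$outcomes, c(10, 100))
  rep1 <- heterogeneity_report(g, n_null = 999, seed = 3)
  fr <- red_fraction(g$outcomes[g$outcomes$colonized, ])
  expect_equal(rep1$n, length(fr))
  expect_equal(rep1$bc, bimodality_coefficient(fr))
  expect_equal(rep1$bc_jackknife, jackknife_bc(fr))
  expect_equal(rep1$dip, dip_statistic(fr))
  expect_equal(rep1$dip_pvalue, dip_pvalue(fr, n_null = 999, seed = 3))
  expect_equal(rep1$variance, population_variance(fr))
  expect_equal(rep1$fst, strain_fst(fr))
  expect_equal(length(rep1$bc_jackknife), rep1$n)
  # dip bounds recorded in the report
  expect_gte(rep1$dip, 1 / (2 * rep1$n))
  expect_lte(rep1$dip, 0.25)
})

test_that("extreme groups produce the expected report signature", {
  g_bi <- group_from_fractions(rep(c(0, 1), each = 30))
  r_bi <- heterogeneity_report(g_bi, seed = 2)
  expect_gt(as.numeric(r_bi$bc), 0.9)
  expect_lte(r_bi$dip_pvalue, 0.05)
  expect_gt(r_bi$fst, 0.9)

  g_mid <- group_from_fractions(rep(0.5, 12))
  r_mid <- heterogeneity_report(g_mid, seed = 2)
  expect_equal(r_mid$fst, 0)
  expect_true(is.nan(r_mid$bc))

  g_small <- group_from_fractions(c(0, 1, 0.5))
  expect_error(heterogeneity_report(g_small), "underpowered",
               class = "gutdrift_underpowered")
})

test_that("reports serialize to the summary-table CSV and JSON", {
  g <- group_from_fractions(c(0, 0, 1, 1, 0.5, 0.4, 0.9, 0.1))
  r <- heterogeneity_report(g, seed = 4)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  tab <- write_reports(list(r), csv_path = csv, json_path = js)
  expect_true(file.exists(csv) && file.exists(js))
  back <- read.csv(csv)
  expect_equal(back$bimodality_coefficient, as.numeric(r$bc))
  expect_equal(back$dip, r$dip)
  expect_equal(back$fst, r$fst)
  expect_equal(back$n, r$n)
  parsed <- jsonlite::read_json(js, simplifyVector = FALSE)
  expect_equal(parsed[[1]]$dip_pvalue, r$dip_pvalue)
  expect_length(parsed[[1]]$bc_jackknife, r$n)
})
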