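# shared test helpers: small in-code fixtures and writers

make_outcomes <- function(density = rep(100, 6),
                          green = c(0, 10, 120, 5, 0, 3),
                          red = c(37, 10, 40, 0, 0, 9)) {
  host_outcomes(data.frame(
    host_id = sprintf("h%02d", seq_along(density)),
    trial_id = "t1",
    inoculum_density = density,
    green_count = green,
    red_count = red))
}

write_trial_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write_trials(host_outcomes(df), path)
  path
}

# mixed battery of small samples for dip cross-validation: all-distinct
# vectors of sizes 2..8 drawn once under a fixed seed
dip_battery <- function(per_size = 5) {
  set.seed(20260920)
  out <- list()
  for (n in 2:8) {
    for (r in seq_len(per_size)) {
      repeat {
        x <- round(runif(n), 3)
        if (!anyDuplicated(x)) break
      }
      out[[length(out) + 1]] <- x
    }
  }
  out
}

# group of hosts with prescribed red fractions (scaled to integer counts)
group_from_fractions <- function(fr, density = 50, total = 40) {
  red <- round(fr * total)
  treatment_group("test",
    host_outcomes(data.frame(
      host_id = sprintf("h%03d", seq_along(fr)), trial_id = "t",
      inoculum_density = density, green_count = total - red, red_count = red)),
    c(10, 100))
}
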