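test_that("scenario sampling is seeded, reproducible and range-respecting", {
  a <- sample_scenarios(100, seed = 1)
  b <- sample_scenarios(100, seed = 1)
  expect_equal(length(a), 100)
  expect_identical(
    vapply(a, function(s) magnitude(s$threshold_volume_per_kg, "ul/kg"),
           numeric(1)),
    vapply(b, function(s) magnitude(s$threshold_volume_per_kg, "ul/kg"),
           numeric(1)))
  r <- default_scenario_ranges()
  for (s in a) {
    expect_s3_class(s, "model_b_scenario")
    expect_true(s$rat_alveolar_fraction >= r$f_rat[1] &&
                  s$rat_alveolar_fraction <= r$f_rat[2])
    expect_true(magnitude(s$particle_density, "g/cm^3") >= 1 &&
                  magnitude(s$particle_density, "g/cm^3") <= 5)
  }
  # degenerate range pins the parameter
  pinned <- default_scenario_ranges()
  pinned$density <- c(2.5, 2.5)
  s <- sample_scenarios(5, ranges = pinned, seed = 3)
  expect_true(all(vapply(s, function(x)
    magnitude(x$particle_density, "g/cm^3"), numeric(1)) == 2.5))
  expect_error(sample_scenarios(0), ">= 1")
  badr <- default_scenario_ranges(); badr$density <- c(5, 1)
  expect_error(sample_scenarios(5, ranges = badr), "ordered")
})

test_that("sampled scenarios bracketing a known case span its HEC", {
  tight <- list(f_rat = c(0.05, 0.08), f_human = c(0.07, 0.10),
                t_half_rat = c(50, 70), t_half_human = c(350, 450),
                density = c(1, 1), threshold = c(1, 1))
  hecs <- vapply(sample_scenarios(200, ranges = tight, seed = 8),
                 function(s) magnitude(hec_volumetric(s)$hec, "mg/m^3"),
                 numeric(1))
  expect_true(min(hecs) < 1.03 && max(hecs) > 1.03)
})

test_that("noise-free simulation reproduces the analytic trajectory", {
  times <- seq(10, 600, length.out = 20)
  s0 <- simulate_burden_series(quantity(0.02175, "mg/day"), 60, times,
                               sigma = 0)
  expect_equal(s0$observed_burdens, oracle_trajectory(0.02175, 60, times),
               tolerance = 1e-12)
  expect_equal(s0$observed_burdens[length(times)],
               oracle_steady_state(0.02175, 60), tolerance = 1e-3)
  s1 <- simulate_burden_series(quantity(0.02175, "mg/day"), 60, times,
                               sigma = 0.05, seed = 4)
  s2 <- simulate_burden_series(quantity(0.02175, "mg/day"), 60, times,
                               sigma = 0.05, seed = 4)
  expect_identical(s1$observed_burdens, s2$observed_burdens)
  expect_false(identical(s0$observed_burdens, s1$observed_burdens))
  expect_error(simulate_burden_series(quantity(1, "mg/day"), 60, times,
                                      sigma = -1), "sigma")
})

test_that("clearance recovery inverts noiseless and noisy series", {
  times <- seq(10, 600, length.out = 20)
  clean <- simulate_burden_series(quantity(0.02175, "mg/day"), 60, times,
                                  sigma = 0)
  fit <- recover_clearance(clean)
  expect_true(fit$converged)
  expect_equal(fit$t_half, 60, tolerance = 1e-3)
  expect_equal(fit$D, 0.02175, tolerance = 1e-3)
  # bootstrap intervals cover the truth for a noisy series
  noisy <- simulate_burden_series(quantity(0.02175, "mg/day"), 60, times,
                                  sigma = 0.05, seed = 12)
  fitb <- recover_clearance(noisy, n_boot = 100, seed = 13)
  expect_true(fitb$ci_t_half[1] < 60 && 60 < fitb$ci_t_half[2])
})

test_that("recovery refuses unidentifiable or underpowered designs", {
  short <- simulate_burden_series(quantity(0.02175, "mg/day"), 60,
                                  c(1, 2, 3, 4, 5), sigma = 0)
  expect_error(recover_clearance(short), "not identifiable")
  few <- simulate_burden_series(quantity(0.02175, "mg/day"), 60,
                                c(30, 60, 120), sigma = 0)
  expect_error(recover_clearance(few), "at least 4")
})

test_that("recovered clearance rate is essentially unbiased at 5% noise", {
  times <- seq(10, 600, length.out = 20)
  k_true <- log(2) / 60
  k_hat <- vapply(1:500, function(i) {
    s <- simulate_burden_series(quantity(0.02175, "mg/day"), 60, times,
                                sigma = 0.05, seed = 1000 + i)
    recover_clearance(s)$k
  }, numeric(1))
  bias <- abs(mean(k_hat) - k_true) / k_true
  expect_lt(bias, 0.02)
  # median recovered half-time within 5% of truth
  expect_lt(abs(stats::median(log(2) / k_hat) - 60) / 60, 0.05)
})
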