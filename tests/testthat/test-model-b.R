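row_scenario <- function(f_rat = 0.075, f_human = 0.164, threshold = 1,
                         t_half_human = 400, density = 1) {
  human <- load_physiology("human_MAK_Brown")
  human$clearance_half_time <- parameter_value(
    quantity(t_half_human, "day"), "test fixture")
  model_b_scenario(
    human = human,
    rat_alveolar_fraction = f_rat, human_alveolar_fraction = f_human,
    threshold_volume_per_kg = quantity(threshold, "ul/kg"),
    particle_density = quantity(density, "g/cm^3"))
}

test_that("Morrow threshold and per-gram-lung conversions", {
  expect_equal(magnitude(morrow_threshold(70), "ul/kg"), 4.2,
               tolerance = 1e-12)
  expect_equal(magnitude(morrow_threshold(70, 0), "ul/kg"), 0)
  expect_equal(magnitude(morrow_threshold(500), "ul/kg"), 30,
               tolerance = 1e-12)
  expect_equal(magnitude(threshold_per_gram_lung(4.2, 4.5), "ul/g"),
               4.2 / 4.5, tolerance = 1e-12)
  expect_equal(round_half_up(magnitude(
    threshold_per_gram_lung(4.2, 4.5), "ul/g"), 2), 0.93)
  expect_equal(magnitude(threshold_per_gram_lung(4.2, 4.2), "ul/g"), 1,
               tolerance = 1e-12)
  # the per-g reading of a 1 ul threshold
  expect_equal(magnitude(threshold_per_gram_lung(1, 4.5), "ul/g"),
               1 / 4.5, tolerance = 1e-12)
})

test_that("volumetric NOAEC inversion matches the printed scenarios", {
  expect_equal(magnitude(noaec_eq7(row_scenario()), "mg/m^3"), 0.5311,
               tolerance = 1e-4)
  expect_equal(magnitude(noaec_eq7(row_scenario(f_rat = 0.033)), "mg/m^3"),
               1.2072, tolerance = 1e-4)
  expect_equal(magnitude(noaec_eq7(row_scenario(f_rat = 0.063,
                                                threshold = 4.2)), "mg/m^3"),
               2.6557, tolerance = 1e-4)
  # fvi enters as a plain divisor
  s <- row_scenario(); s$fvi <- 2
  expect_equal(magnitude(noaec_eq7(s), "mg/m^3"), 0.5311 / 2,
               tolerance = 1e-4)
})

test_that("adjustment factors have the table-validated closed forms", {
  expect_equal(af_lungburden(row_scenario()), (0.29 * 0.075) /
                 ((10 / 70) * 0.164), tolerance = 1e-12)
  expect_equal(round_half_up(af_lungburden(row_scenario()), 2), 0.93)
  expect_equal(round_half_up(af_lungburden(
    row_scenario(f_rat = 0.063, f_human = 0.084)), 2), 1.52)
  expect_equal(af_clearance(row_scenario()), (400 / 60) * (70 / 500),
               tolerance = 1e-12)
  expect_equal(round_half_up(af_clearance(
    row_scenario(t_half_human = 250)), 2), 0.58)
  # identical per-kg ventilation, fractions, half-times and pools give 1
  rat <- load_physiology("rat_MAK")
  same <- model_b_scenario(rat = rat, human = rat,
                           rat_alveolar_fraction = 0.075,
                           human_alveolar_fraction = 0.075)
  expect_equal(af_lungburden(same), 1, tolerance = 1e-12)
  expect_equal(af_clearance(same), 1, tolerance = 1e-12)
})

test_that("volumetric HEC reproduces representative printed rows", {
  r1 <- hec_volumetric(row_scenario())
  expect_equal(magnitude(r1$hec, "mg/m^3"), 0.528, tolerance = 1e-3)
  expect_equal(round_half_up(magnitude(r1$hec, "mg/m^3"), 2), 0.53)
  r2 <- hec_volumetric(row_scenario(f_rat = 0.063, f_human = 0.084))
  expect_equal(magnitude(r2$hec, "mg/m^3"), 1.031, tolerance = 1e-3)
  r8 <- hec_volumetric(row_scenario(f_rat = 0.063, f_human = 0.084,
                                    threshold = 4.2, t_half_human = 250))
  expect_equal(magnitude(r8$hec, "mg/m^3"), 6.931, tolerance = 1e-3)
  expect_true(r8$dimension_audit_clean)
  # result invariant: hec = noaec x af_lb / af_cl
  expect_equal(magnitude(r8$hec, "mg/m^3"),
               magnitude(r8$noaec_rat, "mg/m^3") * r8$af_lungburden /
                 r8$af_clearance, tolerance = 1e-12)
})

test_that("the rat alveolar fraction cancels out of the HEC", {
  for (f in c(0.033, 0.063, 0.075, 0.15)) {
    res <- hec_volumetric(row_scenario(f_rat = f))
    ref <- hec_volumetric(row_scenario(f_rat = 0.075))
    expect_equal(magnitude(res$hec, "mg/m^3"), magnitude(ref$hec, "mg/m^3"),
                 tolerance = 1e-12)
  }
})

test_that("HEC scales linearly with density and threshold, inversely with human half-time", {
  base <- magnitude(hec_volumetric(row_scenario())$hec, "mg/m^3")
  expect_equal(magnitude(hec_volumetric(
    row_scenario(density = 4.3))$hec, "mg/m^3"), 4.3 * base,
    tolerance = 1e-12)
  expect_equal(magnitude(hec_volumetric(
    row_scenario(threshold = 4.2))$hec, "mg/m^3"), 4.2 * base,
    tolerance = 1e-12)
  shorter <- magnitude(hec_volumetric(
    row_scenario(t_half_human = 250))$hec, "mg/m^3")
  expect_gt(shorter, base)
})

test_that("AF decomposition equals the full steady-state burden-per-pool ratio", {
  # randomized scenarios; hec_volumetric() hard-fails internally on any
  # disagreement beyond 1e-10 relative, so a clean run is the assertion
  scenarios <- sample_scenarios(50, seed = 97)
  for (s in scenarios) {
    res <- hec_volumetric(s)
    k_r <- log(2) / magnitude(s$rat$clearance_half_time$quantity, "day")
    k_h <- log(2) / magnitude(s$human$clearance_half_time$quantity, "day")
    full <- (0.29 * s$rat_alveolar_fraction / (k_r * 70)) /
      ((10 / 70) * s$human_alveolar_fraction / (k_h * 500))
    expect_equal(res$af_lungburden / res$af_clearance, full,
                 tolerance = 1e-10)
  }
})

test_that("the density rule-of-thumb reference line is 0.5 x density", {
  expect_equal(magnitude(hec_simple_rule(1), "mg/m^3"), 0.5)
  expect_equal(magnitude(hec_simple_rule(2), "mg/m^3"), 1.0)
  expect_equal(magnitude(hec_simple_rule(4.3), "mg/m^3"), 2.15)
  expect_error(hec_simple_rule(0), "positive")
})
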