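make_scenario_a <- function(density = 1.2, noaec = 1,
                            f_rat = 0.04, f_human = 0.0701,
                            rat_surface = 0.2972, human_surface = 57.22,
                            t_half_human = 400) {
  rat <- load_physiology("rat_allometry_250g")
  rat$alveolar_surface_area <- parameter_value(
    quantity(rat_surface, "m^2"), "test fixture")
  human <- load_physiology("human_MAK_Brown")
  human$alveolar_surface_area <- parameter_value(
    quantity(human_surface, "m^2"), "test fixture")
  human$clearance_half_time <- parameter_value(
    quantity(t_half_human, "day"), "test fixture")
  model_a_scenario(rat = rat, human = human,
                   rat_deposition = f_rat, human_deposition = f_human,
                   noaec_rat = noaec, substance_label = "test dust",
                   substance_density = quantity(density, "g/cm^3"))
}

test_that("mass-per-surface HEC equates steady-state burden per surface", {
  res <- hec_mass_per_surface(make_scenario_a())
  # closed-form hand evaluation with the same inputs
  k_r <- log(2) / 60; k_h <- log(2) / 400
  ve_r <- 0.29 * 0.25; ve_h <- 10
  expected <- 1 * (0.04 * ve_r / (k_r * 0.2972)) /
    (0.0701 * ve_h / (k_h * 57.22))
  expect_equal(magnitude(res$hec, "mg/m^3"), expected, tolerance = 1e-12)
  expect_equal(magnitude(res$hec, "mg/m^3"), 0.1195, tolerance = 1e-3)
  expect_true(res$dimension_audit_clean)
  expect_gt(nrow(res$ledger), 5)
})

test_that("identical species physiology gives a unit translation factor", {
  rat <- load_physiology("rat_MAK")
  s <- model_a_scenario(rat = rat, human = rat, rat_deposition = 0.075,
                        human_deposition = 0.075, noaec_rat = 1)
  res <- hec_mass_per_surface(s)
  expect_equal(res$translation_factor, 1, tolerance = 1e-12)
  expect_equal(magnitude(res$hec, "mg/m^3"), 1, tolerance = 1e-12)
})

test_that("the HEC is exactly invariant under the density metadata", {
  base <- hec_mass_per_surface(make_scenario_a(density = 1))
  for (rho in c(1.2, 4.3, 5)) {
    alt <- hec_mass_per_surface(make_scenario_a(density = rho))
    expect_identical(magnitude(alt$hec, "mg/m^3"),
                     magnitude(base$hec, "mg/m^3"))
  }
})

test_that("HEC responds monotonically to human surface, clearance and deposition", {
  base <- magnitude(hec_mass_per_surface(make_scenario_a())$hec, "mg/m^3")
  doubled_s <- magnitude(hec_mass_per_surface(
    make_scenario_a(human_surface = 2 * 57.22))$hec, "mg/m^3")
  expect_equal(doubled_s, 2 * base, tolerance = 1e-12)
  faster_clearance <- magnitude(hec_mass_per_surface(
    make_scenario_a(t_half_human = 200))$hec, "mg/m^3")
  expect_gt(faster_clearance, base)
  more_deposition <- magnitude(hec_mass_per_surface(
    make_scenario_a(f_human = 0.14))$hec, "mg/m^3")
  expect_lt(more_deposition, base)
})

test_that("surface and clearance corrections rescale a reference HEC", {
  toner <- corrected_hec(0.134, 193, 349, 400, 255)
  expect_equal(magnitude(toner, "mg/m^3"), 0.134 * (349 / 193) * (400 / 255),
               tolerance = 1e-12)
  expect_equal(round_half_up(magnitude(toner, "mg/m^3"), 2), 0.38)
  tio2 <- corrected_hec(1.07, 193, 349, 400, 255)
  expect_equal(round_half_up(magnitude(tio2, "mg/m^3"), 2), 3.04)
  # no-op correction
  noop <- corrected_hec(0.5, 200, 200, 300, 300)
  expect_equal(magnitude(noop, "mg/m^3"), 0.5, tolerance = 1e-15)
  # composition: old->mid then mid->new equals old->new
  set.seed(5)
  for (i in 1:10) {
    r <- sort(runif(3, 100, 400)); t <- sort(runif(3, 100, 500))
    two_step <- corrected_hec(
      magnitude(corrected_hec(1, r[1], r[2], t[1], t[2]), "mg/m^3"),
      r[2], r[3], t[2], t[3])
    one_step <- corrected_hec(1, r[1], r[3], t[1], t[3])
    expect_equal(magnitude(two_step, "mg/m^3"),
                 magnitude(one_step, "mg/m^3"), tolerance = 1e-12)
  }
  expect_error(corrected_hec(-1, 193, 349, 400, 255), "positive")
})

test_that("density division audit reports both the honest and unit-dropping values", {
  audit <- density_division_audit(quantity(1.06, "mg/m^3"),
                                  quantity(4.3, "g/cm^3"))
  expect_false(audit$dimension_ok)
  expect_equal(magnitude(audit$value, "1"), 2.4651e-10, tolerance = 1e-4)
  expect_equal(unname(audit$value$dim), c(0, 0, 0))
  toner <- density_division_audit(quantity(0.133, "mg/m^3"),
                                  quantity(1.2, "g/cm^3"))
  expect_equal(round_half_up(toner$unit_dropping_value, 2), 0.11)
  unity <- density_division_audit(quantity(0.7, "mg/m^3"),
                                  quantity(1, "g/cm^3"))
  expect_equal(unity$unit_dropping_value, 0.7)
})
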