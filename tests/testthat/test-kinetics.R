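test_that("clearance rate is exactly ln(2)/half-time", {
  expect_equal(magnitude(rate_from_half_time(60), "1/day"), log(2) / 60,
               tolerance = 1e-15)
  expect_equal(magnitude(rate_from_half_time(log(2)), "1/day"), 1,
               tolerance = 1e-15)
  expect_equal(magnitude(rate_from_half_time(400), "1/day"), log(2) / 400,
               tolerance = 1e-15)
  cs <- clearance_spec(60)
  expect_equal(magnitude(cs$rate, "1/day") * magnitude(cs$half_time, "day"),
               log(2), tolerance = 1e-12)
  expect_error(rate_from_half_time(0), "positive")
})

test_that("deposition rate is C x F x VE, optionally volumetric", {
  r <- deposition_rate(1, 0.075, 0.29)
  expect_equal(magnitude(r, "mg/day"), 0.02175, tolerance = 1e-12)
  rv <- deposition_rate(1, 0.075, 0.29, density = 1)
  expect_equal(magnitude(rv, "ul/day"), 0.02175, tolerance = 1e-12)
  # per-kg ventilation carries the per-kg through
  rk <- deposition_rate(quantity(1, "mg/m^3"), 0.075,
                        quantity(0.29, "m^3/kg/day"),
                        density = quantity(2, "g/cm^3"))
  expect_equal(magnitude(rk, "ul/kg/day"), 0.02175 / 2, tolerance = 1e-12)
  expect_equal(magnitude(deposition_rate(0, 0.075, 0.29), "mg/day"), 0)
  expect_error(deposition_rate(1, 1.5, 0.29), "\\(0, 1\\)")
})

test_that("steady-state burden is deposition rate over clearance rate", {
  b <- steady_state_burden(quantity(0.02175, "mg/day"), 60)
  expect_equal(magnitude(b, "mg"), oracle_steady_state(0.02175, 60),
               tolerance = 1e-12)
  expect_equal(magnitude(b, "mg"), 1.8827, tolerance = 1e-4)
  expect_equal(magnitude(steady_state_burden(quantity(0, "mg/day"), 60),
                         "mg"), 0)
  v <- steady_state_burden(quantity(0.069, "ul/day"), 60)
  expect_equal(magnitude(v, "ul"), 5.973, tolerance = 1e-3)
  # linear in rate and in half-time
  for (fac in c(0.1, 3)) {
    expect_equal(magnitude(steady_state_burden(
      quantity(0.02175 * fac, "mg/day"), 60), "mg"),
      fac * magnitude(b, "mg"), tolerance = 1e-12)
    expect_equal(magnitude(steady_state_burden(
      quantity(0.02175, "mg/day"), 60 * fac), "mg"),
      fac * magnitude(b, "mg"), tolerance = 1e-12)
  }
})

test_that("analytic trajectory matches closed form and an independent ODE", {
  D <- 0.02175; t_half <- 60
  times <- c(1, 5, 15, 30, 60, 120, 240, 480, 900)
  st <- burden_trajectory(quantity(D, "mg/day"), t_half, times)
  expect_equal(st$trajectory$burden, oracle_trajectory(D, t_half, times),
               tolerance = 1e-12)
  # at one half-time the burden is half the steady state
  at60 <- st$trajectory$burden[times == 60]
  expect_equal(at60, magnitude(st$steady_state_burden, "mg") / 2,
               tolerance = 1e-12)
  # independent numeric integration agrees to 1e-8 relative
  skip_if_not_installed("deSolve")
  ode <- ode_trajectory(D, t_half, times)
  expect_equal(st$trajectory$burden, ode, tolerance = 1e-8)
  # non-decreasing, bounded above by steady state, asymptote at 20 half-times
  expect_true(all(diff(st$trajectory$burden) > 0))
  expect_true(all(st$trajectory$burden <=
                    magnitude(st$steady_state_burden, "mg")))
  late <- burden_trajectory(quantity(D, "mg/day"), t_half, 20 * t_half)
  expect_equal(late$trajectory$burden,
               magnitude(late$steady_state_burden, "mg"),
               tolerance = 1e-6)
  expect_error(burden_trajectory(quantity(D, "mg/day"), t_half, c(5, 1)),
               "increasing")
})

test_that("threshold inversion reproduces the grid NOAECs", {
  n1 <- noaec_from_threshold(quantity(1, "ul/kg"), 60,
                             quantity(0.29, "m^3/kg/day"), 0.075,
                             quantity(1, "g/cm^3"))
  expect_equal(magnitude(n1, "mg/m^3"), log(2) / 60 / (0.29 * 0.075),
               tolerance = 1e-12)
  expect_equal(round_half_up(magnitude(n1, "mg/m^3"), 2), 0.53)
  n2 <- noaec_from_threshold(quantity(4.2, "ul/kg"), 60,
                             quantity(0.29, "m^3/kg/day"), 0.063,
                             quantity(1, "g/cm^3"))
  expect_equal(round_half_up(magnitude(n2, "mg/m^3"), 2), 2.66)
  expect_equal(magnitude(noaec_from_threshold(
    quantity(0, "ul/kg"), 60, quantity(0.29, "m^3/kg/day"), 0.075,
    quantity(1, "g/cm^3")), "mg/m^3"), 0)
})

test_that("NOAEC -> deposition -> steady state round-trips the threshold", {
  set.seed(23)
  for (i in 1:25) {
    thr <- runif(1, 0.1, 20)          # ul/kg
    t_half <- runif(1, 20, 500)       # days
    ve <- runif(1, 0.05, 1)           # m^3/(day kg)
    f <- runif(1, 0.01, 0.5)
    rho <- runif(1, 0.5, 6)           # g/cm^3
    noaec <- noaec_from_threshold(quantity(thr, "ul/kg"), t_half,
                                  quantity(ve, "m^3/kg/day"), f,
                                  quantity(rho, "g/cm^3"))
    dep <- deposition_rate(noaec, f, quantity(ve, "m^3/kg/day"),
                           density = quantity(rho, "g/cm^3"))
    back <- steady_state_burden(dep, t_half)
    expect_equal(magnitude(back, "ul/kg"), thr, tolerance = 1e-10)
  }
})
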