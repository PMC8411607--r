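adj25 <- adjust_to_temperature(c4_parameters(), 25)

test_that("ATP per electron reflects linear/cyclic proton stoichiometry", {
  expect_equal(atp_per_electron(0, 4), 0.75)
  expect_equal(atp_per_electron(0.5, 4), 1.25)
  expect_equal(atp_per_electron(0.3, 4), 2.7 / 2.8)
  expect_error(atp_per_electron(1, 4), "f_cyc")
})

test_that("PSII light fraction shifts towards PSI with cyclic flow", {
  expect_equal(psii_light_fraction(0), 0.5)
  expect_equal(round(psii_light_fraction(0.3), 2), 0.41)
  expect_lt(psii_light_fraction(1 - 1e-9), 1e-8)  # limit as f_cyc -> 1
})

test_that("useful irradiance is the product of its attenuation factors", {
  expect_equal(useful_irradiance(0, 0.85, 0.15, 0.41), 0)
  expect_equal(useful_irradiance(123, 1, 0, 1), 123)
  expect_equal(useful_irradiance(2000, 0.85, 0.15, 0.5), 722.5)
})

test_that("electron transport saturates at Jmax and is continuous in theta", {
  expect_equal(electron_transport_rate(0, 248, 0.7), 0)
  expect_equal(electron_transport_rate(1e9, 248, 0.7), 248, tolerance = 1e-4)
  expect_equal(electron_transport_rate(248, 248, 0), 124)
  # continuity at theta = 0: the quadratic root collapses onto the
  # rectangular hyperbola as the curvature vanishes
  I2 <- c(10, 100, 595, 3000)
  expect_lt(max(abs(electron_transport_rate(I2, 248, 1e-9) -
                      I2 * 248 / (I2 + 248))), 1e-6)
  expect_lt(max(abs(electron_transport_rate(I2, 248, 1e-6) -
                      I2 * 248 / (I2 + 248))), 1e-3)
  # monotone in I2 and in Jmax
  expect_true(all(diff(electron_transport_rate(seq(0, 4000, 25),
                                               248, 0.7)) >= 0))
  expect_true(all(diff(electron_transport_rate(595, seq(50, 600, 25),
                                               0.7)) >= 0))
  expect_error(electron_transport_rate(100, 248, 1.2), "theta")
})

test_that("light-reaction bookkeeping is self-consistent", {
  st <- light_reaction_state(c(0, 200, 2000), adj25)
  expect_equal(st$J1, st$J / (1 - 0.3))
  expect_equal(st$Jcyc, st$J1 - st$J)
  expect_equal(st$JH, st$J * (3 - 0.3) / (1 - 0.3))
  expect_equal(st$JATP, st$z * st$J)  # z*J conservation
  expect_equal(st$Jm + st$Js, st$J)
  expect_equal(st$Jm, 0.4 * st$J)
  expect_true(all(st$J <= adj25$Jmax & st$J <= st$I2 + 1e-9))
})

test_that("energy budget matches direct arithmetic", {
  eb0 <- energy_budget(7, 11, 5000, 200, 1e-300)
  expect_equal(eb0$atp_rate, 2 * 11 + 3 * 7)
  expect_equal(eb0$nadph_rate, 2 * 7)
  expect_equal(energy_budget(0, 0, 100, 200, 0.0003817)$atp_rate, 0)
  eb <- energy_budget(10, 12, 5000, 200, 0.5 / 1310)
  expect_equal(eb$atp_rate, 55.0688, tolerance = 1e-5)
  expect_equal(eb$nadph_rate, 20.6107, tolerance = 1e-5)
  expect_error(energy_budget(10, 12, 0, 200, 0.0003817), "Cs")
})

test_that("idealized partitioning makes the two cycles co-limit at x = 0.4", {
  p <- c4_parameters(gamma_star25 = 1e-12, Rd25 = 0)
  a <- adjust_to_temperature(p, 25)
  st <- light_limited_assimilation(0, 200, 200, a)
  # the quadratic has a double root here, so accuracy is sqrt(eps)-limited
  expect_equal(st$Aj, a$z * 0.2 * 200, tolerance = 1e-4)
})

test_that("min-rule approximation evaluates both branches", {
  ap <- light_limited_approx(100, 200, adj25)
  expect_equal(ap$Aj, 0.9642857 * 0.6 * 200 / 3 - 0.4, tolerance = 1e-6)
  expect_equal(ap$branch, "c3_cycle")
  a_x1 <- adjust_to_temperature(c4_parameters(x = 1), 25)
  expect_equal(light_limited_approx(100, 200, a_x1)$Aj, -a_x1$Rd)
  a_x0 <- adjust_to_temperature(c4_parameters(x = 0), 25)
  expect_equal(light_limited_approx(100, 200, a_x0)$Aj,
               -a_x0$Rm + a_x0$gbs * 100)
})

test_that("light-limited quadratic equals the simultaneity oracle", {
  # no electron transport leaves only respiration
  expect_equal(light_limited_assimilation(100, 200, 0, adj25)$Aj,
               -adj25$Rd, tolerance = 1e-6)
  # frozen oracle value at the default light-saturated state
  J <- light_reaction_state(2000, adj25)$J
  expect_equal(light_limited_assimilation(200, 200, J, adj25)$Aj,
               35.587764, tolerance = 1e-6)
  set.seed(43)
  worst <- 0
  for (i in 1:200) {
    alpha <- sample(c(0, 0.5, 1), 1)
    p <- draw_params(alpha = alpha)
    a <- adjust_to_temperature(p, 25)
    Cm <- stats::runif(1, 0, 2000)
    Om <- sample(c(50, 200, 400), 1)
    J <- stats::runif(1, 5, a$Jmax)
    got <- light_limited_assimilation(Cm, Om, J, a)$Aj
    want <- oracle_light(Cm, Om, J, a)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-6)
})

test_that("light-limited state closes its flux balances", {
  J <- light_reaction_state(1200, adj25)$J
  st <- light_limited_assimilation(150, 200, J, adj25)
  # C4-cycle side vs C3-cycle side of the net rate
  expect_lt(abs((st$Vp - st$L - adj25$Rm) - (st$Vc - 0.5 * st$Vo - adj25$Rd)),
            1e-8)
  # ATP consumption equals ATP supply z*J at the electron-transport limit
  expect_equal(st$atp_rate, adj25$z * J, tolerance = 1e-8)
})

test_that("Aj is monotone in J and in Cm over physiological ranges", {
  J <- seq(5, 240, length.out = 80)
  expect_true(all(diff(light_limited_assimilation(300, 200, J,
                                                  adj25)$Aj) > 0))
  Cm <- seq(5, 2000, length.out = 80)
  expect_true(all(diff(light_limited_assimilation(Cm, 200, 150,
                                                  adj25)$Aj) >= -1e-12))
})

test_that("optimal partitioning is 0.4 in the idealized limit and shifts with alpha", {
  p <- c4_parameters(gamma_star25 = 1e-12, Rd25 = 0)
  a <- adjust_to_temperature(p, 25)
  opt <- optimal_partitioning(0, 200, 1500, a)
  expect_equal(opt$x_opt, 0.4, tolerance = 1e-3)
  # defaults at high light: optimum stays close to the canonical 0.4 (the
  # published optima under varying conditions span roughly 0.40-0.42)
  a0 <- adjust_to_temperature(c4_parameters(), 25)
  opt0 <- optimal_partitioning(100, 200, 2000, a0)
  expect_gt(opt0$x_opt, 0.38)
  expect_lt(opt0$x_opt, 0.43)
  # bundle-sheath O2 evolution raises the optimal allocation to the C4 cycle
  a1 <- adjust_to_temperature(c4_parameters(alpha = 1), 25)
  opt1 <- optimal_partitioning(100, 200, 2000, a1)
  expect_gt(opt1$x_opt, opt0$x_opt)
})
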