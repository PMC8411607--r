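adj25 <- adjust_to_temperature(c4_parameters(), 25)

test_that("PEP carboxylation follows Michaelis-Menten capped by regeneration", {
  r <- pep_carboxylation_rate(c(0, 82, 10000), 200, 82, c(1000, 1000, 80))
  expect_equal(r$Vp, c(0, 100, 80))
  expect_equal(r$vp_limited_by,
               c("carboxylation", "carboxylation", "regeneration"))
  # exact tie resolves to regeneration
  tie <- pep_carboxylation_rate(82, 200, 82, 100)
  expect_equal(tie$Vp, 100)
  expect_equal(tie$vp_limited_by, "regeneration")
  expect_error(pep_carboxylation_rate(-1, 200, 82, 80), "Cm")
})

test_that("bundle-sheath O2 reduces to Om without PSII activity or flux", {
  expect_equal(bundle_sheath_o2(c(-5, 0, 40), 0, 0.047, 0.003, 200),
               rep(200, 3))
  expect_equal(bundle_sheath_o2(0, 1, 0.047, 0.003, 200), 200)
  # 30/(0.047*0.003) ubar = 212.766 mbar on top of 200
  expect_equal(bundle_sheath_o2(30, 1, 0.047, 0.003, 200), 412.76596,
               tolerance = 1e-7)
})

test_that("leak rate is conductance times the CO2 gradient, sign included", {
  expect_equal(leak_rate(0.003, 500, 500), 0)
  expect_equal(leak_rate(0.003, 0, 100), -0.3)  # inward diffusion
  expect_equal(leak_rate(0.003, 5100, 100), 15)
})

test_that("low-CO2 approximation is PEPC rate minus Rm plus inward diffusion", {
  expect_equal(enzyme_limited_lowco2_approx(0, adj25), -adj25$Rm)
  expect_equal(enzyme_limited_lowco2_approx(100, adj25),
               100 * 200 / 182 - 0.2 + 0.3, tolerance = 1e-12)
})

test_that("Rubisco-implied bundle-sheath CO2 inverts the demand function", {
  # at A = -Rd the ratio term vanishes: Cs equals the compensation pressure
  expect_equal(bundle_sheath_co2_from_rubisco(-adj25$Rd, 200, adj25),
               adj25$gamma_star * 200 * 1000, tolerance = 1e-10)
  # half-capacity: Cs = 2*gamma*Os + Kc(1+Os/Ko), frozen independently
  A_half <- 0.5 * adj25$Vcmax - adj25$Rd
  expect_equal(bundle_sheath_co2_from_rubisco(A_half, 200, adj25),
               2191.4389, tolerance = 1e-4)
  expect_error(bundle_sheath_co2_from_rubisco(adj25$Vcmax, 200, adj25),
               "infeasible")
  # the pole: Cs grows without bound as demand approaches capacity
  near <- bundle_sheath_co2_from_rubisco(adj25$Vcmax - adj25$Rd - 1e-6,
                                         200, adj25)
  expect_gt(near, 1e8)
})

test_that("enzyme-limited quadratic approaches its limiting branches", {
  # huge Rubisco capacity: Cs is drawn down to the compensation pressure
  # gamma*Os, so Ac -> Vp - Rm + gbs*(Cm - gamma*Os); the textbook
  # supply-side branch Vp - Rm + gbs*Cm is the same thing with the small
  # compensation term dropped
  p_fast <- c4_parameters(Vcmax25 = 1e7, Vpr = 1e7, Rd25 = 0.4)
  a <- adjust_to_temperature(p_fast, 25)
  st <- enzyme_limited_assimilation(100, 200, a)
  Vp <- 100 * a$Vpmax / (100 + a$Kp)
  gamma_os <- a$gamma_star * 200 * 1000
  expect_lt(abs(st$Ac - (Vp - a$Rm + a$gbs * (100 - gamma_os))), 1e-3)
  expect_lt(abs(st$Ac - (Vp - a$Rm + a$gbs * 100)), a$gbs * gamma_os * 1.1)
  # huge PEPC supply at high CO2: Rubisco branch Ac -> Vcmax - Rd
  p_pep <- c4_parameters(Vpmax25 = 1e7, Vpr = 1e7)
  a2 <- adjust_to_temperature(p_pep, 25)
  st2 <- enzyme_limited_assimilation(5000, 200, a2)
  expect_equal(st2$Ac, a2$Vcmax - a2$Rd, tolerance = 1e-3)
})

test_that("enzyme-limited state satisfies both flux balances and the oracle", {
  st <- enzyme_limited_assimilation(100, 200, adj25)
  expect_equal(st$Ac, 34.675506, tolerance = 1e-6)  # frozen oracle value
  # Eq. of Rubisco side vs mesophyll side
  expect_lt(abs((st$Vc - 0.5 * st$Vo - adj25$Rd) -
                  (st$Vp - st$L - adj25$Rm)), 1e-8)
  expect_equal(st$Vo / st$Vc,
               2 * adj25$gamma_star * st$Os * 1000 / st$Cs,
               tolerance = 1e-10)
  # internal consistency: Ac re-derived from (Cs, Os) via the demand law
  Ac_back <- (st$Cs - adj25$gamma_star * st$Os * 1000) * adj25$Vcmax /
    (st$Cs + adj25$Kc * (1 + st$Os / adj25$Ko)) - adj25$Rd
  expect_lt(abs(Ac_back - st$Ac) / max(abs(st$Ac), 1), 1e-8)
})

test_that("quadratic equals the simultaneity oracle over random draws", {
  set.seed(42)
  worst <- 0
  for (i in 1:200) {
    alpha <- sample(c(0, 0.5, 1), 1)
    p <- draw_params(alpha = alpha)
    a <- adjust_to_temperature(p, 25)
    Cm <- stats::runif(1, 0, 2000)
    Om <- sample(c(50, 200, 400), 1)
    got <- enzyme_limited_assimilation(Cm, Om, a)$Ac
    want <- oracle_enzyme(Cm, Om, a)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-6)
})

test_that("enzyme-limited rate is non-decreasing in mesophyll CO2", {
  Cm <- seq(0, 10000, length.out = 400)
  Ac <- enzyme_limited_assimilation(Cm, 200, adj25)$Ac
  expect_true(all(diff(Ac) > -1e-10))
})

test_that("without bundle-sheath PSII, Os = Om and Ac ignores ao", {
  st <- enzyme_limited_assimilation(c(50, 300, 1500), 200, adj25)
  expect_equal(st$Os, rep(200, 3))
  a_hi <- adjust_to_temperature(c4_parameters(ao25 = 0.094), 25)
  st2 <- enzyme_limited_assimilation(c(50, 300, 1500), 200, a_hi)
  expect_equal(st$Ac, st2$Ac)
})
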