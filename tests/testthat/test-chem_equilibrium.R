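test_that("pKa matches the reference value at 25 degC and the van't Hoff
           oracle elsewhere", {
  expect_equal(pka_nh4(25), 9.25)
  # zero-enthalpy limit: temperature-independent
  k0 <- nhx_constants(dH_kJ_mol = 0)
  expect_equal(pka_nh4(c(0, 13, 25, 50), k0), rep(9.25, 4))
  # frozen independent evaluation at the stream temperature
  expect_equal(pka_nh4(13), 9.6335805, tolerance = 1e-7)
  expect_equal(pka_nh4(13), oracle_pka(13), tolerance = 1e-12)
  # colder water, higher pKa
  expect_true(all(diff(pka_nh4(seq(0, 50, 5))) < 0))
  expect_error(pka_nh4(-5), "temp_C")
  expect_error(pka_nh4(60), "temp_C")
})

test_that("speciation partitions the pool per the Henderson-Hasselbalch
           fraction", {
  # symmetry at the pKa
  expect_equal(speciate_nhx(10, pH = 9.25, pKa = 9.25)$frac_nh3, 0.5)
  # ~1% NH3 at the midpoint of the stream pH range with the 9.25 pKa
  s <- speciate_nhx(100, pH = 7.29, pKa = 9.25)
  expect_equal(s$frac_nh3, 0.010845859, tolerance = 1e-7)
  expect_equal(round(s$frac_nh3, 2), 0.01)
  # frozen arithmetic oracle at pH 7.10, 13 degC (T-corrected pKa)
  s2 <- speciate_nhx(80.7, pH = 7.10, temp_C = 13)
  expect_equal(s2$frac_nh3, 0.0029184362, tolerance = 1e-7)
  expect_equal(s2$frac_nh3, oracle_frac_nh3(7.10, oracle_pka(13)),
               tolerance = 1e-12)
  # exact partition of the total
  expect_equal(s2$frac_nh3 + s2$frac_nh4, 1, tolerance = 1e-12)
  expect_equal(s2$nh3_aq_M + s2$nh4_aq_M, 80.7e-6, tolerance = 1e-12)
  expect_error(speciate_nhx(-1, 7), "nhx_uM")
  expect_error(speciate_nhx(1, 15), "pH")
})

test_that("speciation fraction is monotone in pH and temperature with the
           expected limits", {
  f <- speciate_nhx(10, pH = seq(0.5, 13.5, 0.25), temp_C = 25)$frac_nh3
  expect_true(all(diff(f) > 0))
  fT <- speciate_nhx(10, pH = 7.2, temp_C = seq(0, 50, 2))$frac_nh3
  expect_true(all(diff(fT) > 0)) # warmer water, lower pKa, more NH3
  expect_lt(speciate_nhx(10, pH = 0)$frac_nh3, 1e-8)
  expect_gt(speciate_nhx(10, pH = 14)$frac_nh3, 1 - 1e-4)
})

test_that("Henry constant has the reference value at 25 degC and the
           van't Hoff temperature dependence", {
  expect_equal(henry_constant_nh3(25), 59)
  k0 <- nhx_constants(kh_vant_hoff_K = 0)
  expect_equal(henry_constant_nh3(c(0, 13, 25, 50), k0), rep(59, 4))
  # frozen hand evaluation: 59 * exp(4200 * (1/286.15 - 1/298.15))
  expect_equal(henry_constant_nh3(13), 106.51492, tolerance = 1e-7)
  expect_equal(henry_constant_nh3(13), oracle_kh(13), tolerance = 1e-12)
  # NH3 more soluble in cold water
  expect_true(all(diff(henry_constant_nh3(seq(0, 50, 5))) < 0))
  expect_error(henry_constant_nh3(-1), "temp_C")
})

test_that("equilibrium NH3(g) prediction reproduces the stream endmembers
           and obeys its structural identities", {
  # zero NH_x, zero gas
  expect_equal(equilibrium_nh3_gas(
    data.frame(pH = 7.2, temp_C = 13, nhx_uM = 0))$nh3_ppbv, 0)
  # low stream endmember: ~2 ppbv to one significant figure
  low <- equilibrium_nh3_gas(
    data.frame(pH = 7.10, temp_C = 13, nhx_uM = 80.7))
  expect_equal(signif(low$nh3_ppbv, 1), 2)
  expect_equal(low$nh3_ppbv, oracle_ppbv(80.7, 7.10, 13),
               tolerance = 1e-12)
  # frozen chained hand evaluation for the high-pH, high-NH_x stream
  high <- equilibrium_nh3_gas(
    data.frame(pH = 7.48, temp_C = 14, nhx_uM = 158.0))
  expect_equal(high$nh3_ppbv, 11.74290, tolerance = 1e-6)
  expect_equal(high$nh3_ppbv, oracle_ppbv(158.0, 7.48, 14),
               tolerance = 1e-12)
  # round trip through the Henry constant recovers NH3(aq)
  expect_equal(low$partial_pressure_atm * low$kh_M_per_atm,
               low$nh3_aq_M, tolerance = 1e-10)
  # homogeneous of degree 1 in NH_x
  twice <- equilibrium_nh3_gas(
    data.frame(pH = 7.10, temp_C = 13, nhx_uM = 2 * 80.7))
  expect_equal(twice$nh3_ppbv, 2 * low$nh3_ppbv, tolerance = 1e-12)
  # missing-field diagnostics name the field
  expect_error(equilibrium_nh3_gas(data.frame(pH = 7, temp_C = 13)),
               "nhx_uM")
  expect_error(equilibrium_nh3_gas(
    data.frame(pH = NA, temp_C = 13, nhx_uM = 10)), "pH")
})

test_that("chem-equilibrium operations match the brute-force oracle on
           randomized inputs", {
  set.seed(424)
  n <- 25
  temps <- runif(n, 0, 50)
  pHs <- runif(n, 1, 13)
  concs <- runif(n, 0.1, 500)
  expect_equal(pka_nh4(temps), oracle_pka(temps), tolerance = 1e-9)
  expect_equal(henry_constant_nh3(temps), oracle_kh(temps),
               tolerance = 1e-9)
  got <- speciate_nhx(concs, pHs, temps)$frac_nh3
  expect_equal(got, oracle_frac_nh3(pHs, oracle_pka(temps)),
               tolerance = 1e-9)
  ppbv <- equilibrium_nh3_gas(
    data.frame(pH = pHs, temp_C = temps, nhx_uM = concs))$nh3_ppbv
  expect_equal(ppbv, oracle_ppbv(concs, pHs, temps), tolerance = 1e-9)
})
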