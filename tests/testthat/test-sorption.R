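test_that("zero total pressure returns the trivial zero-sorption state", {
  sys <- pure_gas_system(phbv8, co2, -0.002)
  res <- solve_sorption(sys, 0, y = 1)
  expect_identical(res$mass_fraction, 0)
  expect_identical(res$concentration_cm3stp_cm3, 0)
  expect_equal(res$mixture_density_g_cm3,
    sl_density(phbv8, 308.15, 0, phase = "liquid"),
    tolerance = 1e-10
  )
})

test_that("chemical-potential equality holds at every returned state", {
  sys2 <- sorption_system(phbv8,
    kij_gas_polymer = c(-0.002, -0.069),
    kij_gas_gas = -0.03
  )
  iso <- sorption_isotherm(sys2, c(0.5, 1.5, 3), y = c(0.5, 0.5))
  expect_true(all(iso$mu_residual < 1e-8))
  pure <- sorption_isotherm(pure_gas_system(phbv25, co2, -0.043),
    pressures = c(0.1, 1, 3), y = 1
  )
  expect_true(all(pure$mu_residual < 1e-8))
})

test_that("single-gas sorption obeys Henry's law below 1 bar", {
  for (gas in list(co2, ch4)) {
    sys <- pure_gas_system(phbv0, gas)
    S <- vapply(c(0.01, 0.05, 0.1), function(p) {
      solubility_coefficient(solve_sorption(sys, p, y = 1), 1L)
    }, numeric(1))
    expect_lt(max(S) / min(S) - 1, 0.01)
  }
})

test_that("doubling the fugacity doubles the dilute concentration", {
  sys <- pure_gas_system(phbv0, co2)
  r1 <- solve_sorption(sys, 0.02, y = 1)
  r2 <- solve_sorption(sys, 0.04, y = 1)
  ratio <- r2$concentration_cm3stp_cm3 / r1$concentration_cm3stp_cm3
  f_ratio <- r2$fugacity_bar / r1$fugacity_bar
  expect_equal(ratio, f_ratio, tolerance = 0.005)
})

test_that("S at 1 bar matches the infinite-dilution limit within 2 percent", {
  sys <- pure_gas_system(phbv8, co2, -0.002)
  S_1bar <- solubility_coefficient(solve_sorption(sys, 0.1, y = 1), 1L)
  S_dilute <- solubility_coefficient(solve_sorption(sys, 0.001, y = 1), 1L)
  expect_lt(abs(S_1bar / S_dilute - 1), 0.02)
})

test_that("pure-gas isotherms are increasing and CO2 convex in fugacity", {
  sys <- pure_gas_system(phbv8, co2, -0.002)
  iso <- sorption_isotherm(sys, seq(0.5, 3, by = 0.5), y = 1)
  expect_true(all(iso$concentration_cm3stp_cm3 >= 0))
  expect_true(all(diff(iso$concentration_cm3stp_cm3) > 0))
  # positive second difference of c(f): mild convexity towards fugacity
  sec <- diff(diff(iso$concentration_cm3stp_cm3) / diff(iso$fugacity_bar))
  expect_true(all(sec > 0))
})

test_that("selectivity of a gas against itself is 1", {
  expect_identical(solubility_selectivity(0.8, 0.8), 1)
})

test_that("swelling is stronger for CO2 than CH4 in both polymers", {
  for (pol in list(phbv8, phbv25)) {
    r_co2 <- solve_sorption(pure_gas_system(pol, co2), 2, y = 1)
    r_ch4 <- solve_sorption(pure_gas_system(pol, ch4), 2, y = 1)
    expect_gt(abs(r_co2$density_change_pct), abs(r_ch4$density_change_pct))
  }
})

test_that("CO2 uptake at matched fugacity is reduced by a co-penetrant", {
  sys2 <- sorption_system(phbv8,
    kij_gas_polymer = c(-0.002, -0.069), kij_gas_gas = -0.03
  )
  mix <- solve_sorption(sys2, 3, y = c(0.5, 0.5))
  pure_iso <- sorption_isotherm(pure_gas_system(phbv8, co2, -0.002),
    pressures = seq(0.25, 3, by = 0.25), y = 1
  )
  c_pure_at_f <- stats::approx(
    pure_iso$fugacity_bar, pure_iso$concentration_cm3stp_cm3,
    xout = mix$fugacity_bar[1]
  )$y
  expect_lt(mix$concentration_cm3stp_cm3[1], c_pure_at_f)
})

test_that("amorphous rescaling inverts the crystalline dilution", {
  expect_identical(amorphous_rescale(0.7, 0), 0.7)
  expect_identical(amorphous_rescale(0.7, 0.5), 1.4)
  expect_equal(amorphous_rescale(0.4, 0.6), 1.0)
  expect_error(amorphous_rescale(0.4, 1), "\\[0, 1\\)")
})

test_that("kij sensitivity reference rows reproduce the baseline exactly", {
  sys2 <- sorption_system(phbv100, kij_gas_gas = -0.03)
  sweep <- kij_sensitivity(sys2,
    kij_values = c(-0.01, 0), pressures = c(1, 3), y = c(0.8, 0.2)
  )
  ref_rows <- dplyr::filter(sweep, kij == 0)
  expect_true(all(abs(ref_rows$deviation_pct) < 1e-9))
  expect_setequal(unique(sweep$varied_gas), c("CO2", "CH4"))
})

test_that("CO2 uptake responds to its own kij far more than to CH4's", {
  sys2 <- sorption_system(phbv100, kij_gas_gas = -0.03)
  sweep <- kij_sensitivity(sys2,
    kij_values = c(-0.05, 0), pressures = 3, y = c(0.8, 0.2)
  )
  dev_own <- abs(dplyr::filter(
    sweep, varied_gas == "CO2", kij == -0.05, species == "CO2"
  )$deviation_pct)
  dev_cross <- abs(dplyr::filter(
    sweep, varied_gas == "CH4", kij == -0.05, species == "CO2"
  )$deviation_pct)
  expect_gt(dev_own, 10 * dev_cross)
})

test_that("fitting the gas-polymer kij recovers a known value", {
  true_kij <- -0.02
  sys <- pure_gas_system(phbv8, co2, true_kij)
  obs <- tibble::tibble(
    p_MPa = c(0.5, 1.5),
    S_cm3stp_cm3_bar = vapply(p_MPa, function(p) {
      solubility_coefficient(solve_sorption(sys, p, y = 1), 1L)
    }, numeric(1))
  )
  fit <- fit_gas_polymer_kij(phbv8, co2, obs)
  expect_lt(abs(fit$kij - true_kij), 1e-4)
  # fitting to the kij = 0 prediction itself returns ~0
  sys0 <- pure_gas_system(phbv8, co2, 0)
  obs0 <- tibble::tibble(
    p_MPa = 1,
    S_cm3stp_cm3_bar = solubility_coefficient(solve_sorption(sys0, 1, y = 1), 1L)
  )
  fit0 <- fit_gas_polymer_kij(phbv8, co2, obs0)
  expect_lt(abs(fit0$kij), 1e-3)
})

test_that("mixed and ideal selectivity coincide at vanishing pressure", {
  sys2 <- sorption_system(phbv8,
    kij_gas_polymer = c(-0.002, -0.069), kij_gas_gas = -0.03
  )
  cmp <- mixed_vs_ideal_selectivity(sys2, pressures = 0.02, y_first = 0.2)
  expect_lt(abs(cmp$pct_below_ideal), 0.5)
})
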