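test_that("a single-component mixture reproduces the pure fluid", {
  mix <- sl_mixture(list(co2), 1)
  expect_equal(
    sl_mixture_density(mix, 308.15, 2, phase = "vapor"),
    sl_density(co2, 308.15, 2, phase = "vapor"),
    tolerance = 1e-12
  )
  expect_equal(mix$Tstar, co2$Tstar)
  expect_equal(mix$pstar, co2$pstar)
  expect_equal(mix$rhostar, co2$rhostar)
})

test_that("zero penetrant mass fraction gives the pure polymer density", {
  mix <- sl_mixture(list(co2, phbv8), c(0, 1))
  expect_equal(
    sl_mixture_density(mix, 308.15, 0.1),
    sl_density(phbv8, 308.15, 0.1, phase = "liquid"),
    tolerance = 1e-12
  )
})

test_that("mixture construction validates composition and kij", {
  expect_error(sl_mixture(list(co2, ch4), c(0.5, 0.4)), "sum to 1")
  expect_error(
    sl_mixture(list(co2, ch4), c(0.5, 0.5), matrix(c(0, 1, 2, 0), 2, 2)),
    "symmetric"
  )
})

test_that("chemical potential is a state function of (composition, T, p)", {
  mix_a <- sl_mixture(list(co2, phbv8), c(0.02, 0.98), -0.002)
  mix_b <- sl_mixture(list(co2, phbv8), c(0.02, 0.98), -0.002)
  expect_identical(
    sl_chemical_potential(mix_a, 308.15, 3),
    sl_chemical_potential(mix_b, 308.15, 3)
  )
})

test_that("penetrant chemical potential increases with its own mass fraction", {
  ws <- c(0.002, 0.005, 0.01, 0.02, 0.04)
  mus <- vapply(ws, function(w) {
    mix <- sl_mixture(list(co2, phbv8), c(w, 1 - w))
    sl_chemical_potential(mix, 308.15, 3, component = 1L)
  }, numeric(1))
  expect_true(all(diff(mus) > 0))
})

test_that("Gibbs-Duhem holds under a composition perturbation at fixed T, p", {
  # finite CO2/CH4 gas mixture: sum_i n_i dmu_i = 0 along any composition path
  T <- 308.15
  p <- 2
  w1 <- 0.4
  h <- 1e-6
  mu <- function(w) {
    mix <- sl_mixture(list(co2, ch4), c(w, 1 - w), -0.03)
    sl_chemical_potential(mix, T, p, phase = "vapor")
  }
  n <- c(w1 / co2$molar_mass, (1 - w1) / ch4$molar_mass) # mol per g
  dmu <- (mu(w1 + h) - mu(w1 - h)) / (2 * h)
  expect_lt(abs(sum(n * dmu)) / max(abs(n * dmu)), 1e-5)
})

test_that("dissolving CO2 swells the polymer matrix", {
  # polymer-partial density decreases as the CO2 mass fraction rises
  wg <- c(0.005, 0.01, 0.02, 0.04)
  partial <- vapply(wg, function(w) {
    mix <- sl_mixture(list(co2, phbv8), c(w, 1 - w), -0.002)
    sl_mixture_density(mix, 308.15, 3) * (1 - w)
  }, numeric(1))
  expect_true(all(diff(partial) < 0))
})

test_that("mixing rules are invariant under component relabelling", {
  k <- matrix(c(0, -0.03, -0.03, 0), 2, 2)
  m12 <- sl_mixture(list(co2, ch4), c(0.3, 0.7), k)
  m21 <- sl_mixture(list(ch4, co2), c(0.7, 0.3), k)
  expect_equal(m12$Tstar, m21$Tstar, tolerance = 1e-12)
  expect_equal(m12$pstar, m21$pstar, tolerance = 1e-12)
  expect_equal(m12$rhostar, m21$rhostar, tolerance = 1e-12)
  expect_equal(
    sl_chemical_potential(m12, 308.15, 2, phase = "vapor"),
    rev(sl_chemical_potential(m21, 308.15, 2, phase = "vapor")),
    tolerance = 1e-10
  )
})
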