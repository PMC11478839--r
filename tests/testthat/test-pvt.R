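test_that("MAPE definition: identity, hand value, permutation invariance", {
  expect_identical(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(c(1.0, 2.0), c(1.1, 1.8)), 10.0)
  set.seed(42)
  o <- runif(20, 0.5, 2)
  p <- o * (1 + rnorm(20, 0, 0.05))
  i <- sample(20)
  expect_equal(mape(o, p), mape(o[i], p[i]))
  expect_error(mape(1, c(1, 2)), "equal")
  expect_error(mape(c(0, 1), c(1, 1)), "zero")
})

test_that("R^2 definition: perfect fit, mean predictor, worked case", {
  o <- c(1.2, 1.9, 3.1)
  expect_identical(r_squared(o, o), 1)
  expect_equal(r_squared(o, rep(mean(o), 3)), 0)
  p <- c(1.0, 2.1, 3.0)
  expected <- 1 - sum((o - p)^2) / sum((o - mean(o))^2)
  expect_equal(r_squared(o, p), expected, tolerance = 1e-12)
  expect_error(r_squared(c(1, 1), c(1, 2)), "constant")
})

test_that("noiseless synthetic data returns the generating parameters", {
  pvt <- generate_pvt(phbv0, noise_sigma = 0, replicates = 1)
  fit <- fit_sl_params(pvt)
  est <- c(fit$params$Tstar, fit$params$pstar, fit$params$rhostar)
  expect_lt(max(abs(est / c(859.4, 607.4, 1.226) - 1)), 0.001)
  expect_lt(fit$mape, 1e-4)
  expect_true(fit$converged)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("the fitted MAPE never exceeds the MAPE at the initial guess", {
  pvt <- generate_pvt(phbv100, noise_sigma = 0.005, seed = 3)
  init <- sl_params(800, 550, 1.2)
  pred0 <- sl_density(init, pvt$T_K, pvt$p_MPa, phase = "liquid")
  fit <- fit_sl_params(pvt, initial = init)
  expect_lte(fit$mape, mape(pvt$rho_g_cm3, pred0))
})

test_that("fitting is invariant to row order and replicate relabelling", {
  pvt <- generate_pvt(phbv8, noise_sigma = 0.003, seed = 11)
  fit_a <- fit_sl_params(pvt)
  shuffled <- pvt[sample(nrow(pvt)), ]
  shuffled$replicate <- rev(shuffled$replicate)
  fit_b <- fit_sl_params(shuffled)
  expect_equal(tidy(fit_a)$estimate, tidy(fit_b)$estimate, tolerance = 1e-9)
})

test_that("noisy-data recovery is statistically bounded (small sweep)", {
  errs <- sapply(1:3, function(s) {
    pvt <- generate_pvt(phbv0, noise_sigma = 0.005, seed = s)
    fit <- fit_sl_params(pvt)
    c(
      rho_err = abs(fit$params$rhostar / 1.226 - 1),
      r2 = fit$r_squared
    )
  })
  expect_true(all(errs["rho_err", ] < 0.01))
  expect_true(all(errs["r2", ] >= 0.98))
})

test_that("replicate-mean fitting mode is available and close to all-points", {
  pvt <- generate_pvt(phbv0, noise_sigma = 0.005, seed = 5)
  f_pts <- fit_sl_params(pvt)
  f_mean <- fit_sl_params(pvt, replicate_mode = "means")
  expect_lt(abs(f_mean$params$rhostar / f_pts$params$rhostar - 1), 0.01)
})

test_that("tidy/glance/autoplot expose the fit in standard shapes", {
  pvt <- generate_pvt(phbv0, noise_sigma = 0, replicates = 1)
  fit <- fit_sl_params(pvt)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "unit"))
  expect_equal(td$term, c("Tstar", "pstar", "rhostar"))
  gl <- glance(fit)
  expect_named(gl, c("mape", "r_squared", "n_points", "converged", "iterations"))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("PVT round trip through disk is the identity", {
  pvt <- generate_pvt(phbv0, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pvt(pvt, path)
  back <- read_pvt(path)
  expect_equal(as.data.frame(back), as.data.frame(pvt[names(back)]),
    tolerance = 1e-15
  )
  expect_identical(nrow(back), 90L)
})

test_that("PVT reader accepts permuted headers and names unknown columns", {
  pvt <- generate_pvt(phbv0, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  perm <- pvt[c("replicate", "rho_g_cm3", "T_K", "p_MPa")]
  utils::write.csv(perm, path, row.names = FALSE)
  expect_named(read_pvt(path), c("T_K", "p_MPa", "rho_g_cm3", "replicate"))
  bad <- cbind(pvt, junk_column = 1)
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_pvt(path), "junk_column")
  writeLines("T_K,p_MPa,rho_g_cm3,replicate", path)
  expect_error(read_pvt(path), "empty")
})
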