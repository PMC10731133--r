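# Shape function fitting and the combined angle + mineralization model.

test_that("exact sin^2 profiles are recovered with negligible residual", {
  th <- seq(0, 90, by = 10)
  M <- 16 + 8 * sin(th * pi / 180)^2
  sf <- fit_shape_function(th, M)
  expect_equal(unname(sf$coefficients[["sin2"]]), 1, tolerance = 1e-9)
  expect_lt(sf$residual_rms, 1e-9)
  expect_equal(eval_shape(sf, 0), 0, tolerance = 1e-12)
  expect_equal(eval_shape(sf, 90), 1, tolerance = 1e-12)
})

test_that("insufficient or non-spanning grids are rejected", {
  expect_error(fit_shape_function(c(0, 90), c(16, 24)), "at least 5")
  expect_error(fit_shape_function(seq(10, 90, by = 10),
                                  seq(16, 24, length.out = 9)), "span")
})

test_that("shape fit of the module's own modulus profile is self-consistent", {
  prof <- indentation_modulus_profile(elastic_constants(),
                                      theta = seq(0, 90, by = 10))
  sf <- fit_shape_function(prof$theta, prof$modulus)
  expect_lt(sf$residual_rms, 0.01)       # < 1 percent of M(90) - M(0)
  f_grid <- eval_shape(sf, 0:90)
  expect_true(all(diff(f_grid) >= -1e-9))
  expect_equal(f_grid[1], 0, tolerance = 1e-9)
  expect_equal(f_grid[91], 1, tolerance = 1e-9)
})

test_that("noise-free combined-model recovery is exact", {
  sf <- fit_shape_function(seq(0, 90, by = 10),
                           16 + 8 * sin(seq(0, 90, by = 10) * pi / 180)^2)
  set.seed(3)
  th <- runif(23, 0, 90); dbm <- runif(23, 2, 4)
  sites <- data.frame(E_ind = 5 + 2 * dbm + 8 * eval_shape(sf, th),
                      theta = th, dbm = dbm)
  fit <- suppressWarnings(fit_combined_model(sites, sf))
  expect_equal(fit$alpha, 5, tolerance = 1e-6)
  expect_equal(fit$beta, 2, tolerance = 1e-6)
  expect_equal(fit$deltaE, 8, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lte(fit$adj_r_squared, fit$r_squared)
})

test_that("predictions satisfy the f(0) = 0 / f(90) = 1 identities", {
  sf <- fit_shape_function(seq(0, 90, by = 15),
                           16 + 6 * sin(seq(0, 90, by = 15) * pi / 180)^2)
  set.seed(4)
  th <- runif(12, 0, 90); dbm <- runif(12, 2, 4)
  sites <- data.frame(
    E_ind = 4 + 3 * dbm + 6 * eval_shape(sf, th) + rnorm(12, 0, 0.5),
    theta = th, dbm = dbm)
  fit <- fit_combined_model(sites, sf)
  expect_equal(predict_indentation_modulus(fit, 0, 3),
               fit$alpha + 3 * fit$beta, tolerance = 1e-12)
  expect_equal(predict_indentation_modulus(fit, 90, 3),
               fit$alpha + 3 * fit$beta + fit$deltaE, tolerance = 1e-12)
  # OLS identity: prediction at a fitted site = observed - residual
  pred <- predict_indentation_modulus(fit, sites$theta, sites$dbm)
  expect_equal(pred, sites$E_ind - residuals(fit$lm_fit),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(predict_indentation_modulus(fit, 120, 3), "\\[0, 90\\]")
})

test_that("rank-deficient designs are rejected naming the columns", {
  sf <- fit_shape_function(seq(0, 90, by = 15),
                           16 + 6 * sin(seq(0, 90, by = 15) * pi / 180)^2)
  sites <- data.frame(E_ind = rnorm(10, 20), theta = runif(10, 0, 90),
                      dbm = 3)
  expect_error(fit_combined_model(sites, sf), "collinear.*dbm")
})

test_that("interaction p-value is calibrated under a non-interacting truth", {
  sf <- fit_shape_function(seq(0, 90, by = 15),
                           16 + 6 * sin(seq(0, 90, by = 15) * pi / 180)^2)
  set.seed(11)
  pvals <- replicate(150, {
    th <- runif(23, 0, 90); dbm <- runif(23, 2, 4)
    sites <- data.frame(
      E_ind = 5 + 2 * dbm + 8 * eval_shape(sf, th) + rnorm(23, 0, 1.5),
      theta = th, dbm = dbm)
    fit <- fit_combined_model(sites, sf, include_interaction = TRUE)
    unname(fit$p_values[["dbm:f"]])
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.005)
})
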