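# qPRS: baseline correction, band fitting, orientation and DBM.

wn <- seq(800, 1800, by = 1)

test_that("pure quadratic baselines are removed essentially exactly", {
  y <- 40 + 0.02 * (wn - 1300) + 1e-5 * (wn - 1300)^2
  out <- subtract_baseline(wn, y)
  expect_lt(max(abs(out$intensity)), 1e-6 * max(abs(y)))
  # flat zero baseline: identity transform
  out0 <- subtract_baseline(wn, rep(0, length(wn)))
  expect_lt(max(abs(out0$intensity)), 1e-9)
})

test_that("peak area survives baseline subtraction within 2 percent", {
  A <- 400; hw <- 10
  peak <- A / (pi * hw) * hw^2 / ((wn - 960)^2 + hw^2)
  y <- 30 + 0.01 * (wn - 1300) + 2e-5 * (wn - 1300)^2 + peak
  out <- subtract_baseline(wn, y)
  fit <- fit_bands(wn, out$intensity)
  expect_equal(fit$v1po4$area, A, tolerance = 0.02)
})

test_that("Lorentzian band areas are recovered from exact superpositions", {
  hw <- 12; A1 <- 300; A2 <- 450
  y <- A1 / (pi * hw) * hw^2 / ((wn - 1638)^2 + hw^2) +
    A2 / (pi * hw) * hw^2 / ((wn - 1670)^2 + hw^2)
  y[wn < 1500] <- 0  # compact support: the phosphate window is truly empty
  fit <- fit_bands(wn, y)
  expect_equal(fit$amide1$area, A1 + A2, tolerance = 0.02)
  expect_false(fit$amide1$flagged)
  # zero-intensity window is flagged with zero area
  expect_true(fit$v1po4$flagged)
  expect_equal(fit$v1po4$area, 0)
})

test_that("orientation maps ratios through the calibration exactly", {
  cal <- raman_calibration()
  r30 <- cal$inverse(30)
  fits <- fake_fits(a1 = rep(100 * r30, 13), a3 = rep(100, 13),
                    apo = rep(300, 13))
  expect_equal(compute_orientation(fits, cal), 30, tolerance = 1e-6)
  # below-domain ratio clamps to 0 with a warning
  lowf <- fake_fits(a1 = rep(50, 13), a3 = rep(100, 13), apo = rep(1, 13))
  expect_warning(th <- compute_orientation(lowf, cal), "clamped")
  expect_equal(th, 0)
  # non-positive amide III is an error
  badf <- fake_fits(a1 = rep(100, 13), a3 = rep(0, 13), apo = rep(1, 13))
  expect_error(compute_orientation(badf, cal), "amide III")
})

test_that("DBM is the polarization-average of the area ratio", {
  expect_equal(compute_dbm(fake_fits(rep(100, 13), rep(50, 13),
                                     rep(300, 13))), 3)
  alt <- fake_fits(rep(100, 12), rep(50, 12),
                   rep(c(200, 400), 6))
  expect_equal(compute_dbm(alt), 3)
  mixed <- fake_fits(c(rep(100, 12), 0), rep(50, 13), rep(300, 13))
  expect_warning(v <- compute_dbm(mixed), "excluded")
  expect_equal(v, 3)
  allbad <- fake_fits(rep(0, 13), rep(50, 13), rep(300, 13))
  expect_error(compute_dbm(allbad), "every polarization")
})

test_that("line-scan summaries are the sample mean and SD over positions", {
  th <- seq(30, 60, by = 5)
  s <- summarize_linescan(th, rep(3, 7))
  expect_equal(s$theta_mean, 45)
  expect_equal(s$theta_sd, sqrt(700 / 6), tolerance = 1e-12)
  s2 <- summarize_linescan(rep(40, 5), rep(3, 5))
  expect_equal(s2$theta_sd, 0)
  expect_warning(s3 <- summarize_linescan(40, 3), "single position")
  expect_true(s3$flagged && is.na(s3$theta_sd))
})

test_that("full-spectrum zero-noise round trip is exact", {
  sc <- generate_polarized_scan(30, 3.0, positions = 2, seed = 1)
  res <- analyze_polarized_scan(sc)
  expect_equal(res$theta_mean, 30, tolerance = 1e-6)
  expect_equal(res$dbm, 3.0, tolerance = 1e-6)
})

test_that("orientation is invariant to a global intensity scale", {
  sc <- generate_polarized_scan(55, 2.8, positions = 1, seed = 9)
  sc2 <- sc
  for (a in seq_along(sc2$positions[[1]]$spectra)) {
    sc2$positions[[1]]$spectra[[a]]$intensity <-
      4 * sc2$positions[[1]]$spectra[[a]]$intensity
  }
  r1 <- suppressWarnings(analyze_polarized_scan(sc))
  r2 <- suppressWarnings(analyze_polarized_scan(sc2))
  expect_equal(r2$theta_mean, r1$theta_mean, tolerance = 1e-6)
  expect_equal(r2$dbm, r1$dbm, tolerance = 1e-6)
})

test_that("DBM is invariant to the quadratic baseline used", {
  r1 <- suppressWarnings(analyze_polarized_scan(
    generate_polarized_scan(45, 3.1, positions = 1,
                            baseline = c(50, 20, 30), seed = 5)))
  r2 <- suppressWarnings(analyze_polarized_scan(
    generate_polarized_scan(45, 3.1, positions = 1,
                            baseline = c(200, -40, 80), seed = 5)))
  expect_equal(r1$dbm, r2$dbm, tolerance = 1e-6)
  expect_equal(r1$theta_mean, r2$theta_mean, tolerance = 1e-6)
})

test_that("amide III is polarization-independent while amide I is modulated", {
  sc <- generate_polarized_scan(40, 3, positions = 1, seed = 2)
  fits <- lapply(sc$positions[[1]]$spectra, function(sp) {
    corr <- subtract_baseline(sc$wavenumber, sp$intensity)
    fit_bands(sc$wavenumber, corr$intensity)
  })
  a3 <- vapply(fits, function(f) f$amide3$area, numeric(1))
  a1 <- vapply(fits, function(f) f$amide1$area, numeric(1))
  expect_lt(diff(range(a3)) / mean(a3), 0.01)
  expect_gt(diff(range(a1)) / mean(a1), 0.3)  # kappa = 0.8 modulation
})
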