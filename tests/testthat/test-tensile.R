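# Microtensile conversion and property extraction.

test_that("stress and strain conversion is exact unit arithmetic", {
  geom <- list(width = 5, thickness = 2, length = 10)
  cv <- compute_stress_strain(force = c(0, 10), displacement = c(0, 100),
                              geometry = geom)
  expect_equal(cv$data$stress[2], 1.0)    # 10 uN / 10 um^2 = 1 MPa
  expect_equal(cv$data$strain[2], 0.01)   # 100 nm / 10 um
  expect_error(compute_stress_strain(1, 1, list(width = 0, thickness = 2,
                                                length = 10)),
               "area")
})

test_that("generator raw channels round-trip through the conversion", {
  tc <- generate_tensile_curve(15, 240, seed = 1)
  back <- compute_stress_strain(tc$raw$force, tc$raw$displacement,
                                tc$geometry, time = tc$raw$time)
  expect_equal(back$data$stress, tc$data$stress, tolerance = 1e-9)
  expect_equal(back$data$strain, tc$data$strain, tolerance = 1e-9)
})

test_that("a perfect linear ramp recovers its slope exactly", {
  strain <- seq(0, 0.02, by = 5e-5)
  stress <- 15000 * strain  # 15 GPa in MPa/strain
  curve <- structure(list(
    data = data.frame(time = seq_along(strain), strain = strain,
                      stress = stress),
    geometry = list(width = 5, thickness = 2, length = 10), id = "lin"),
    class = "tensile_curve")
  r <- extract_tensile_properties(curve)
  expect_equal(r$E_loading, 15, tolerance = 1e-9)
  expect_equal(r$sigma_ult, max(stress))
  expect_false(r$failure_detected)
  expect_equal(r$failure_class, "brittle")
})

test_that("bilinear curves return the larger slope (brute-force oracle)", {
  strain <- seq(0, 0.02, by = 5e-5)
  stress <- ifelse(strain <= 0.01, 20000 * strain,
                   200 + 5000 * (strain - 0.01))
  curve <- structure(list(
    data = data.frame(time = seq_along(strain), strain = strain,
                      stress = stress),
    geometry = list(width = 5, thickness = 2, length = 10), id = "bi"),
    class = "tensile_curve")
  r <- extract_tensile_properties(curve, slope_window = 0.002)
  oracle <- brute_force_max_slope(strain, stress, window = 0.002)
  expect_equal(r$E_loading, 20, tolerance = 1e-6)
  expect_equal(r$E_loading * 1000, oracle, tolerance = 1e-6)
})

test_that("extraction scales linearly with stress and survives resampling", {
  tc <- generate_tensile_curve(15, 240, seed = 2)
  r1 <- extract_tensile_properties(tc)
  tc2 <- tc
  tc2$data$stress <- 3 * tc2$data$stress
  r2 <- extract_tensile_properties(tc2)
  expect_equal(r2$E_loading, 3 * r1$E_loading, tolerance = 1e-12)
  expect_equal(r2$sigma_ult, 3 * r1$sigma_ult, tolerance = 1e-12)
  # uniform time resampling: regenerate at a higher sampling rate
  tc3 <- generate_tensile_curve(15, 240, sample_rate = 25, seed = 2)
  r3 <- extract_tensile_properties(tc3)
  expect_equal(r3$E_loading, r1$E_loading, tolerance = 5e-3)
})

test_that("sigma_ult always equals the pre-failure stress maximum", {
  set.seed(5)
  for (i in 1:10) {
    tc <- generate_tensile_curve(runif(1, 10, 25), runif(1, 150, 450),
                                 ductile = i %% 2 == 0,
                                 noise = list(force = 5, displacement = 2))
    r <- extract_tensile_properties(tc)
    d <- tc$data
    runmax <- cummax(d$stress)
    fail_i <- which(d$stress < 0.5 * runmax &
                      runmax > 0.05 * max(d$stress))[1]
    load_idx <- seq_len(max(fail_i - 1, 2))
    expect_equal(r$sigma_ult, max(d$stress[load_idx]))
    expect_gte(r$eps_fail, r$eps_ult)
  }
})

test_that("failure classification respects the ductility threshold", {
  mk <- function(ratio) list(eps_ult = 0.02, eps_fail = 0.02 * ratio)
  expect_equal(classify_failure(mk(1.0)), "brittle")
  expect_equal(classify_failure(mk(1.2)), "ductile")
  expect_equal(classify_failure(mk(1.04)), "brittle")
  expect_equal(classify_failure(mk(1.04), threshold = 0.02), "ductile")
})

test_that("ductile generator curves carry the configured strain excess", {
  tc <- generate_tensile_curve(15, 240, ductile = TRUE, tail_factor = 1.2,
                               seed = 3)
  r <- extract_tensile_properties(tc)
  expect_equal(r$eps_fail / r$eps_ult, 1.2, tolerance = 1e-6)
  expect_equal(r$failure_class, "ductile")
})

test_that("healthy-like specimen set recovers the configured group mean", {
  set.seed(17)
  E <- rnorm(8, 14.8, 1.8)
  got <- vapply(E, function(e) {
    extract_tensile_properties(
      generate_tensile_curve(e, 242))$E_loading
  }, numeric(1))
  expect_lt(abs(mean(got) - 14.8), 3 * 1.8 / sqrt(8))
})
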