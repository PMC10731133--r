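# Synthetic cohort generator: validation, determinism, distributions.

test_that("invalid configurations are rejected", {
  g <- reference_cohort_params()
  g$fst_axial[1] <- 0.9
  expect_error(cohort_config(groups = g), "sum to 1")
  g2 <- reference_cohort_params()
  g2$E_ind_sd[2] <- -1
  expect_error(cohort_config(groups = g2), ">= 0")
  g3 <- reference_cohort_params()
  g3$n_sites[1] <- 0L
  expect_error(cohort_config(groups = g3), "sites per biopsy")
})

test_that("identical seeds give identical datasets", {
  g <- one_group_spec(3)
  d1 <- generate_cohort(cohort_config(groups = g, seed = 5), level = "raw")
  d2 <- generate_cohort(cohort_config(groups = g, seed = 5), level = "raw")
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$raw$sites[[1]]$tensile$data,
                   d2$raw$sites[[1]]$tensile$data)
  expect_identical(d1$raw$sites[[2]]$raman$positions[[1]]$spectra[[3]],
                   d2$raw$sites[[2]]$raman$positions[[1]]$spectra[[3]])
  d3 <- generate_cohort(cohort_config(groups = g, seed = 6))
  expect_false(identical(d1$sites$E_ind_true, d3$sites$E_ind_true))
})

test_that("all-zero SDs collapse every site onto the group mean", {
  g <- one_group_spec(6)
  for (col in grep("_sd$", names(g), value = TRUE)) g[[col]] <- 0
  g$fst_axial <- 1; g$fst_mixed <- 0; g$fst_transversal <- 0
  cfg <- cohort_config(groups = g, seed = 1,
                       coupling = list(resid_floor_frac = 0))
  s <- generate_cohort(cfg)$sites
  expect_equal(s$E_ind_true, rep(g$E_ind_mean, 6), tolerance = 1e-9)
  expect_equal(s$E_loading_true, rep(g$E_loading_mean, 6), tolerance = 1e-9)
  expect_equal(s$sigma_ult_true, rep(g$sigma_ult_mean, 6), tolerance = 1e-9)
  expect_equal(s$dbm_true, rep(g$dbm_mean, 6), tolerance = 1e-9)
  expect_equal(s$theta_true, rep(g$theta_mean, 6), tolerance = 1e-9)
})

test_that("group sample means land within 3 SE of the configured means", {
  s <- generate_cohort(cohort_config(groups = one_group_spec(200),
                                     seed = 21))$sites
  g <- one_group_spec(200)
  for (p in c("E_ind", "E_loading", "sigma_ult", "dbm", "H_IT")) {
    m <- mean(s[[paste0(p, "_true")]])
    mu <- g[[paste0(p, "_mean")]]
    se <- g[[paste0(p, "_sd")]] / sqrt(200)
    expect_lt(abs(m - mu), 3 * se)
  }
  expect_true(all(s$theta_true >= 0 & s$theta_true <= 90))
  expect_true(all(s$dbm_true > 0))
})

test_that("a healthy-like reference cohort recovers Table-level E_ind", {
  s <- generate_cohort(cohort_config(seed = 31))$sites
  h <- s[s$group == "healthy", ]
  expect_equal(nrow(h), 8)
  expect_lt(abs(mean(h$E_ind_true) - 17.2), 3 * 2.2 / sqrt(8))
})

test_that("tensile generator rejects non-positive inputs", {
  expect_error(generate_tensile_curve(-1, 240), "positive")
  expect_error(generate_tensile_curve(15, 0), "positive")
  expect_error(generate_polarized_scan(120, 3), "\\[0, 90\\]")
  expect_error(generate_indentation_curve(-5, 500))
  expect_error(generate_microct_volume(-10))
})

test_that("noisy tensile records recover the ultimate stress to 2 percent", {
  # force noise of 20 uN on a 10 um^2 section = 2 MPa stress noise;
  # the max-statistic is slightly upward biased, so accuracy not
  # unbiasedness is asserted
  set.seed(41)
  got <- replicate(50, {
    tc <- generate_tensile_curve(15, 240, noise = list(force = 20,
                                                       displacement = 0))
    extract_tensile_properties(tc)$sigma_ult
  })
  expect_lt(abs(mean(got) - 240) / 240, 0.02)
  expect_gte(mean(got), 240)  # extreme-value bias is non-negative
})

test_that("raw bundles are internally consistent with the site truths", {
  g <- one_group_spec(2)
  ds <- generate_cohort(cohort_config(groups = g, seed = 8,
                                      noise = list(force = 0,
                                                   displacement = 0,
                                                   spectral = 0,
                                                   depth = 0, load = 0,
                                                   density = 0)),
                        level = "raw")
  s <- ds$sites[1, ]
  r <- extract_tensile_properties(ds$raw$sites[[1]]$tensile)
  expect_equal(r$E_loading, s$E_loading_true, tolerance = 1e-6)
  expect_equal(r$sigma_ult, s$sigma_ult_true, tolerance = 1e-6)
  ram <- analyze_polarized_scan(ds$raw$sites[[1]]$raman)
  expect_equal(ram$theta_mean, mean(ds$raw$sites[[1]]$raman$truth$theta_positions),
               tolerance = 1e-6)
  expect_equal(ram$dbm, s$dbm_true, tolerance = 1e-6)
  vol <- ds$raw$volumes[[1]]
  tmd <- compute_tmd(calibrate_volume(vol$grey, vol$calibration[["slope"]],
                                      vol$calibration[["intercept"]],
                                      mask = vol$mask))
  expect_equal(as.numeric(tmd), ds$biopsies$tmd_true[1], tolerance = 1e-9)
})
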