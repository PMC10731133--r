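# Multilinear tensile models, mixed-model LRT, Dunn-Holm, loading modes.

test_that("noise-free multilinear tensile model is recovered exactly", {
  set.seed(2)
  fst <- rep(c("axial", "mixed", "transversal"), each = 8)
  tmd <- runif(24, 850, 1000)
  alpha <- c(axial = 18, mixed = 15, transversal = 12)
  sites <- data.frame(value = alpha[fst] + 0.01 * tmd, fst = fst, tmd = tmd)
  fit <- suppressWarnings(fit_tensile_model(sites))
  expect_equal(unname(fit$alpha[names(alpha)]), unname(alpha),
               tolerance = 1e-9)
  expect_equal(fit$beta, 0.01, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lte(fit$adj_r_squared, fit$r_squared)
})

test_that("degenerate tensile designs are handled as specified", {
  sites <- data.frame(value = rnorm(8, 15), fst = "axial",
                      tmd = runif(8, 850, 1000))
  expect_error(fit_tensile_model(sites), "two FST levels")
  sites2 <- data.frame(value = rnorm(8, 15),
                       fst = rep(c("axial", "mixed"), 4), tmd = 900)
  expect_warning(fit <- fit_tensile_model(sites2), "constant")
  expect_true(is.na(fit$beta))
})

test_that("permuted responses have near-zero adjusted R2", {
  set.seed(6)
  fst <- rep(c("axial", "mixed", "transversal"), c(9, 7, 7))
  tmd <- rep(c(870, 990, 980), c(8, 7, 8))
  alpha <- c(axial = 18, mixed = 15, transversal = 12)
  n_low <- 0
  for (i in 1:40) {
    y <- alpha[fst] + 0.01 * tmd + rnorm(23, 0, 2)
    fit <- fit_tensile_model(data.frame(value = sample(y), fst = fst,
                                        tmd = tmd))
    if (fit$adj_r_squared <= 0.1) n_low <- n_low + 1
  }
  expect_gte(n_low, 38 * 0.9)
})

test_that("strength-modulus correlation handles exact and null cases", {
  d <- data.frame(E_loading = 1:10, sigma_ult = 3 + 2 * (1:10))
  r <- suppressWarnings(correlate_strength_modulus(d))
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_error(correlate_strength_modulus(
    data.frame(E_loading = rep(1, 5), sigma_ult = rnorm(5))), "variance")
  set.seed(9)
  r2s <- replicate(100, correlate_strength_modulus(data.frame(
    E_loading = rnorm(23), sigma_ult = rnorm(23)))$r_squared)
  expect_gte(mean(r2s < 0.2), 0.9)
})

test_that("with zero biopsy variance the LRT agrees with plain fixed effects", {
  set.seed(12)
  group <- rep(c("a", "b", "c"), each = 16)
  biopsy <- rep(sprintf("b%02d", 1:12), each = 4)
  y <- c(a = 0, b = 2, c = 4)[group] + rnorm(48)  # no biopsy effect
  g <- suppressWarnings(lrt_group_effect(y, group, biopsy))
  expect_equal(g$df, 2)
  # the full model should find (essentially) no biopsy variance
  vc <- as.data.frame(lme4::VarCorr(g$fit_full))
  expect_lt(vc$vcov[vc$grp == "biopsy"], 0.2)
  # conclusion agrees with the one-way fixed-effects comparison; the
  # mixed LRT is more conservative because the null's biopsy intercepts
  # (nested in groups) can absorb part of the group contrast
  f_p <- anova(lm(y ~ group))$`Pr(>F)`[1]
  expect_lt(g$p_value, 1e-4)
  expect_lt(f_p, 1e-4)
  l1 <- logLik(lm(y ~ group)); l0 <- logLik(lm(y ~ 1))
  expect_lte(g$lrt_stat, as.numeric(2 * (l1 - l0)) + 1e-6)
})

test_that("a large group shift is detected with very small p", {
  set.seed(13)
  for (i in 1:5) {
    group <- rep(c("a", "b", "c"), each = 32)
    biopsy <- rep(sprintf("b%02d", 1:24), each = 4)
    y <- rnorm(96, 0, 1) + 0.5 * rnorm(24)[as.integer(factor(biopsy))] +
      c(a = 0, b = 0, c = 3)[group]
    g <- suppressWarnings(lrt_group_effect(y, group, biopsy))
    expect_lt(g$p_value, 1e-3)
  }
})

test_that("the single-biopsy-per-group design warns about confounding", {
  set.seed(14)
  group <- rep(c("a", "b", "c"), each = 8)
  expect_warning(lrt_group_effect(rnorm(24), group, group), "confounded")
})

test_that("Dunn two-group statistic attains the exhaustive-rank extreme", {
  d <- dunn_posthoc(c(1, 2, 3, 10, 11, 12), rep(c("g1", "g2"), each = 3))
  # closed form for fully separated ranks: z = 3 / sqrt(7/3)
  expect_equal(abs(d$z), 3 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(d$p_raw, 2 * pnorm(-3 / sqrt(7 / 3)), tolerance = 1e-12)
  # exhaustive enumeration over all C(6,3) labelings: the observed
  # assignment maximizes |z|, so its p is the smallest attainable
  vals <- c(1, 2, 3, 10, 11, 12)
  zs <- apply(utils::combn(6, 3), 2, function(idx) {
    lab <- rep("g2", 6); lab[idx] <- "g1"
    abs(dunn_posthoc(vals, lab)$z)
  })
  expect_equal(max(zs), abs(d$z), tolerance = 1e-12)
  expect_equal(min(2 * pnorm(-zs)), d$p_raw, tolerance = 1e-12)
})

test_that("Holm adjustment matches the step-down definition", {
  p <- c(0.01, 0.04, 0.03)
  expect_equal(p.adjust(p, "holm"), holm_oracle(p))
  expect_equal(holm_oracle(p), c(0.03, 0.06, 0.06))
  set.seed(15)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1))
    expect_equal(p.adjust(p, "holm"), holm_oracle(p))
  }
})

test_that("adjusted p never falls below raw p and preserves ordering", {
  set.seed(16)
  for (i in 1:20) {
    y <- rnorm(30)
    g <- sample(rep(c("a", "b", "c"), 10))
    d <- dunn_posthoc(y, g)
    expect_true(all(d$p_adjusted >= d$p_raw - 1e-15))
    o <- order(d$p_raw)
    expect_true(all(diff(d$p_adjusted[o]) >= -1e-15))
  }
})

test_that("Dunn-Holm controls the family-wise error under the null", {
  set.seed(18)
  any_sig <- replicate(100, {
    y <- rnorm(30)
    g <- rep(c("a", "b", "c"), 10)
    any(dunn_posthoc(y, g)$p_adjusted < 0.05)
  })
  expect_lte(mean(any_sig), 0.10)
})

test_that("tied data are handled by the tie correction with a warning", {
  y <- c(1, 1, 2, 2, 3, 3, 1, 1, 2)
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_posthoc(y, g)
  expect_true(all(is.finite(d$z)))
  expect_warning(dunn_posthoc(rep(1, 9), g), "tied")
})

test_that("loading-mode relative changes follow the reporting convention", {
  tension <- data.frame(property = "strength", group = "healthy",
                        mean = 242)
  compression <- data.frame(property = "strength", group = "healthy",
                            type = "ultimate", mean = 584)
  out <- loading_mode_comparison(tension, compression)
  expect_equal(out$relative_change_rounded, -58.6)
  # equality gives exactly zero
  eq <- loading_mode_comparison(
    data.frame(property = "x", group = "g", mean = 5),
    data.frame(property = "x", group = "g", type = "ultimate", mean = 5))
  expect_equal(eq$relative_change_rounded, 0)
  # zero compression mean is flagged undefined
  z <- loading_mode_comparison(
    data.frame(property = "x", group = "g", mean = 5),
    data.frame(property = "x", group = "g", type = "ultimate", mean = 0))
  expect_true(z$undefined)
  expect_true(is.na(z$relative_change))
})

test_that("report rounding is half-away-from-zero at one decimal", {
  expect_equal(round_half_away(-58.55, 1), -58.6)
  expect_equal(round_half_away(15.85, 1), 15.9)
  expect_equal(round_half_away(-4.3478, 1), -4.3)
  expect_equal(round_half_away(0.25, 1), 0.3)
})
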