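# Group statistics and the multilinear tensile-property models.
#
# Tensile model (cell-means coding): value = alpha_FST + beta * TMD + eps,
# with FST a three-level factor (axial / mixed / transversal) and TMD the
# biopsy tissue mineral density. Group differences use a random-intercept
# mixed model value ~ group + (1 | biopsy), ML-fitted, with a likelihood
# ratio test against the no-group model, followed by Dunn's rank-based
# pairwise post hoc test with Bonferroni-Holm adjustment.

fst_levels <- c("axial", "mixed", "transversal")

#' Multilinear tensile-property model
#'
#' Least-squares fit of a tensile property on the fracture surface type
#' (categorical, cell-means coding: one level effect per FST, no separate
#' intercept) and tissue mineral density (continuous):
#' `value = alpha_FST + beta * TMD + eps`. R2 and the F statistic are
#' computed against the grand-mean null model.
#'
#' @param sites data frame with columns `value`, `fst` and `tmd`.
#' @return object of class `tensile_model_fit`: `alpha` (named level
#'   effects, value units at TMD = 0), `beta` (value units per mgHA/cm3,
#'   NA if TMD was constant and dropped), `sigma` residual SD,
#'   `r_squared`, `adj_r_squared`, `f_p_value`, `n`.
#' @export
fit_tensile_model <- function(sites) {
  stopifnot(all(c("value", "fst", "tmd") %in% names(sites)))
  sites <- sites[complete.cases(sites[c("value", "fst", "tmd")]), ]
  f <- factor(as.character(sites$fst), levels = fst_levels)
  f <- droplevels(f)
  if (nlevels(f) < 2) stop("at least two FST levels are required")
  if (nrow(sites) < 5) stop("at least 5 sites are required")
  tmd_constant <- var(sites$tmd) < 1e-12
  if (tmd_constant) {
    warning("TMD is constant; the TMD column was dropped from the model")
    fit <- lm(value ~ 0 + f, data = data.frame(value = sites$value, f = f))
  } else {
    fit <- lm(value ~ 0 + f + tmd,
              data = data.frame(value = sites$value, f = f, tmd = sites$tmd))
  }
  y <- sites$value
  n <- length(y)
  p <- length(coef(fit))
  sse <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  fnum <- (sst - sse) / (p - 1)
  fden <- sse / (n - p)
  fp <- pf(fnum / fden, p - 1, n - p, lower.tail = FALSE)
  cf <- coef(fit)
  alpha <- cf[grep("^f", names(cf))]
  names(alpha) <- sub("^f", "", names(alpha))
  structure(list(
    alpha = alpha,
    beta = if (tmd_constant) NA_real_ else unname(cf["tmd"]),
    sigma = sqrt(sse / (n - p)),
    r_squared = r2, adj_r_squared = adj, f_p_value = fp,
    n = n, lm_fit = fit
  ), class = "tensile_model_fit")
}

#' @export
print.tensile_model_fit <- function(x, ...) {
  cat("Multilinear tensile model value = alpha_FST + beta*TMD + eps\n")
  for (l in names(x$alpha)) {
    cat(sprintf("  alpha[%s] = %.4g\n", l, x$alpha[[l]]))
  }
  cat(sprintf("  beta = %.4g per mgHA/cm3, residual SD = %.4g\n",
              x$beta, x$sigma))
  cat(sprintf("  R2 = %.3f, adj R2 = %.3f, F p = %.3g, n = %d\n",
              x$r_squared, x$adj_r_squared, x$f_p_value, x$n))
  invisible(x)
}

#' Strength-modulus correlation
#'
#' Univariate least squares of ultimate stress on loading modulus.
#'
#' @param sites data frame with columns `sigma_ult` (MPa) and `E_loading`
#'   (GPa).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
correlate_strength_modulus <- function(sites) {
  stopifnot(all(c("sigma_ult", "E_loading") %in% names(sites)))
  sites <- sites[complete.cases(sites[c("sigma_ult", "E_loading")]), ]
  if (nrow(sites) < 3) stop("at least 3 sites are required")
  if (var(sites$E_loading) < 1e-12) stop("zero variance in the predictor")
  fit <- lm(sigma_ult ~ E_loading, data = sites)
  sm <- summary(fit)
  list(slope = unname(coef(fit)["E_loading"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["E_loading", "Pr(>|t|)"],
       n = nrow(sites))
}

#' Likelihood-ratio test for a group effect with biopsy random intercepts
#'
#' Fits the random-intercept mixed models `value ~ group + (1 | biopsy)`
#' and `value ~ 1 + (1 | biopsy)` by maximum likelihood (not REML, so the
#' likelihoods of the nested fixed-effect structures are comparable) and
#' reports the likelihood ratio statistic with a chi-square reference on
#' `groups - 1` degrees of freedom.
#'
#' A design in which every group contains a single biopsy confounds the
#' group effect with the biopsy random effect; such degenerate designs are
#' accepted with a loud warning.
#'
#' @param value numeric response per site.
#' @param group group label per site.
#' @param biopsy biopsy label per site.
#' @return object of class `group_comparison`: `lrt_stat`, `df`,
#'   `p_value`, `n_groups`, `descriptives` (per-group mean/SD/n),
#'   `degenerate`.
#' @export
lrt_group_effect <- function(value, group, biopsy) {
  stopifnot(length(value) == length(group), length(value) == length(biopsy))
  group <- factor(group)
  biopsy <- factor(biopsy)
  if (nlevels(group) < 2) stop("at least two groups are required")
  degenerate <- all(tapply(biopsy, group, function(b) length(unique(b))) == 1)
  if (degenerate) {
    warning(paste(
      "each group contains a single biopsy: the group fixed effect is",
      "confounded with the biopsy random effect; interpret with caution"))
  }
  d <- data.frame(value = value, group = group, biopsy = biopsy)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- lme4::lmer(value ~ group + (1 | biopsy), data = d,
                     REML = FALSE, control = ctrl)
  null <- lme4::lmer(value ~ 1 + (1 | biopsy), data = d,
                     REML = FALSE, control = ctrl)
  stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  df <- nlevels(group) - 1
  desc <- do.call(rbind, lapply(levels(group), function(g) {
    v <- value[group == g]
    data.frame(group = g, mean = mean(v), sd = sd(v), n = length(v))
  }))
  structure(list(lrt_stat = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 n_groups = nlevels(group),
                 descriptives = desc,
                 degenerate = degenerate,
                 fit_full = full, fit_null = null),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mixed-model LRT: chi2(%d) = %.3f, p = %.3g%s\n",
              x$df, x$lrt_stat, x$p_value,
              if (x$degenerate) " [degenerate design]" else ""))
  print(x$descriptives, row.names = FALSE)
  invisible(x)
}

#' Dunn's rank-based pairwise post hoc test with Holm adjustment
#'
#' All pairwise two-sided comparisons on the joint ranks with tie
#' correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`,
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups, followed by the
#' Bonferroni-Holm step-down adjustment.
#'
#' @param value numeric response.
#' @param group group label per observation (>= 2 groups, each n >= 2).
#' @return data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(value, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("at least two groups are required")
  ns <- table(group)
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  N <- length(value)
  r <- rank(value)
  ties <- table(value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  if (tie_term > 0 && any(ties == N)) {
    warning("all values tied; comparisons are degenerate")
  }
  rbar <- tapply(r, group, mean)
  pairs <- utils::combn(levels(group), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p_raw = res["p", ])
  out$p_adjusted <- p.adjust(out$p_raw, method = "holm")
  rownames(out) <- NULL
  out
}

#' Tension-vs-compression comparison table
#'
#' Relative change of matched group/property summary means between the
#' two loading modes: `100 * (tension - compression) / compression`, with
#' the one-decimal half-away-from-zero rounding used for report tables.
#' A zero compression mean yields an NA cell flagged in `undefined`.
#'
#' @param tension,compression data frames with columns `property`,
#'   `group`, `type` and `mean` (see
#'   [reference_loading_mode_means()]). Tension rows are matched to
#'   every compression row of the same property and group.
#' @return data frame with columns `property`, `group`, `type`,
#'   `tension`, `compression`, `relative_change` (percent, unrounded),
#'   `relative_change_rounded` and `undefined`.
#' @export
loading_mode_comparison <- function(tension, compression) {
  need <- c("property", "group", "mean")
  stopifnot(all(need %in% names(tension)), all(need %in% names(compression)))
  if (is.null(compression$type)) compression$type <- "ultimate"
  out <- merge(
    compression[c("property", "group", "type", "mean")],
    tension[c("property", "group", "mean")],
    by = c("property", "group"),
    suffixes = c("_compression", "_tension"))
  if (!nrow(out)) stop("no matched group/property entries")
  undefined <- out$mean_compression == 0
  rel <- ifelse(undefined, NA_real_,
                100 * (out$mean_tension - out$mean_compression) /
                  out$mean_compression)
  data.frame(property = out$property, group = out$group, type = out$type,
             tension = out$mean_tension, compression = out$mean_compression,
             relative_change = rel,
             relative_change_rounded = round_half_away(rel, 1),
             undefined = undefined)
}
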