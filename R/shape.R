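# Shape function f(theta) of the transverse isotropic indentation tensor,
# and the combined fiber-angle + mineralization model of the indentation
# modulus:
#
#   E0_ind(theta) = E11 + (E33 - E11) * f(theta) = E11 + deltaE * f(theta)
#   E_ind(DBM)    = alpha + beta * DBM
#   combined:       E_ind = (alpha + E11) + beta * DBM + deltaE * f(theta)
#
# f is normalized to f(0) = 0, f(90) = 1 and fitted in the two-parameter
# class c1 sin^2(theta) + c2 sin^4(theta) with c1 + c2 = 1, which is smooth,
# satisfies the normalization identically and is monotone for c1 in [0, 2].

#' Evaluate a fitted shape function
#'
#' @param fit a `shape_function_fit` (or a bare `sin2` coefficient).
#' @param theta angles in degrees.
#' @return f(theta), unitless in \[0, 1\] for monotone fits.
#' @export
eval_shape <- function(fit, theta) {
  c1 <- if (inherits(fit, "shape_function_fit")) fit$coefficients[["sin2"]]
        else as.numeric(fit)
  s2 <- sin(theta * pi / 180)^2
  c1 * s2 + (1 - c1) * s2^2
}

#' Fit the shape function of the indentation tensor
#'
#' Normalizes an M(theta) profile to `(M - M(0)) / (M(90) - M(0))` and fits
#' `f(theta) = c1 sin^2 + (1 - c1) sin^4` by least squares. The endpoints
#' M(0) and M(90) are taken from the profile (linear interpolation if the
#' grid does not sample them exactly), so `f(0) = 0` and `f(90) = 1` hold
#' by construction.
#'
#' @param theta angles in degrees spanning \[0, 90\] (at least 5 values).
#' @param moduli indentation moduli (GPa) at `theta`.
#' @param constants optional [elastic_constants()] recorded with the fit.
#' @param monotone_tol tolerated non-monotonicity (GPa) in the input
#'   profile before a warning is raised.
#' @return object of class `shape_function_fit` with the `sin2`/`sin4`
#'   coefficients, endpoints `M0`/`M90`, the fitted grid and residual RMS
#'   (in f units and in GPa).
#' @export
fit_shape_function <- function(theta, moduli, constants = NULL,
                               monotone_tol = 1e-6) {
  stopifnot(length(theta) == length(moduli))
  if (length(theta) < 5) {
    stop("at least 5 angle samples spanning [0, 90] are required")
  }
  if (min(theta) > 0 + 1e-9 || max(theta) < 90 - 1e-9) {
    stop("angle grid must span [0, 90] degrees")
  }
  o <- order(theta)
  theta <- theta[o]; moduli <- moduli[o]
  if (any(diff(moduli) < -monotone_tol * max(abs(moduli)))) {
    warning("modulus profile is not monotone in theta; fit proceeds")
  }
  M0 <- approx(theta, moduli, xout = 0)$y
  M90 <- approx(theta, moduli, xout = 90)$y
  if (abs(M90 - M0) < 1e-12) stop("degenerate profile: M(90) equals M(0)")
  y <- (moduli - M0) / (M90 - M0)
  s2 <- sin(theta * pi / 180)^2
  s4 <- s2^2
  # least squares for c1 in y = c1 s2 + (1 - c1) s4
  c1 <- sum((y - s4) * (s2 - s4)) / sum((s2 - s4)^2)
  resid <- y - (c1 * s2 + (1 - c1) * s4)
  structure(list(
    form = "c1*sin^2 + (1-c1)*sin^4",
    coefficients = c(sin2 = c1, sin4 = 1 - c1),
    M0 = M0, M90 = M90,
    grid = data.frame(theta = theta, modulus = moduli, f = y),
    residual_rms = sqrt(mean(resid^2)),
    residual_rms_gpa = sqrt(mean(resid^2)) * abs(M90 - M0),
    monotone = c1 >= 0 && c1 <= 2,
    constants = constants
  ), class = "shape_function_fit")
}

#' @export
print.shape_function_fit <- function(x, ...) {
  cat(sprintf("Shape function f(theta) = %.4f sin^2 + %.4f sin^4\n",
              x$coefficients[["sin2"]], x$coefficients[["sin4"]]))
  cat(sprintf("  M(0) = %.3f GPa, M(90) = %.3f GPa, residual RMS = %.3g (f units)\n",
              x$M0, x$M90, x$residual_rms))
  if (!x$monotone) cat("  warning: fitted f is not monotone on [0, 90]\n")
  invisible(x)
}

#' Fit the combined angle + mineralization model of the indentation modulus
#'
#' Ordinary least squares of site-level indentation moduli on mineralization
#' (DBM) and the shape function of the fiber out-of-plane angle:
#' `E_ind = alpha + beta * DBM + deltaE * f(theta)`, optionally with the
#' `f(theta) * DBM` interaction. The intercept absorbs the transverse
#' modulus E11 together with the mineralization-model offset.
#'
#' @param sites data frame with columns `E_ind` (GPa), `theta` (degrees,
#'   in \[0, 90\]) and `dbm`.
#' @param shape a `shape_function_fit` used to map theta to f(theta).
#' @param include_interaction add the `f(theta) * DBM` term.
#' @return object of class `combined_model_fit`: coefficients `alpha`
#'   (GPa), `beta` (GPa per DBM unit), `deltaE` (GPa) and optionally
#'   `interaction`, their p-values, R2, adjusted R2, model F p-value and
#'   the underlying `lm` fit.
#' @export
fit_combined_model <- function(sites, shape, include_interaction = FALSE) {
  stopifnot(all(c("E_ind", "theta", "dbm") %in% names(sites)))
  if (nrow(sites) < 5) stop("at least 5 sites are required")
  if (any(sites$theta < 0 | sites$theta > 90)) {
    stop("theta must lie in [0, 90] degrees")
  }
  d <- data.frame(E_ind = sites$E_ind, dbm = sites$dbm,
                  f = eval_shape(shape, sites$theta))
  X <- if (include_interaction) {
    model.matrix(~ dbm + f + dbm:f, d)
  } else {
    model.matrix(~ dbm + f, d)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- if (include_interaction) lm(E_ind ~ dbm + f + dbm:f, data = d)
         else lm(E_ind ~ dbm + f, data = d)
  sm <- summary(fit)
  cf <- sm$coefficients
  fstat <- sm$fstatistic
  out <- list(
    alpha = cf["(Intercept)", "Estimate"],
    beta = cf["dbm", "Estimate"],
    deltaE = cf["f", "Estimate"],
    interaction = if (include_interaction) cf["dbm:f", "Estimate"] else NULL,
    p_values = cf[, "Pr(>|t|)"],
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = nrow(d),
    shape = shape,
    lm_fit = fit
  )
  class(out) <- "combined_model_fit"
  out
}

#' @export
print.combined_model_fit <- function(x, ...) {
  cat("Combined indentation-modulus model E_ind = alpha + beta*DBM + deltaE*f(theta)\n")
  cat(sprintf("  alpha  = %8.3f GPa  (p = %.3g)\n", x$alpha,
              x$p_values[["(Intercept)"]]))
  cat(sprintf("  beta   = %8.3f GPa/DBM (p = %.3g)\n", x$beta,
              x$p_values[["dbm"]]))
  cat(sprintf("  deltaE = %8.3f GPa  (p = %.3g)\n", x$deltaE,
              x$p_values[["f"]]))
  if (!is.null(x$interaction)) {
    cat(sprintf("  interaction = %.3f (p = %.3g)\n", x$interaction,
                x$p_values[["dbm:f"]]))
  }
  cat(sprintf("  R2 = %.3f, adj R2 = %.3f, F p = %.3g, n = %d\n",
              x$r_squared, x$adj_r_squared, x$f_p_value, x$n))
  invisible(x)
}

#' Predict indentation modulus from the combined model
#'
#' @param fit a `combined_model_fit`.
#' @param theta fiber out-of-plane angle(s), degrees in \[0, 90\].
#' @param dbm mineralization value(s).
#' @return predicted indentation modulus (GPa).
#' @export
predict_indentation_modulus <- function(fit, theta, dbm) {
  stopifnot(inherits(fit, "combined_model_fit"))
  if (any(theta < 0 | theta > 90)) stop("theta must lie in [0, 90] degrees")
  f <- eval_shape(fit$shape, theta)
  out <- fit$alpha + fit$beta * dbm + fit$deltaE * f
  if (!is.null(fit$interaction)) out <- out + fit$interaction * dbm * f
  out
}
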