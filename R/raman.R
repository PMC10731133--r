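# Quantitative polarized Raman spectroscopy (qPRS) analysis.
#
# Out-of-plane mineralized collagen fiber angle theta_MCF is estimated from
# the polarization-averaged amide I / amide III integrated area ratio
# through a monotone calibration function; the degree of bone
# mineralization (DBM) is the v1PO4 / amide I area ratio averaged over the
# 13 polarization angles. Spectra are baseline-corrected with a
# second-order polynomial fitted to detected local minima, and bands are
# fitted with Lorentzian superpositions (analytic band area
# pi * amplitude * half-width).

#' Default Raman band definitions
#'
#' Fit windows and sub-peak layouts for the three bands used by the
#' pipeline: the primary phosphate band v1PO4 (920-990 cm-1, single peak
#' near 960, polarization-dependent), amide III (1215-1300 cm-1, sub-peaks
#' at 1242 and 1273, polarization-independent) and amide I (1550-1750
#' cm-1, sub-peaks at 1638 and 1670, polarization-dependent).
#'
#' @return named list of band definitions (window, centers, widths).
#' @export
raman_bands <- function() {
  list(
    v1po4 = list(window = c(920, 990), centers = 960, widths = 8),
    amide3 = list(window = c(1215, 1300), centers = c(1242, 1273),
                  widths = c(10, 10)),
    amide1 = list(window = c(1550, 1750), centers = c(1638, 1670),
                  widths = c(14, 14))
  )
}

#' Orientation calibration function
#'
#' Monotone parametric map from the polarization-aggregated amide I /
#' amide III area ratio `r` to the out-of-plane fiber angle:
#' `theta = 90 * ((r - r_min) / (r_max - r_min))^exponent` degrees.
#' The synthetic generator uses the exact inverse, so estimator and
#' generator form a well-posed round trip.
#'
#' @param r_min,r_max ratio values mapped to 0 and 90 degrees.
#' @param exponent shape exponent (> 0).
#' @return object of class `raman_calibration` with `map` (ratio ->
#'   degrees, clamped to \[0, 90\] with a warning outside the domain) and
#'   `inverse` (degrees -> ratio).
#' @export
raman_calibration <- function(r_min = 2, r_max = 8, exponent = 1) {
  stopifnot(r_max > r_min, exponent > 0)
  structure(list(
    r_min = r_min, r_max = r_max, exponent = exponent,
    map = function(r) {
      x <- (r - r_min) / (r_max - r_min)
      if (any(x < -1e-9 | x > 1 + 1e-9)) {
        warning("ratio outside calibration domain; clamped to [0, 90] degrees")
      }
      90 * pmin(pmax(x, 0), 1)^exponent
    },
    inverse = function(theta) {
      stopifnot(all(theta >= 0 & theta <= 90))
      r_min + (r_max - r_min) * (theta / 90)^(1 / exponent)
    }
  ), class = "raman_calibration")
}

lorentzian <- function(x, center, hwhm, amplitude) {
  amplitude * hwhm^2 / ((x - center)^2 + hwhm^2)
}

#' Subtract a second-order polynomial baseline
#'
#' Detects baseline anchor points as rolling-window local minima of the
#' (lightly smoothed) spectrum, fits a quadratic to them by iteratively
#' trimmed least squares (anchors sitting on peak tails have positive
#' residuals and are discarded), and subtracts the fitted polynomial.
#'
#' @param wavenumber wavenumber grid (cm-1).
#' @param intensity intensity counts.
#' @param anchor_window rolling window width in samples for minima
#'   detection.
#' @param n_iter maximum trimming iterations.
#' @return list with `intensity` (corrected), `baseline` (fitted values),
#'   `coefficients` of the quadratic, and `anchors` (indices used).
#' @export
subtract_baseline <- function(wavenumber, intensity, anchor_window = 20,
                              n_iter = 12) {
  n <- length(wavenumber)
  stopifnot(length(intensity) == n)
  sm <- stats::filter(intensity, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- intensity[is.na(sm)]
  starts <- seq(1, n, by = anchor_window)
  anchors <- unique(vapply(starts, function(s) {
    idx <- s:min(s + anchor_window - 1, n)
    idx[which.min(sm[idx])]
  }, integer(1)))
  if (length(anchors) < 10) {
    stop("too few local minima for baseline estimation (need >= 10)")
  }
  x0 <- mean(range(wavenumber))
  keep <- anchors
  fit <- NULL
  for (it in seq_len(n_iter)) {
    xa <- wavenumber[keep] - x0
    fit <- lm(intensity[keep] ~ xa + I(xa^2))
    res <- intensity[anchors] -
      predict(fit, newdata = data.frame(xa = wavenumber[anchors] - x0))
    # peak-tail contamination is strictly positive: trim anchors whose
    # residual exceeds the spread of the currently trusted set
    spread <- mad(res[match(keep, anchors)])
    cut <- 3 * spread + 1e-12 * max(abs(intensity), 1)
    new_keep <- anchors[res < cut]
    if (length(new_keep) < 10) {
      new_keep <- anchors[order(res)[1:10]]
    }
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  xall <- wavenumber - x0
  baseline <- predict(fit, newdata = data.frame(xa = xall))
  list(intensity = intensity - baseline, baseline = baseline,
       coefficients = coef(fit), anchors = keep)
}

#' Fit Lorentzian band superpositions
#'
#' For each band window, fits a superposition of Lorentzian sub-peaks to a
#' baseline-corrected spectrum by least squares (Levenberg-Marquardt) and
#' reports the analytic integrated areas `pi * amplitude * half-width`.
#' A window with essentially zero intensity yields zero area and is
#' flagged; a non-converged fit is flagged with its residual norm.
#'
#' @param wavenumber,intensity baseline-corrected spectrum.
#' @param bands band definitions as from [raman_bands()].
#' @return object of class `band_fit`: named list per band with sub-peak
#'   parameters, `area` (total), `flagged` and `residual_norm`.
#' @export
fit_bands <- function(wavenumber, intensity, bands = raman_bands()) {
  out <- lapply(names(bands), function(bn) {
    b <- bands[[bn]]
    idx <- wavenumber >= b$window[1] & wavenumber <= b$window[2]
    x <- wavenumber[idx]; y <- intensity[idx]
    if (!length(x)) stop("spectrum does not cover window of band ", bn)
    if (max(abs(y)) < 1e-9 * max(abs(intensity), 1e-12) ||
        max(y) <= 0) {
      return(list(band = bn, centers = b$centers, hwhm = b$widths,
                  amplitudes = rep(0, length(b$centers)), area = 0,
                  flagged = TRUE, residual_norm = 0))
    }
    k <- length(b$centers)
    start <- list(a = pmax(vapply(b$centers, function(cc)
      y[which.min(abs(x - cc))], numeric(1)), 1e-6),
      c = b$centers, w = b$widths)
    model <- function(p, x) {
      s <- 0
      for (i in seq_len(k)) {
        s <- s + lorentzian(x, p$c[i], p$w[i], p$a[i])
      }
      s
    }
    fml <- as.formula(paste(
      "y ~",
      paste(sprintf("a%d * w%d^2 / ((x - c%d)^2 + w%d^2)", 1:k, 1:k, 1:k, 1:k),
            collapse = " + ")))
    st <- c(setNames(as.list(start$a), paste0("a", 1:k)),
            setNames(as.list(start$c), paste0("c", 1:k)),
            setNames(as.list(start$w), paste0("w", 1:k)))
    lower <- c(rep(0, k), b$window[1] + 0 * start$c, rep(1, k))
    upper <- c(rep(Inf, k), b$window[2] + 0 * start$c, rep(diff(b$window), k))
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = data.frame(x = x, y = y), start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(list(band = bn, centers = b$centers, hwhm = b$widths,
                  amplitudes = rep(NA_real_, k), area = NA_real_,
                  flagged = TRUE,
                  residual_norm = sqrt(sum(y^2))))
    }
    p <- coef(fit)
    a <- p[paste0("a", 1:k)]; cc <- p[paste0("c", 1:k)]
    w <- p[paste0("w", 1:k)]
    list(band = bn, centers = unname(cc), hwhm = unname(w),
         amplitudes = unname(a),
         area = sum(pi * a * w),
         flagged = FALSE,
         residual_norm = sqrt(sum(residuals(fit)^2)))
  })
  names(out) <- names(bands)
  structure(out, class = "band_fit")
}

#' Fiber out-of-plane angle from polarization-resolved band fits
#'
#' Normalizes the amide I area by the amide III area for each polarization
#' angle, aggregates over the polarization series (arithmetic mean by
#' default, max-minus-min modulation depth optionally) and maps the
#' aggregate ratio through the calibration function to theta in
#' \[0, 90\] degrees.
#'
#' @param fits list of `band_fit` objects, one per polarization angle.
#' @param calibration a [raman_calibration()].
#' @param aggregate `"mean"` or `"modulation"`.
#' @return angle in degrees.
#' @export
compute_orientation <- function(fits, calibration = raman_calibration(),
                                aggregate = c("mean", "modulation")) {
  aggregate <- match.arg(aggregate)
  a1 <- vapply(fits, function(f) f$amide1$area, numeric(1))
  a3 <- vapply(fits, function(f) f$amide3$area, numeric(1))
  if (any(!is.finite(a3)) || any(a3 <= 0)) {
    stop("non-positive amide III area; orientation undefined")
  }
  r <- a1 / a3
  agg <- switch(aggregate,
                mean = mean(r),
                modulation = calibration$r_min + diff(range(r)))
  calibration$map(agg)
}

#' Degree of bone mineralization from polarization-resolved band fits
#'
#' Arithmetic mean over the polarization angles of the v1PO4 / amide I
#' integrated area ratio. Angles with non-positive amide I area are
#' excluded with a warning; if all angles are excluded an error is raised.
#'
#' @param fits list of `band_fit` objects, one per polarization angle.
#' @return DBM (unitless).
#' @export
compute_dbm <- function(fits) {
  a1 <- vapply(fits, function(f) f$amide1$area, numeric(1))
  ap <- vapply(fits, function(f) f$v1po4$area, numeric(1))
  ok <- is.finite(a1) & a1 > 0 & is.finite(ap)
  if (!any(ok)) stop("amide I area non-positive at every polarization angle")
  if (!all(ok)) {
    warning(sum(!ok), " polarization angle(s) excluded from DBM (non-positive amide I)")
  }
  mean(ap[ok] / a1[ok])
}

#' Summarize a qPRS line scan into a site result
#'
#' Sample mean and standard deviation of the per-position angle estimates,
#' and the mean DBM, over the positions of one osteonal line scan.
#'
#' @param theta per-position angles (degrees).
#' @param dbm per-position DBM values.
#' @param id site identifier.
#' @return object of class `raman_site_result` with `theta_mean`,
#'   `theta_sd` (NA and flagged for a single position), `dbm`,
#'   `n_positions` and the per-position values.
#' @export
summarize_linescan <- function(theta, dbm, id = NA_character_) {
  stopifnot(length(theta) == length(dbm), length(theta) >= 1)
  flagged <- length(theta) < 2
  if (flagged) warning("single position: angle SD undefined")
  structure(list(
    theta_mean = mean(theta),
    theta_sd = if (flagged) NA_real_ else sd(theta),
    dbm = mean(dbm),
    n_positions = length(theta),
    positions = data.frame(position = seq_along(theta),
                           theta = theta, dbm = dbm),
    flagged = flagged,
    id = id
  ), class = "raman_site_result")
}

#' @export
print.raman_site_result <- function(x, ...) {
  cat(sprintf(
    "qPRS site '%s': theta %.1f +/- %.1f deg, DBM %.3f (%d positions)\n",
    x$id, x$theta_mean, if (is.na(x$theta_sd)) 0 else x$theta_sd,
    x$dbm, x$n_positions))
  invisible(x)
}

#' Analyze a polarized Raman line scan
#'
#' Full qPRS chain for one osteonal site: per spectrum baseline
#' subtraction and Lorentzian band fitting, per position orientation and
#' DBM estimation, then the line-scan summary.
#'
#' @param scan a `polarized_line_scan` (see
#'   [generate_polarized_scan()] or [read_polarized_scan()]).
#' @param calibration a [raman_calibration()].
#' @param bands band definitions.
#' @param aggregate polarization aggregation for the orientation ratio.
#' @return a `raman_site_result`.
#' @export
analyze_polarized_scan <- function(scan, calibration = raman_calibration(),
                                   bands = raman_bands(),
                                   aggregate = "mean") {
  theta <- numeric(length(scan$positions))
  dbm <- numeric(length(scan$positions))
  for (ip in seq_along(scan$positions)) {
    pos <- scan$positions[[ip]]
    fits <- lapply(pos$spectra, function(sp) {
      corr <- subtract_baseline(scan$wavenumber, sp$intensity)
      fit_bands(scan$wavenumber, corr$intensity, bands)
    })
    theta[ip] <- compute_orientation(fits, calibration, aggregate)
    dbm[ip] <- compute_dbm(fits)
  }
  summarize_linescan(theta, dbm, id = scan$id)
}
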