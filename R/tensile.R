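# Microtensile curve analysis: force/displacement -> stress/strain
# conversion and extraction of loading modulus, ultimate stress/strain and
# the failure point.
#
# The loading modulus is defined as the highest slope of the loading part
# of the stress-strain curve, estimated with moving-window least squares so
# that single-point noise spikes cannot masquerade as slope. Failure is
# detected as the first abrupt stress drop (below a fraction of the running
# maximum), matching the near-vertical fracture of dry bone ECM in tension.

#' Convert force-displacement to a stress-strain curve
#'
#' `stress = force / (width * thickness)` and
#' `strain = displacement / gauge length`. With force in micro-Newton and
#' the cross-section in square micrometers the stress is in MPa directly;
#' displacement in nanometers over a gauge length in micrometers gives
#' unitless strain.
#'
#' @param force force channel in micro-Newton.
#' @param displacement displacement channel in nanometers.
#' @param geometry list with `width`, `thickness`, `length` in micrometers.
#' @param time optional time stamps in seconds.
#' @param id specimen/site identifier.
#' @return object of class `tensile_curve`: data frame `data` with columns
#'   `time`, `strain`, `stress` (MPa) plus the geometry and id.
#' @export
compute_stress_strain <- function(force, displacement, geometry,
                                  time = NULL, id = NA_character_) {
  stopifnot(length(force) == length(displacement))
  area <- geometry$width * geometry$thickness
  if (!is.finite(area) || area <= 0) stop("gauge cross-section area must be positive")
  if (geometry$length <= 0) stop("gauge length must be positive")
  if (is.null(time)) time <- seq_along(force) - 1
  structure(list(
    data = data.frame(time = time,
                      strain = displacement / (geometry$length * 1000),
                      stress = force / area),
    geometry = geometry,
    id = id
  ), class = "tensile_curve")
}

#' @export
print.tensile_curve <- function(x, ...) {
  cat(sprintf("Microtensile curve '%s': %d samples, peak stress %.1f MPa\n",
              x$id, nrow(x$data), max(x$data$stress)))
  invisible(x)
}

# moving-window least-squares slope, window defined in strain units but
# never narrower than min_points samples; O(n) via cumulative sums
max_window_slope <- function(strain, stress, window, min_points) {
  n <- length(strain)
  if (n < min_points) return(NA_real_)
  ss <- cummax(strain)  # monotone proxy against displacement noise
  ends <- pmin(pmax(findInterval(ss + window, ss),
                    seq_len(n) + min_points - 1L), n)
  starts <- seq_len(n)
  ok <- ends - starts + 1L >= min_points
  cx <- c(0, cumsum(strain)); cy <- c(0, cumsum(stress))
  cxx <- c(0, cumsum(strain^2)); cxy <- c(0, cumsum(strain * stress))
  i <- starts[ok]; j <- ends[ok]
  k <- j - i + 1
  sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
  sxx <- cxx[j + 1] - cxx[i]; sxy <- cxy[j + 1] - cxy[i]
  den <- k * sxx - sx^2
  sl <- (k * sxy - sx * sy) / den
  sl <- sl[is.finite(sl) & den > 0]
  if (!length(sl)) return(NA_real_)
  max(sl)
}

#' Extract microtensile properties from a stress-strain curve
#'
#' Finds the failure event (first sample whose stress falls below
#' `drop_fraction` of the running maximum), restricts to the loading
#' segment before it, and extracts the loading modulus (highest
#' moving-window least-squares slope, GPa), ultimate stress (global
#' maximum, MPa), the strain at ultimate stress, and the strain at
#' failure. If no drop is found the result is flagged rather than raising
#' an error.
#'
#' @param curve a `tensile_curve`.
#' @param slope_window moving-window width in strain units (default 0.002,
#'   i.e. 0.2 percent strain).
#' @param min_points minimum samples per slope window.
#' @param drop_fraction failure threshold relative to the running stress
#'   maximum.
#' @param ductility_threshold passed to [classify_failure()].
#' @param fst optional fracture surface type label
#'   (`axial`/`mixed`/`transversal`) carried through to the result.
#' @return object of class `tensile_result` with fields `E_loading` (GPa),
#'   `sigma_ult` (MPa), `eps_ult`, `eps_fail`, `failure_class`,
#'   `failure_detected`, `fst`, `id`.
#' @export
extract_tensile_properties <- function(curve, slope_window = 0.002,
                                       min_points = 10,
                                       drop_fraction = 0.5,
                                       ductility_threshold = 0.05,
                                       fst = NA_character_) {
  stopifnot(inherits(curve, "tensile_curve"))
  d <- curve$data
  n <- nrow(d)
  if (n < 2 * min_points) stop("curve too short for slope estimation")
  runmax <- cummax(d$stress)
  floor_level <- 0.05 * max(d$stress)
  drop_idx <- which(d$stress < drop_fraction * runmax &
                      runmax > floor_level)
  failure_detected <- length(drop_idx) > 0
  fail_i <- if (failure_detected) drop_idx[1] else n + 1L
  load_idx <- seq_len(min(max(fail_i - 1L, 2L), n))
  stress_l <- d$stress[load_idx]
  strain_l <- d$strain[load_idx]
  i_ult <- which.max(stress_l)
  sigma_ult <- stress_l[i_ult]
  eps_ult <- strain_l[i_ult]
  eps_fail <- strain_l[length(strain_l)]
  E_loading <- max_window_slope(strain_l, stress_l, slope_window,
                                min_points) / 1000  # MPa -> GPa
  res <- structure(list(
    E_loading = E_loading,
    sigma_ult = sigma_ult,
    eps_ult = eps_ult,
    eps_fail = max(eps_fail, eps_ult),
    failure_detected = failure_detected,
    fst = fst,
    id = curve$id
  ), class = "tensile_result")
  res$failure_class <- classify_failure(res, ductility_threshold)
  res
}

#' @export
print.tensile_result <- function(x, ...) {
  cat(sprintf(
    "Tensile result '%s': E_loading %.2f GPa, sigma_ult %.1f MPa, eps_ult %.4f (%s%s)\n",
    x$id, x$E_loading, x$sigma_ult, x$eps_ult, x$failure_class,
    if (!x$failure_detected) ", no failure event detected" else ""))
  invisible(x)
}

#' Classify tensile failure as brittle or ductile
#'
#' A specimen is ductile when the failure strain exceeds the strain at
#' ultimate stress by more than `threshold` (relative):
#' `(eps_fail - eps_ult) / eps_ult > threshold`.
#'
#' @param result a `tensile_result` (or any list with `eps_fail`,
#'   `eps_ult`).
#' @param threshold relative strain excess separating the classes.
#' @return `"brittle"` or `"ductile"`.
#' @export
classify_failure <- function(result, threshold = 0.05) {
  excess <- (result$eps_fail - result$eps_ult) / result$eps_ult
  if (isTRUE(excess > threshold)) "ductile" else "brittle"
}
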