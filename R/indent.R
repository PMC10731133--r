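# Oliver-Pharr analysis of trapezoidal nanoindentation records.
#
# Unit conventions: load in mN, depth in nm, time in s. With these units
# work integrals are in pJ directly (1 mN * 1 nm = 1 pJ), stiffness is in
# mN/nm and moduli convert to GPa via 1 mN/nm^2 = 1e6 GPa.

#' Berkovich indenter specification
#'
#' Ideal Berkovich area function `A(h) = 24.5 h^2` (optionally with
#' polynomial tip-defect terms `sum(poly[i] * h^(1/2^(i-1)))`), plus the
#' diamond tip constants used to remove the tip compliance from the
#' reduced modulus.
#'
#' @param area_coeff leading area coefficient.
#' @param poly optional tip-defect polynomial coefficients.
#' @param E_tip,nu_tip indenter modulus (GPa) and Poisson ratio.
#' @return list with the tip parameters and an `area(h)` function.
#' @export
berkovich_tip <- function(area_coeff = 24.5, poly = NULL,
                          E_tip = 1141, nu_tip = 0.07) {
  list(area_coeff = area_coeff, poly = poly, E_tip = E_tip, nu_tip = nu_tip,
       area = function(h) {
         a <- area_coeff * h^2
         if (!is.null(poly)) {
           for (i in seq_along(poly)) a <- a + poly[i] * h^(1 / 2^(i - 1))
         }
         a
       })
}

#' Oliver-Pharr analysis of an indentation curve
#'
#' Identifies the load/hold/unload segments, fits a power law
#' `P = B (h - h_f)^m` to the top fraction of the unload segment, and
#' extracts: contact stiffness `S = dP/dh` at maximum depth, contact depth
#' `h_c = h_max - epsilon P_max / S`, projected area `A(h_c)`, reduced
#' modulus `E_r = sqrt(pi)/2 * S / sqrt(A)`, the specimen (plane-strain)
#' indentation modulus after removing the diamond tip compliance, hardness
#' `H_IT = P_max / A`, and the elastic and total work as load-depth
#' integrals over unload and load+hold.
#'
#' Negative stiffness or a contact depth exceeding the maximum depth mark
#' the result invalid (flagged, not an error).
#'
#' @param curve an `indentation_curve` (see
#'   [generate_indentation_curve()] or [read_indentation_curve()]).
#' @param tip a [berkovich_tip()].
#' @param unload_fraction fraction of the unload load range used in the
#'   power-law fit (from the top).
#' @param epsilon Oliver-Pharr geometry factor (0.75 for a paraboloid).
#' @return object of class `indentation_result`: `E_ind` (GPa), `H_IT`
#'   (MPa), `W_el`, `W_tot` (pJ), `h_c` (nm), `stiffness` (mN/nm),
#'   `valid`, `id`.
#' @export
analyze_indentation <- function(curve, tip = berkovich_tip(),
                                unload_fraction = 0.8, epsilon = 0.75) {
  d <- curve$data
  seg <- curve$segments %||% infer_segments(d)
  unl <- d[seg$unload, , drop = FALSE]
  if (nrow(unl) < 20) stop("unload segment has fewer than 20 samples")
  P_max <- max(d$load)
  h_max <- max(d$depth[seg$load | seg$hold])
  top <- unl[unl$load >= (1 - unload_fraction) * P_max, , drop = FALSE]
  hf_start <- min(top$depth) * 0.9
  fit <- tryCatch(
    minpack.lm::nlsLM(load ~ b * (depth - hf)^m, data = top,
                      start = list(b = P_max / (h_max - hf_start)^1.5,
                                   m = 1.5, hf = hf_start),
                      lower = c(0, 1, 0),
                      upper = c(Inf, 10, min(top$depth) - 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(invalid_indentation_result(curve$id, "unload fit failed"))
  }
  p <- coef(fit)
  S <- unname(p["b"] * p["m"] * (h_max - p["hf"])^(p["m"] - 1))
  h_c <- unname(h_max - epsilon * P_max / S)
  if (!is.finite(S) || S <= 0 || h_c <= 0 || h_c > h_max) {
    return(invalid_indentation_result(curve$id, "non-physical contact"))
  }
  A <- tip$area(h_c)
  E_r <- sqrt(pi) / 2 * S / sqrt(A) * 1e6       # GPa
  inv_ind <- 1 / E_r - (1 - tip$nu_tip^2) / tip$E_tip
  if (inv_ind <= 0) {
    return(invalid_indentation_result(curve$id, "tip compliance exceeds total"))
  }
  E_ind <- 1 / inv_ind
  H_IT <- P_max / A * 1e6 * 1000                # MPa
  lh <- d[seg$load | seg$hold, , drop = FALSE]
  W_tot <- pracma::trapz(lh$depth, lh$load)     # pJ
  # include the peak point so the elastic work starts at (h_max, P_max)
  unl_w <- rbind(lh[nrow(lh), , drop = FALSE], unl)
  W_el <- abs(pracma::trapz(unl_w$depth, unl_w$load))
  W_el <- min(W_el, W_tot)
  structure(list(E_ind = E_ind, H_IT = H_IT, W_el = W_el, W_tot = W_tot,
                 h_c = h_c, stiffness = unname(S), P_max = P_max,
                 h_max = h_max, valid = TRUE, reason = NULL,
                 id = curve$id),
            class = "indentation_result")
}

invalid_indentation_result <- function(id, reason) {
  structure(list(E_ind = NA_real_, H_IT = NA_real_, W_el = NA_real_,
                 W_tot = NA_real_, h_c = NA_real_, stiffness = NA_real_,
                 P_max = NA_real_, h_max = NA_real_, valid = FALSE,
                 reason = reason, id = id),
            class = "indentation_result")
}

#' @export
print.indentation_result <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("Indentation result '%s': INVALID (%s)\n", x$id, x$reason))
  } else {
    cat(sprintf(
      "Indentation result '%s': E_ind %.2f GPa, H_IT %.0f MPa, W_el %.0f / W_tot %.0f pJ\n",
      x$id, x$E_ind, x$H_IT, x$W_el, x$W_tot))
  }
  invisible(x)
}

# Segment boundaries from the load profile when no protocol metadata is
# present: hold = contiguous samples at (essentially) maximum load.
infer_segments <- function(d) {
  P_max <- max(d$load)
  at_max <- d$load >= 0.995 * P_max
  i1 <- which(at_max)[1]
  i2 <- tail(which(at_max), 1)
  n <- nrow(d)
  list(load = seq_len(n) < i1,
       hold = seq_len(n) >= i1 & seq_len(n) <= i2,
       unload = seq_len(n) > i2)
}

#' Aggregate indentation results over an osteonal site
#'
#' Arithmetic mean of each property over the valid indents of one site
#' (typically three), with the number of invalid indents reported.
#'
#' @param results list of `indentation_result` objects.
#' @param id site identifier.
#' @return list with the averaged properties, `n_valid`, `n_invalid` and
#'   `flagged` (TRUE when any indent was invalid).
#' @export
aggregate_osteon <- function(results, id = NA_character_) {
  valid <- Filter(function(r) isTRUE(r$valid), results)
  if (!length(valid)) stop("no valid indentation result to aggregate")
  avg <- function(field) mean(vapply(valid, `[[`, numeric(1), field))
  list(E_ind = avg("E_ind"), H_IT = avg("H_IT"),
       W_el = avg("W_el"), W_tot = avg("W_tot"),
       n_valid = length(valid), n_invalid = length(results) - length(valid),
       flagged = length(valid) < length(results), id = id)
}

#' Indent layout for one osteonal site
#'
#' Positions of the site's indents on a line with fixed spacing
#' (micrometers), guaranteeing the minimum inter-indent distance that
#' avoids interaction of plastic zones.
#'
#' @param n number of indents.
#' @param spacing distance between neighboring indents in micrometers.
#' @return matrix of x/y positions (micrometers).
#' @export
indent_layout <- function(n = 3, spacing = 7) {
  stopifnot(spacing >= 7)
  cbind(x = (seq_len(n) - 1) * spacing, y = rep(0, n))
}
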