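# Indentation modulus of an anisotropic elastic half-space.
#
# A rigid frictionless axisymmetric indenter pressed along the surface
# normal of an anisotropic half-space sees an effective ("indentation")
# modulus M that generalizes E/(1 - nu^2). The surface displacement due to
# a point force P on the surface decays as u(r, gamma) = P h(gamma) / r,
# where the angular profile h is obtained from the Barnett-Lothe tensor
# B(t) of the in-plane direction t:
#
#   B(t) = (1 / 2 pi) * integral over rotations of the orthonormal pair
#          (m, n) in the plane perpendicular to t of
#          [ (nn) - (nm)(mm)^-1(mn) ],   (ab)_jk = a_i C_ijkl b_l
#
#   h(gamma) = (1 / 2 pi) * a . B(t(gamma))^-1 . a      (a = surface normal)
#
# For a circular contact the polar average of h governs the load-
# displacement relation, giving M = 1 / (pi * <h>) = 2 / <a.B^-1.a>.
# For isotropic media h is constant and M reduces to E/(1 - nu^2) exactly;
# for a tilted transverse isotropic material the circular-contact polar
# average is the standard approximation.

# (ab)_jk = a_i C_ijkl b_l for a full 3x3x3x3 tensor flattened to 3 x 27.
contract_ab <- function(Cm1, a, b) {
  # Cm1: 3 x 27 matrix, rows index i, columns (j,k,l) column-major
  t1 <- array(crossprod(a, Cm1), c(3, 3, 3))   # (j,k,l)
  matrix(t1, 9, 3) %*% b                        # -> (j,k)
}

barnett_lothe <- function(Cm1, t, n_inner) {
  # orthonormal pair spanning the plane perpendicular to t
  ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- ref - sum(ref * t) * t
  p <- p / sqrt(sum(p^2))
  q <- c(t[2] * p[3] - t[3] * p[2],
         t[3] * p[1] - t[1] * p[3],
         t[1] * p[2] - t[2] * p[1])
  B <- matrix(0, 3, 3)
  phis <- (seq_len(n_inner) - 1) * pi / n_inner  # integrand has period pi
  for (phi in phis) {
    m <- cos(phi) * p + sin(phi) * q
    n <- -sin(phi) * p + cos(phi) * q
    nn <- matrix(contract_ab(Cm1, n, n), 3, 3)
    nm <- matrix(contract_ab(Cm1, n, m), 3, 3)
    mm <- matrix(contract_ab(Cm1, m, m), 3, 3)
    B <- B + nn - nm %*% solve(mm, t(nm))
  }
  B / n_inner
}

indentation_modulus_once <- function(Cm1, axis, n_outer, n_inner) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  gammas <- (seq_len(n_outer) - 1) * pi / n_outer  # B(t) = B(-t)
  acc <- 0
  for (g in gammas) {
    t <- cos(g) * u + sin(g) * v
    B <- barnett_lothe(Cm1, t, n_inner)
    acc <- acc + drop(crossprod(axis, solve(B, axis)))
  }
  2 / (acc / n_outer)
}

#' Indentation modulus of an anisotropic half-space
#'
#' Computes the indentation modulus for a rigid frictionless axisymmetric
#' indenter acting along `axis` on a half-space with the given stiffness,
#' by angular integration of the Barnett-Lothe surface Green's function
#' with Richardson-style grid-doubling until the result is converged to
#' `tol` (relative).
#'
#' @param tensor a `stiffness_tensor` (GPa) or bare 6x6 Voigt matrix.
#' @param axis unit indentation direction (defaults to the laboratory
#'   surface normal e3); normalized internally.
#' @param tol relative convergence tolerance of the grid refinement.
#' @param n_outer,n_inner initial quadrature sizes for the in-plane
#'   direction and the Barnett-Lothe integral.
#' @param max_refine maximum number of grid doublings before giving up.
#' @return indentation modulus in GPa, with attribute `"rel_err"` giving
#'   the final refinement change.
#' @export
indentation_modulus <- function(tensor, axis = c(0, 0, 1), tol = 1e-3,
                                n_outer = 16, n_inner = 32,
                                max_refine = 6) {
  C <- as_stiffness_matrix(tensor)
  ev <- eigen(kelvin_form(C), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("stiffness tensor is not positive definite")
  axis <- axis / sqrt(sum(axis^2))
  Cm1 <- matrix(voigt_to_full(C), 3, 27)
  m_prev <- indentation_modulus_once(Cm1, axis, n_outer, n_inner)
  for (r in seq_len(max_refine)) {
    n_outer <- n_outer * 2L
    n_inner <- n_inner * 2L
    m_new <- indentation_modulus_once(Cm1, axis, n_outer, n_inner)
    rel <- abs(m_new - m_prev) / abs(m_new)
    if (rel < tol) {
      return(structure(m_new, rel_err = rel))
    }
    m_prev <- m_new
  }
  stop(sprintf(
    "indentation modulus did not converge to %.1e (last change %.2e at %d x %d grid)",
    tol, abs(m_new - m_prev) / abs(m_new), n_outer, n_inner))
}

#' Isotropic indentation modulus (closed form)
#'
#' `E / (1 - nu^2)`, the plane-strain modulus of an isotropic half-space.
#' Serves as an independent oracle for [indentation_modulus()].
#'
#' @param E Young's modulus (GPa).
#' @param nu Poisson ratio.
#' @return modulus in GPa.
#' @export
isotropic_indentation_modulus <- function(E, nu) E / (1 - nu^2)

#' Symmetry-axis indentation modulus of a transverse isotropic half-space
#'
#' Exact closed-form indentation modulus for indentation along the
#' symmetry axis (e3 of the material frame), in terms of the Voigt
#' stiffness components:
#' `M3 = 2 sqrt((C33 - C13^2/C11) / (1/C44 + 2/(sqrt(C11 C33) + C13)))`.
#' Independent of the numerical Green's-function route; reduces to
#' `E/(1 - nu^2)` in the isotropic limit.
#'
#' @param tensor material-frame `stiffness_tensor` or 6x6 matrix (GPa).
#' @return modulus in GPa.
#' @export
axial_indentation_modulus_closed_form <- function(tensor) {
  C <- as_stiffness_matrix(tensor)
  c11 <- C[1, 1]; c13 <- C[1, 3]; c33 <- C[3, 3]; c44 <- C[4, 4]
  s <- sqrt(c11 * c33)
  if (s <= c13) stop("invalid transverse isotropic constants (C13 too large)")
  a <- c33 - c13^2 / c11
  b <- 1 / (1 / c44 + 2 / (s + c13))
  2 * sqrt(a * b)
}

#' Indentation modulus profile over fiber out-of-plane angle
#'
#' Evaluates M(theta) for fiber out-of-plane angles `theta` (degrees): the
#' material-frame tensor (fiber along e3) is rotated by `90 - theta` so
#' that theta = 90 indents along the fiber axis and theta = 0 across it.
#'
#' @param constants an [elastic_constants()] object.
#' @param theta vector of angles in degrees, in \[0, 90\].
#' @param ... passed on to [indentation_modulus()].
#' @return data frame with columns `theta` and `modulus` (GPa).
#' @export
indentation_modulus_profile <- function(constants,
                                        theta = seq(0, 90, by = 10), ...) {
  stopifnot(all(theta >= 0 & theta <= 90))
  C0 <- assemble_stiffness(constants)
  mod <- vapply(theta, function(th) {
    as.numeric(indentation_modulus(rotate_stiffness(C0, 90 - th), ...))
  }, numeric(1))
  data.frame(theta = theta, modulus = mod)
}
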