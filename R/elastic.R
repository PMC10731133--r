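# Transverse isotropic elasticity: engineering constants, Voigt-notation
# stiffness assembly, and rotation of fourth-order stiffness tensors.
#
# Conventions: Voigt index order (11, 22, 33, 23, 13, 12), engineering shear
# strains, symmetry axis of the material frame along e3. The indentation
# surface normal is e3 of the laboratory frame; the mineralized collagen
# fiber (MCF) out-of-plane angle theta is the angle between the fiber axis
# and the surface plane, so theta = 90 degrees puts the fiber along the
# indentation axis.

#' Transverse isotropic engineering constants
#'
#' Bundles the five independent constants of a transverse isotropic
#' material: in-plane modulus `E11`, axial modulus `E33`, in-plane Poisson
#' ratio `nu12`, axial Poisson ratio `nu31` (contraction in the plane per
#' unit axial strain, entering the compliance as `-nu31/E33`), and axial
#' shear modulus `G31`. Defaults are bone-like values for osteonal lamellar
#' tissue (GPa).
#'
#' @param E11,E33 transverse and axial Young's moduli in GPa.
#' @param nu12,nu31 Poisson ratios (unitless).
#' @param G31 axial shear modulus in GPa.
#' @return object of class `elastic_constants`.
#' @export
elastic_constants <- function(E11 = 15, E33 = 26, nu12 = 0.32,
                              nu31 = 0.25, G31 = 7) {
  stopifnot(E11 > 0, E33 > 0, G31 > 0)
  ec <- structure(list(E11 = E11, E33 = E33, nu12 = nu12,
                       nu31 = nu31, G31 = G31, deltaE = E33 - E11),
                  class = "elastic_constants")
  ec
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat("Transverse isotropic constants [GPa]:\n")
  cat(sprintf("  E11 = %.3f  E33 = %.3f  (deltaE = %.3f)\n",
              x$E11, x$E33, x$deltaE))
  cat(sprintf("  nu12 = %.3f  nu31 = %.3f  G31 = %.3f\n",
              x$nu12, x$nu31, x$G31))
  invisible(x)
}

#' Assemble a transverse isotropic stiffness tensor
#'
#' Builds the 6x6 Voigt compliance from the five engineering constants and
#' inverts it to a stiffness matrix. Positive definiteness is verified on
#' the Kelvin-normalized form; a non-physical set of constants is rejected
#' with the offending eigenvalue.
#'
#' @param constants an [elastic_constants()] object.
#' @return object of class `stiffness_tensor`: list with the 6x6 `matrix`
#'   (GPa), the generating `constants` and the `rotation` applied so far
#'   (degrees, 0 for a freshly assembled tensor).
#' @export
assemble_stiffness <- function(constants) {
  stopifnot(inherits(constants, "elastic_constants"))
  k <- constants
  S <- matrix(0, 6, 6)
  S[1, 1] <- S[2, 2] <- 1 / k$E11
  S[3, 3] <- 1 / k$E33
  S[1, 2] <- S[2, 1] <- -k$nu12 / k$E11
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- -k$nu31 / k$E33
  S[4, 4] <- S[5, 5] <- 1 / k$G31
  S[6, 6] <- 2 * (S[1, 1] - S[1, 2])
  C <- solve(S)
  C <- (C + t(C)) / 2
  ev <- eigen(kelvin_form(C), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop(sprintf(
      "stiffness is not positive definite (smallest eigenvalue %.4g GPa)",
      min(ev)))
  }
  structure(list(matrix = C, constants = constants, rotation = 0),
            class = "stiffness_tensor")
}

#' @export
print.stiffness_tensor <- function(x, digits = 3, ...) {
  cat(sprintf("6x6 stiffness [GPa], rotation %.1f deg:\n", x$rotation))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Recover engineering constants from a transverse isotropic stiffness
#'
#' Inverts the stiffness to compliance and reads the five engineering
#' constants back; the round trip with [assemble_stiffness()] is exact to
#' machine precision.
#'
#' @param tensor a `stiffness_tensor` in the material frame.
#' @return an [elastic_constants()] object.
#' @export
stiffness_to_constants <- function(tensor) {
  S <- solve(as_stiffness_matrix(tensor))
  elastic_constants(
    E11 = 1 / S[1, 1],
    E33 = 1 / S[3, 3],
    nu12 = -S[1, 2] / S[1, 1],
    nu31 = -S[1, 3] / S[3, 3],
    G31 = 1 / S[4, 4]
  )
}

as_stiffness_matrix <- function(x) {
  if (inherits(x, "stiffness_tensor")) x$matrix else as.matrix(x)
}

# Kelvin normalization: scales the Voigt stiffness so that its eigenvalues
# are the true tensor eigenvalues (diag(1,1,1,sqrt 2,sqrt 2,sqrt 2) scaling).
kelvin_form <- function(C) {
  d <- diag(c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2)))
  d %*% C %*% d
}

# --- Voigt <-> full fourth-order tensor -------------------------------------

voigt_pairs <- matrix(c(1, 1, 2, 2, 3, 3, 2, 3, 1, 3, 1, 2),
                      ncol = 2, byrow = TRUE)

voigt_to_full <- function(C) {
  Cf <- array(0, c(3, 3, 3, 3))
  for (a in 1:6) {
    i <- voigt_pairs[a, 1]; j <- voigt_pairs[a, 2]
    for (b in 1:6) {
      k <- voigt_pairs[b, 1]; l <- voigt_pairs[b, 2]
      v <- C[a, b]
      Cf[i, j, k, l] <- v; Cf[j, i, k, l] <- v
      Cf[i, j, l, k] <- v; Cf[j, i, l, k] <- v
    }
  }
  Cf
}

full_to_voigt <- function(Cf) {
  C <- matrix(0, 6, 6)
  for (a in 1:6) {
    i <- voigt_pairs[a, 1]; j <- voigt_pairs[a, 2]
    for (b in 1:6) {
      k <- voigt_pairs[b, 1]; l <- voigt_pairs[b, 2]
      C[a, b] <- Cf[i, j, k, l]
    }
  }
  (C + t(C)) / 2
}

#' Rotate a stiffness tensor about an in-plane axis
#'
#' Applies the fourth-order rotation C'_ijkl = R_ia R_jb R_kc R_ld C_abcd
#' (implemented via the Kronecker square of the rotation matrix on the 9x9
#' unfolding) for a right-handed rotation by `theta` degrees about the
#' laboratory e1 axis. Rotating by `90 - theta_MCF` brings a material frame
#' with fiber axis along e3 to a configuration with fiber out-of-plane
#' angle `theta_MCF`.
#'
#' @param tensor a `stiffness_tensor` (or bare 6x6 matrix).
#' @param theta rotation angle in degrees.
#' @return rotated `stiffness_tensor`; the cumulative `rotation` metadata
#'   is updated.
#' @export
rotate_stiffness <- function(tensor, theta) {
  C <- as_stiffness_matrix(tensor)
  a <- theta * pi / 180
  R <- matrix(c(1, 0, 0,
                0, cos(a), -sin(a),
                0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  Cf <- voigt_to_full(C)
  C9 <- matrix(Cf, 9, 9)  # column-major (ij) x (kl) unfolding
  K <- kronecker(R, R)
  C9r <- K %*% C9 %*% t(K)
  Cfr <- array(C9r, c(3, 3, 3, 3))
  out <- list(matrix = full_to_voigt(Cfr),
              constants = if (inherits(tensor, "stiffness_tensor"))
                tensor$constants else NULL,
              rotation = (if (inherits(tensor, "stiffness_tensor"))
                tensor$rotation else 0) + theta)
  class(out) <- "stiffness_tensor"
  out
}
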