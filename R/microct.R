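# Tissue mineral density (TMD) from calibrated micro-CT volumes.
#
# Raw grey values relate to hydroxyapatite-equivalent density by a linear
# calibration density = slope * grey + intercept (mgHA/cm3). TMD is the
# mean calibrated density over the cortical mask.

#' Apply a linear density calibration to a grey-value volume
#'
#' @param grey 3-D array of raw grey values.
#' @param slope,intercept linear calibration (slope must be finite and
#'   non-zero).
#' @param voxel_size voxel edge length in micrometers.
#' @param mask optional logical/0-1 array of the same shape (cortical
#'   bone).
#' @return object of class `calibrated_volume` with the `density` array
#'   (mgHA/cm3), `voxel_size`, `mask` and the calibration used.
#' @export
calibrate_volume <- function(grey, slope, intercept, voxel_size = 10,
                             mask = NULL) {
  stopifnot(is.finite(slope), slope != 0, voxel_size > 0)
  if (!is.null(mask) && !identical(dim(mask), dim(grey))) {
    stop("mask must have the same shape as the volume")
  }
  structure(list(density = slope * grey + intercept,
                 voxel_size = voxel_size,
                 mask = mask,
                 calibration = c(slope = slope, intercept = intercept)),
            class = "calibrated_volume")
}

#' @export
print.calibrated_volume <- function(x, ...) {
  cat(sprintf("Calibrated volume %s, voxel %.1f um, %s\n",
              paste(dim(x$density), collapse = "x"), x$voxel_size,
              if (is.null(x$mask)) "no mask" else
                sprintf("mask with %d voxels", sum(x$mask > 0))))
  invisible(x)
}

#' Tissue mineral density of a masked volume
#'
#' Mean calibrated density over the cortical mask. If neither a mask nor a
#' threshold is given, a two-cluster k-means split of the density values
#' provides a standalone segmentation fallback (voxels in the
#' high-density cluster).
#'
#' @param volume a `calibrated_volume`.
#' @param mask logical/0-1 array overriding the volume's own mask.
#' @param threshold scalar density threshold (mgHA/cm3) as an alternative
#'   to a mask.
#' @return TMD in mgHA/cm3, with attribute `"n_voxels"`.
#' @export
compute_tmd <- function(volume, mask = NULL, threshold = NULL) {
  stopifnot(inherits(volume, "calibrated_volume"))
  dens <- volume$density
  sel <- if (!is.null(mask)) {
    if (!identical(dim(mask), dim(dens))) stop("mask shape mismatch")
    mask > 0
  } else if (!is.null(threshold)) {
    dens >= threshold
  } else if (!is.null(volume$mask)) {
    volume$mask > 0
  } else {
    v <- as.numeric(dens)
    km <- kmeans(v, centers = range(v) + c(1e-6, -1e-6), iter.max = 50)
    hi <- which.max(km$centers)
    array(km$cluster == hi, dim(dens))
  }
  n <- sum(sel)
  if (n == 0) stop("empty voxel selection; TMD undefined")
  structure(mean(dens[sel]), n_voxels = n)
}
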