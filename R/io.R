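# Delimited-text and TIFF interchange for curves, spectra, site tables
# and volumes. All text formats carry a small '#'-prefixed metadata
# header; volumes are multi-page 32-bit float TIFFs.

write_header <- function(con, meta) {
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, paste(meta[[nm]], collapse = " ")),
               con)
  }
}

read_header <- function(path) {
  lines <- readLines(path, n = 100)
  hdr <- grep("^# ", lines, value = TRUE)
  out <- list()
  for (l in hdr) {
    kv <- sub("^# ", "", l)
    key <- sub(":.*$", "", kv)
    out[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  out
}

#' Write / read a microtensile record
#'
#' Tab-separated time / force (micro-N) / displacement (nm) with the gauge
#' geometry in the header.
#'
#' @param curve a `tensile_curve` carrying raw channels.
#' @param path file path.
#' @return `read_tensile_curve` returns a `tensile_curve`.
#' @export
write_tensile_curve <- function(curve, path) {
  stopifnot(inherits(curve, "tensile_curve"), !is.null(curve$raw))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(id = curve$id,
                         width_um = curve$geometry$width,
                         thickness_um = curve$geometry$thickness,
                         length_um = curve$geometry$length))
  writeLines("time_s\tforce_uN\tdisplacement_nm", con)
  utils::write.table(format(curve$raw, digits = 12), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tensile_curve
#' @export
read_tensile_curve <- function(path) {
  h <- read_header(path)
  d <- read.delim(path, comment.char = "#")
  geometry <- list(width = as.numeric(h$width_um),
                   thickness = as.numeric(h$thickness_um),
                   length = as.numeric(h$length_um))
  curve <- compute_stress_strain(d$force_uN, d$displacement_nm, geometry,
                                 time = d$time_s, id = h$id %||% NA)
  curve$raw <- data.frame(time = d$time_s, force = d$force_uN,
                          displacement = d$displacement_nm)
  curve
}

#' Write / read an indentation record
#'
#' Tab-separated time / load (mN) / depth (nm) / segment label.
#'
#' @param curve an `indentation_curve`.
#' @param path file path.
#' @return `read_indentation_curve` returns an `indentation_curve`.
#' @export
write_indentation_curve <- function(curve, path) {
  seg_lab <- ifelse(curve$segments$load, "load",
                    ifelse(curve$segments$hold, "hold", "unload"))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(id = curve$id,
                         h_max_nm = curve$protocol$h_max,
                         hold_time_s = curve$protocol$hold_time))
  writeLines("time_s\tload_mN\tdepth_nm\tsegment", con)
  utils::write.table(cbind(format(curve$data, digits = 12), seg_lab), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_indentation_curve
#' @export
read_indentation_curve <- function(path) {
  h <- read_header(path)
  d <- read.delim(path, comment.char = "#",
                  col.names = c("time", "load", "depth", "segment"))
  structure(list(
    data = data.frame(time = d$time, load = d$load, depth = d$depth),
    segments = list(load = d$segment == "load",
                    hold = d$segment == "hold",
                    unload = d$segment == "unload"),
    protocol = list(h_max = as.numeric(h$h_max_nm %||% NA),
                    hold_time = as.numeric(h$hold_time_s %||% NA)),
    truth = NULL, id = h$id %||% NA
  ), class = "indentation_curve")
}

#' Write / read a polarized Raman line scan
#'
#' One wide tab-separated table: wavenumber column plus one intensity
#' column per (position, polarization) pair, with the layout in the
#' header.
#'
#' @param scan a `polarized_line_scan`.
#' @param path file path.
#' @return `read_polarized_scan` returns a `polarized_line_scan`.
#' @export
write_polarized_scan <- function(scan, path) {
  pol <- vapply(scan$positions[[1]]$spectra, `[[`, numeric(1),
                "polarization")
  cols <- do.call(cbind, lapply(scan$positions, function(p) {
    do.call(cbind, lapply(p$spectra, `[[`, "intensity"))
  }))
  colnames(cols) <- as.vector(outer(
    pol, seq_along(scan$positions),
    function(a, p) sprintf("p%02d_pol%03d", p, a)))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(
    id = scan$id, n_positions = length(scan$positions),
    pol_angles = paste(pol, collapse = ","),
    offsets_um = paste(vapply(scan$positions, `[[`, numeric(1),
                              "offset_um"), collapse = ",")))
  writeLines(paste(c("wavenumber", colnames(cols)), collapse = "\t"), con)
  utils::write.table(cbind(scan$wavenumber, signif(cols, 10)), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_polarized_scan
#' @export
read_polarized_scan <- function(path) {
  h <- read_header(path)
  d <- read.delim(path, comment.char = "#")
  pol <- as.numeric(strsplit(h$pol_angles, ",")[[1]])
  offs <- as.numeric(strsplit(h$offsets_um, ",")[[1]])
  np <- as.integer(h$n_positions)
  positions <- lapply(seq_len(np), function(p) {
    spectra <- lapply(seq_along(pol), function(a) {
      col <- sprintf("p%02d_pol%03d", p, pol[a])
      list(polarization = pol[a], intensity = d[[col]])
    })
    list(offset_um = offs[p], spectra = spectra)
  })
  structure(list(wavenumber = d$wavenumber, positions = positions,
                 truth = NULL, id = h$id %||% NA),
            class = "polarized_line_scan")
}

#' Write / read a micro-CT volume as multi-page float TIFF
#'
#' The grey volume and its cortical mask are written as z-stacks of
#' 32-bit float pages; the calibration travels in a sidecar text file
#' `<path>.meta`.
#'
#' @param volume a `microct_volume`.
#' @param path TIFF path.
#' @return `read_microct_volume` returns a `microct_volume` (without
#'   generation truth).
#' @export
write_microct_volume <- function(volume, path) {
  gmax <- max(abs(volume$grey))
  pages <- lapply(seq_len(dim(volume$grey)[3]), function(z) {
    volume$grey[, , z] / gmax
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  mask_path <- paste0(path, ".mask.tif")
  tiff::writeTIFF(lapply(seq_len(dim(volume$mask)[3]), function(z) {
    volume$mask[, , z] * 1.0
  }), mask_path, bits.per.sample = 32L)
  writeLines(c(sprintf("slope: %g", volume$calibration[["slope"]]),
               sprintf("intercept: %g", volume$calibration[["intercept"]]),
               sprintf("voxel_size: %g", volume$voxel_size),
               sprintf("grey_scale: %g", gmax),
               sprintf("id: %s", volume$id)),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_microct_volume
#' @export
read_microct_volume <- function(path) {
  meta <- read.delim(paste0(path, ".meta"), sep = ":", header = FALSE,
                     strip.white = TRUE, row.names = 1)
  val <- function(k) meta[k, 1]
  pages <- tiff::readTIFF(path, all = TRUE)
  grey <- simplify2array(pages) * as.numeric(val("grey_scale"))
  mask <- simplify2array(tiff::readTIFF(paste0(path, ".mask.tif"),
                                        all = TRUE)) > 0.5
  structure(list(grey = grey, mask = mask,
                 voxel_size = as.numeric(val("voxel_size")),
                 calibration = c(slope = as.numeric(val("slope")),
                                 intercept = as.numeric(val("intercept"))),
                 truth = NULL, id = val("id")),
            class = "microct_volume")
}

#' Write / read the cohort site table
#'
#' Plain CSV of the site-level table; a companion `<path>.schema` file
#' documents the columns and units.
#'
#' @param sites site data frame (truths and/or measured values).
#' @param path CSV path.
#' @return `read_site_table` returns the data frame.
#' @export
write_site_table <- function(sites, path) {
  write.csv(sites, path, row.names = FALSE)
  schema <- c(
    "site_id: unique site identifier",
    "biopsy_id: parent biopsy",
    "group: healthy / oi1 / oi3",
    "theta*: MCF out-of-plane angle, degrees",
    "dbm*: v1PO4/amide I area ratio, unitless",
    "fst: fracture surface type (axial/mixed/transversal)",
    "E_loading*: loading modulus, GPa",
    "sigma_ult*: ultimate stress, MPa",
    "eps_ult*: strain at ultimate stress, unitless",
    "E_ind*: indentation modulus, GPa",
    "H_IT*: indentation hardness, MPa",
    "W_el*, W_tot*: elastic / total indentation work, pJ",
    "tmd*: tissue mineral density, mgHA/cm3",
    "columns suffixed _true are generator truths, _meas are pipeline outputs")
  writeLines(schema, paste0(path, ".schema"))
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
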