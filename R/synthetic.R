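# Synthetic cohort generator.
#
# Generates every input the pipeline consumes: site-level ground truths
# with the statistical structure the analysis assumes, plus (optionally)
# the raw measurement records - microtensile force/displacement ramps,
# polarization-resolved Raman line scans, trapezoidal indentation curves
# and calibrated micro-CT phantoms. Each generator is the exact inverse of
# its analyzer in the zero-noise limit, so the full chain is testable
# without any external data.
#
# Ground-truth coupling laws (group-mean-centred, so configured group
# means are matched in expectation while the model structure stays
# recoverable):
#   E_ind     = mu_g + beta_dbm (DBM - E[DBM]_g) + deltaE (f(theta) - E[f]_g) + eps
#   E_loading = mu_g + a_FST - E[a_FST]_g + beta_tmd (TMD_b - TMD_g) + eps
#   sigma_ult = mu_g + rho (sd_sigma/sd_E) (E_loading - mu_E,g) + sqrt(1-rho^2) sd_sigma z

#' Cohort configuration
#'
#' Builds a validated configuration for [generate_cohort()]. The
#' `"reference"` preset mirrors the reference study conditions (one biopsy
#' per group, 8/7/8 osteonal sites, group parameters from
#' [reference_cohort_params()]); the `"wellposed"` preset keeps the
#' group-level parameters but uses 8 biopsies per group with 4 sites each
#' (TMD and biopsy intercepts varying between biopsies), which makes the
#' biopsy random effect and the TMD slope identifiable and gives the
#' mixed-model likelihood-ratio test enough biopsy-level replication for
#' its chi-square reference.
#'
#' @param preset `"reference"` or `"wellposed"`.
#' @param groups optional data frame overriding the group specifications
#'   (same columns as [reference_cohort_params()] plus optionally
#'   `n_biopsies`, `n_sites`, `tmd_sd`).
#' @param noise list of channel noise levels: `force` (micro-N),
#'   `displacement` (nm), `spectral` (relative to the amide I peak),
#'   `depth` (nm), `load` (mN), `density` (mgHA/cm3).
#' @param coupling list of generative coupling coefficients: `beta_dbm`
#'   (GPa per DBM unit), `deltaE` (GPa), `shape_sin2` (sin^2 coefficient
#'   of the true shape function), `fst_offsets` (GPa, named), `beta_tmd`
#'   (GPa per mgHA/cm3), `rho_sigma_E` (strength-modulus correlation),
#'   `biopsy_sd_frac` (between-biopsy SD as a fraction of the group SD,
#'   used when a group has more than one biopsy).
#' @param seed integer seed fanned out deterministically to all stages.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(preset = c("reference", "wellposed"),
                          groups = NULL, noise = list(),
                          coupling = list(), seed = 1) {
  preset <- match.arg(preset)
  g <- groups %||% reference_cohort_params()
  if (is.null(g$n_biopsies)) g$n_biopsies <- 1L
  if (is.null(g$tmd_sd)) g$tmd_sd <- 0
  if (preset == "wellposed" && is.null(groups)) {
    # enough biopsy-level replication for the chi-square reference of the
    # mixed-model LRT to be trustworthy
    g$n_biopsies <- 8L
    g$n_sites <- 4L
    g$tmd_sd <- 25
  }
  noise <- modifyList(list(force = 2, displacement = 2, spectral = 0.01,
                           depth = 1, load = 0.02, density = 25), noise)
  coupling <- modifyList(list(
    beta_dbm = 2.0, deltaE = 6.0, shape_sin2 = 1.0,
    fst_offsets = c(axial = 1.5, mixed = 0, transversal = -1.5),
    beta_tmd = 0.02, rho_sigma_E = 0.77, biopsy_sd_frac = 0.5,
    resid_floor_frac = 0.05
  ), coupling)
  fs <- g$fst_axial + g$fst_mixed + g$fst_transversal
  if (any(abs(fs - 1) > 1e-9)) {
    stop("FST frequencies must sum to 1 within 1e-9")
  }
  sds <- g[grep("_sd$", names(g))]
  if (any(unlist(sds) < 0)) stop("standard deviations must be >= 0")
  if (any(g$n_sites < 1)) stop("sites per biopsy must be >= 1")
  if (any(unlist(noise[c("force", "displacement", "spectral", "depth")]) < 0)) {
    stop("noise levels must be >= 0")
  }
  structure(list(preset = preset, groups = g, noise = noise,
                 coupling = coupling, seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config ('%s' preset, seed %d): %d groups\n",
              x$preset, x$seed, nrow(x$groups)))
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  %-16s %d biopsy(ies) x %d sites\n", x$groups$group[i],
                x$groups$n_biopsies[i], x$groups$n_sites[i]))
  }
  invisible(x)
}

# per-site sites in the reference preset keep the configured per-group
# totals (8/7/8 over a single biopsy); otherwise n_sites is per biopsy
sites_for <- function(gr, preset) {
  if (gr$n_biopsies == 1L) gr$n_sites else rep(gr$n_sites, gr$n_biopsies)
}

#' Generate a synthetic cohort
#'
#' Draws biopsy- and site-level ground truths from the configured group
#' distributions (truncated normal for bounded quantities) and, when
#' `level = "raw"`, also synthesizes the raw measurement bundles for every
#' site (tensile curve, polarized Raman line scan, three indentation
#' curves) and a micro-CT phantom per biopsy. Identical seed and
#' configuration give identical datasets.
#'
#' @param config a [cohort_config()].
#' @param level `"truth"` (site table only; fast) or `"raw"` (also the
#'   raw records).
#' @return object of class `cohort_dataset`: data frames `biopsies`
#'   (biopsy_id, group, tmd_true) and `sites` (ids, group, true theta /
#'   theta_sd / dbm, FST and true mechanical properties), plus `raw`
#'   (named per-site lists and per-biopsy volumes) when requested.
#' @export
generate_cohort <- function(config, level = c("truth", "raw")) {
  stopifnot(inherits(config, "cohort_config"))
  level <- match.arg(level)
  cp <- config$coupling
  set.seed(child_seed(config$seed, 1))
  f_true <- function(th) eval_shape(cp$shape_sin2, th)
  biopsies <- NULL
  sites <- NULL
  for (gi in seq_len(nrow(config$groups))) {
    gr <- as.list(config$groups[gi, ])
    nb <- gr$n_biopsies
    nsite <- sites_for(gr, config$preset)
    tmd_b <- if (nb == 1L) gr$tmd else rnorm(nb, gr$tmd, gr$tmd_sd)
    b_ids <- sprintf("%s_b%02d", gr$group, seq_len(nb))
    biopsies <- rbind(biopsies, data.frame(
      biopsy_id = b_ids, group = gr$group, tmd_true = tmd_b))
    # biopsy random intercepts (shared across properties up to scale)
    bs <- if (nb > 1L) cp$biopsy_sd_frac else 0
    re <- rnorm(nb)
    # group-level expectations of the coupled covariates
    Ef <- truncnorm_efun(f_true, gr$theta_mean, gr$theta_sd, 0, 90)
    Ef2 <- truncnorm_efun(function(t) f_true(t)^2,
                          gr$theta_mean, gr$theta_sd, 0, 90)
    var_f <- max(Ef2 - Ef^2, 0)
    Edbm <- truncnorm_mean(gr$dbm_mean, gr$dbm_sd, 0.1, Inf)
    fst_freq <- c(axial = gr$fst_axial, mixed = gr$fst_mixed,
                  transversal = gr$fst_transversal)
    off <- cp$fst_offsets[names(fst_freq)]
    Eoff <- sum(fst_freq * off)
    var_off <- sum(fst_freq * (off - Eoff)^2)
    for (bi in seq_len(nb)) {
      ns <- nsite[bi]
      theta <- rtruncnorm(ns, gr$theta_mean, gr$theta_sd, 0, 90)
      theta_sd_site <- rtruncnorm(ns, gr$theta_sd_mean, gr$theta_sd_sd,
                                  0.5, Inf)
      dbm <- rtruncnorm(ns, gr$dbm_mean, gr$dbm_sd, 0.1, Inf)
      counts <- fst_freq * ns
      fst <- if (nb == 1L && all(abs(counts - round(counts)) < 1e-9)) {
        # frequencies commensurate with the site count: use the exact
        # composition (as in the reference biopsies) in random order
        sample(rep(names(fst_freq), round(counts)))
      } else {
        sample(names(fst_freq), ns, replace = TRUE, prob = fst_freq)
      }
      resid_sd <- function(total_sd, explained_var, re_sd) {
        sqrt(max(total_sd^2 - explained_var - re_sd^2,
                 (cp$resid_floor_frac * total_sd)^2))
      }
      # indentation modulus: angle + mineralization coupling
      re_E <- bs * gr$E_ind_sd * re[bi]
      s_E <- resid_sd(gr$E_ind_sd,
                      cp$beta_dbm^2 * gr$dbm_sd^2 + cp$deltaE^2 * var_f,
                      bs * gr$E_ind_sd)
      E_ind <- gr$E_ind_mean + cp$beta_dbm * (dbm - Edbm) +
        cp$deltaE * (f_true(theta) - Ef) + re_E + rnorm(ns, 0, s_E)
      # loading modulus: FST + TMD coupling
      re_EL <- bs * gr$E_loading_sd * re[bi]
      s_EL <- resid_sd(gr$E_loading_sd, var_off, bs * gr$E_loading_sd)
      E_loading <- gr$E_loading_mean + off[fst] - Eoff +
        cp$beta_tmd * (tmd_b[bi] - gr$tmd) + re_EL + rnorm(ns, 0, s_EL)
      E_loading <- pmax(E_loading, 1)
      # ultimate stress correlated with the loading modulus
      rho <- cp$rho_sigma_E
      slope_sE <- if (gr$E_loading_sd > 0) {
        rho * gr$sigma_ult_sd / gr$E_loading_sd
      } else 0
      sigma_ult <- gr$sigma_ult_mean +
        slope_sE * (E_loading - gr$E_loading_mean) +
        sqrt(1 - rho^2) * gr$sigma_ult_sd * rnorm(ns)
      sigma_ult <- pmax(sigma_ult, 20)
      # ultimate strain, clamped to the feasible region of the curve
      # model (max slope E implies eps_ult >= sigma/E)
      eps_ult <- rtruncnorm(ns, gr$eps_ult_mean, gr$eps_ult_sd, 0.004, Inf)
      lo <- 1.02 * sigma_ult / (1000 * E_loading)
      hi <- 1.98 * sigma_ult / (1000 * E_loading)
      eps_ult <- pmin(pmax(eps_ult, lo), hi)
      H_IT <- rtruncnorm(ns, gr$H_IT_mean,
                         gr$H_IT_sd * sqrt(max(1 - bs^2, 0)), 50, Inf) +
        bs * gr$H_IT_sd * re[bi]
      W_el <- rtruncnorm(ns, gr$W_el_mean, gr$W_el_sd, 10, Inf)
      W_tot <- pmax(rtruncnorm(ns, gr$W_tot_mean, gr$W_tot_sd, 100, Inf),
                    W_el + 1)
      ductile <- runif(ns) < 0.15 & fst != "transversal"
      sites <- rbind(sites, data.frame(
        site_id = sprintf("%s_s%02d", b_ids[bi], seq_len(ns)),
        biopsy_id = b_ids[bi], group = gr$group,
        theta_true = theta, theta_sd_true = theta_sd_site,
        dbm_true = dbm, fst = fst,
        E_loading_true = E_loading, sigma_ult_true = sigma_ult,
        eps_ult_true = eps_ult, ductile_true = ductile,
        E_ind_true = E_ind, H_IT_true = H_IT,
        W_el_true = W_el, W_tot_true = W_tot,
        tmd_true = tmd_b[bi]))
    }
  }
  rownames(sites) <- NULL
  out <- structure(list(config = config, biopsies = biopsies,
                        sites = sites, raw = NULL),
                   class = "cohort_dataset")
  if (level == "raw") out$raw <- generate_raw_bundles(out)
  out
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d biopsies, %d sites%s\n",
              nrow(x$biopsies), nrow(x$sites),
              if (is.null(x$raw)) " (truth level)" else " (with raw records)"))
  print(table(x$sites$group))
  invisible(x)
}

generate_raw_bundles <- function(ds) {
  cfg <- ds$config
  nz <- cfg$noise
  sites <- ds$sites
  raw_sites <- vector("list", nrow(sites))
  names(raw_sites) <- sites$site_id
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    sd_seed <- child_seed(cfg$seed, 100 + i)
    tensile <- generate_tensile_curve(
      E_true = s$E_loading_true, sigma_ult_true = s$sigma_ult_true,
      eps_ult = s$eps_ult_true, ductile = s$ductile_true,
      noise = list(force = nz$force, displacement = nz$displacement),
      seed = sd_seed, id = s$site_id)
    scan <- generate_polarized_scan(
      theta_true = s$theta_true, dbm_true = s$dbm_true,
      position_sd = s$theta_sd_true,
      noise = list(spectral = nz$spectral),
      seed = child_seed(cfg$seed, 200 + i), id = s$site_id)
    set.seed(child_seed(cfg$seed, 300 + i))
    indents <- lapply(1:3, function(k) {
      generate_indentation_curve(
        E_true = s$E_ind_true * (1 + 0.02 * rnorm(1)),
        H_true = s$H_IT_true * (1 + 0.02 * rnorm(1)),
        noise = list(load = nz$load, depth = nz$depth),
        seed = child_seed(cfg$seed, 300 + 10 * i + k),
        id = sprintf("%s_i%d", s$site_id, k))
    })
    raw_sites[[i]] <- list(tensile = tensile, raman = scan,
                           indents = indents)
  }
  volumes <- lapply(seq_len(nrow(ds$biopsies)), function(b) {
    generate_microct_volume(ds$biopsies$tmd_true[b],
                            noise = nz$density,
                            seed = child_seed(cfg$seed, 900 + b),
                            id = ds$biopsies$biopsy_id[b])
  })
  names(volumes) <- ds$biopsies$biopsy_id
  list(sites = raw_sites, volumes = volumes)
}

#' Generate a microtensile force-displacement record
#'
#' Quasi-static ramp at constant displacement rate, sampled at
#' `sample_rate`, of a specimen whose stress-strain response rises
#' linearly with slope `E_true` and bends over a quadratic cap to the peak
#' `(eps_ult, sigma_ult_true)`; a ductile specimen continues on the
#' concave tail until `eps_fail = tail_factor * eps_ult` before the abrupt
#' fracture drop, a brittle one fractures at the peak. The peak and
#' failure strains are sampled exactly. Additive Gaussian noise goes on
#' the raw force and displacement channels.
#'
#' @param E_true loading modulus, GPa.
#' @param sigma_ult_true ultimate stress, MPa.
#' @param eps_ult strain at peak stress; default places the peak at
#'   `1.35 * sigma / E` (curvature typical of bone ECM loading curves).
#'   Clamped to the feasible band `(1.02, 1.98) * sigma / E` of the curve
#'   model with a warning.
#' @param ductile logical; add a post-peak tail.
#' @param tail_factor `eps_fail / eps_ult` for ductile specimens.
#' @param rate displacement rate in nm/s.
#' @param sample_rate sampling frequency in Hz.
#' @param geometry gauge dimensions in micrometers.
#' @param noise list with `force` (micro-N SD) and `displacement` (nm SD).
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @param id specimen identifier.
#' @return a `tensile_curve` with raw channels in `$raw` and the
#'   generating truth in `$truth`.
#' @export
generate_tensile_curve <- function(E_true, sigma_ult_true, eps_ult = NULL,
                                   ductile = FALSE, tail_factor = 1.2,
                                   rate = 5, sample_rate = 10,
                                   geometry = list(width = 5, thickness = 2,
                                                   length = 10),
                                   noise = list(force = 0, displacement = 0),
                                   seed = NULL, id = "tensile") {
  if (E_true <= 0 || sigma_ult_true <= 0) {
    stop("modulus and ultimate stress must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  eps_lin <- sigma_ult_true / (1000 * E_true)
  if (is.null(eps_ult)) eps_ult <- 1.35 * eps_lin
  k <- eps_ult / eps_lin
  if (k < 1.02 || k > 1.98) {
    warning("eps_ult outside the feasible curvature band; clamped")
    k <- min(max(k, 1.02), 1.98)
    eps_ult <- k * eps_lin
  }
  x1 <- 2 / k - 1
  cc <- k^2 / (4 * (k - 1))
  xf <- if (ductile) tail_factor else 1
  strain_rate <- rate / (geometry$length * 1000)
  eps_fail <- xf * eps_ult
  grid <- seq(0, eps_fail, by = strain_rate / sample_rate)
  grid <- sort(unique(c(grid, x1 * eps_ult, eps_ult, eps_fail)))
  x <- grid / eps_ult
  y <- ifelse(x <= x1, k * x, 1 - cc * (1 - x)^2)
  stress <- sigma_ult_true * y
  # abrupt fracture: two trailing samples at zero stress
  dstep <- strain_rate / sample_rate
  strain <- c(grid, eps_fail + dstep, eps_fail + 2 * dstep)
  stress <- c(stress, 0, 0)
  time <- strain / strain_rate
  area <- geometry$width * geometry$thickness
  force <- stress * area + rnorm(length(stress), 0, noise$force %||% 0)
  disp <- strain * geometry$length * 1000 +
    rnorm(length(strain), 0, noise$displacement %||% 0)
  curve <- compute_stress_strain(force, disp, geometry, time = time, id = id)
  curve$raw <- data.frame(time = time, force = force, displacement = disp)
  curve$truth <- list(E_loading = E_true, sigma_ult = sigma_ult_true,
                      eps_ult = eps_ult, eps_fail = eps_fail,
                      ductile = ductile)
  curve
}

#' Generate a polarization-resolved Raman line scan
#'
#' Builds `positions x length(pol_angles)` spectra as Lorentzian band
#' superpositions on a quadratic baseline. Polarization-dependent bands
#' (amide I, v1PO4) are modulated as `1 + kappa cos^2(phi)` (Malus-type);
#' amide III is polarization-independent. Band areas are scaled so that
#' the polarization-averaged amide I / amide III ratio equals the inverse
#' calibration at the position's true angle and the averaged v1PO4 /
#' amide I ratio equals `dbm_true`, making the generator the exact inverse
#' of the analyzer at zero noise. Bands are given smooth compact support
#' (cosine taper outside their fit windows) so that baseline anchors away
#' from the windows sit exactly on the quadratic baseline.
#'
#' @param theta_true site-mean out-of-plane angle, degrees in \[0, 90\].
#' @param dbm_true true mineral-to-matrix ratio (> 0).
#' @param positions number of line-scan positions.
#' @param position_sd SD of the per-position angle around `theta_true`
#'   (lamellar variation), degrees.
#' @param spacing lateral spacing in micrometers.
#' @param pol_angles polarization angles in degrees.
#' @param wavenumber wavenumber grid in cm-1.
#' @param kappa polarization modulation depth of the dependent bands.
#' @param baseline quadratic baseline coefficients (counts; evaluated in
#'   the centred variable `(x - 1300)/1000`).
#' @param noise list with `spectral`: Gaussian SD relative to the amide I
#'   peak amplitude.
#' @param calibration a [raman_calibration()].
#' @param bands band definitions.
#' @param taper width (cm-1) of the cosine taper outside each window.
#' @param seed integer seed.
#' @param id site identifier.
#' @return object of class `polarized_line_scan`.
#' @export
generate_polarized_scan <- function(theta_true, dbm_true, positions = 7,
                                    position_sd = 0, spacing = 3,
                                    pol_angles = seq(0, 180, by = 15),
                                    wavenumber = seq(800, 1800, by = 1),
                                    kappa = 0.8,
                                    baseline = c(50, 20, 30),
                                    noise = list(spectral = 0),
                                    calibration = raman_calibration(),
                                    bands = raman_bands(),
                                    taper = 40, seed = NULL,
                                    id = "scan") {
  if (theta_true < 0 || theta_true > 90) {
    stop("theta_true must lie in [0, 90] degrees")
  }
  stopifnot(dbm_true > 0)
  if (!is.null(seed)) set.seed(seed)
  theta_pos <- rtruncnorm(positions, theta_true, position_sd, 0, 90)
  phi <- pol_angles * pi / 180
  s_mod <- 1 + kappa * cos(phi)^2
  s_norm <- s_mod / mean(s_mod)
  xb <- (wavenumber - 1300) / 1000
  base <- baseline[1] + baseline[2] * xb + baseline[3] * xb^2
  A3 <- 100
  shape_of <- function(bd) {
    # unit-area band profile: Lorentzian sub-peaks, cosine-tapered to
    # compact support outside the fit window
    prof <- 0
    k <- length(bd$centers)
    for (j in seq_len(k)) {
      prof <- prof + (1 / k) *
        lorentzian(wavenumber, bd$centers[j], bd$widths[j], 1) /
        (pi * bd$widths[j] * 1 / 1)  # amplitude 1 -> area pi*w; normalize
    }
    lo <- bd$window[1]; hi <- bd$window[2]
    w <- rep(1, length(wavenumber))
    left <- wavenumber < lo
    w[left] <- ifelse(wavenumber[left] > lo - taper,
                      cos((lo - wavenumber[left]) / taper * pi / 2)^2, 0)
    right <- wavenumber > hi
    w[right] <- ifelse(wavenumber[right] < hi + taper,
                       cos((wavenumber[right] - hi) / taper * pi / 2)^2, 0)
    prof * w
  }
  prof <- lapply(bands, shape_of)
  pos_list <- vector("list", positions)
  for (p in seq_len(positions)) {
    r_p <- calibration$inverse(theta_pos[p])
    A1 <- r_p * A3
    Apo <- dbm_true * A1
    spectra <- vector("list", length(pol_angles))
    for (a in seq_along(pol_angles)) {
      a1 <- A1 * s_norm[a]
      apo <- Apo * s_norm[a]
      intensity <- base +
        a1 * prof$amide1 + A3 * prof$amide3 + apo * prof$v1po4
      peak_amp <- a1 * max(prof$amide1)
      if ((noise$spectral %||% 0) > 0) {
        intensity <- intensity +
          rnorm(length(intensity), 0, noise$spectral * peak_amp)
      }
      spectra[[a]] <- list(polarization = pol_angles[a],
                           intensity = intensity)
    }
    pos_list[[p]] <- list(offset_um = (p - 1) * spacing,
                          theta_true = theta_pos[p], spectra = spectra)
  }
  structure(list(wavenumber = wavenumber, positions = pos_list,
                 truth = list(theta = theta_true, dbm = dbm_true,
                              theta_positions = theta_pos),
                 id = id),
            class = "polarized_line_scan")
}

#' Generate a trapezoidal nanoindentation record
#'
#' Berkovich contact with Kick's-law loading `P = P_max (h/h_max)^2` to
#' the target depth, a constant-force hold, and power-law unloading
#' `P = P_max ((h - h_f)/(h_max - h_f))^m`. The final depth, peak load,
#' contact stiffness and residual depth are solved so that Oliver-Pharr
#' analysis of the noise-free record returns exactly (`E_true`, `H_true`)
#' for the given tip. `elastic = TRUE` instead makes the unload retrace
#' the loading curve (reversible limit, `W_el = W_tot`).
#'
#' @param E_true indentation modulus, GPa.
#' @param H_true hardness, MPa.
#' @param protocol list with `load_rate` (mN/min), `hold_time` (s),
#'   `unload_rate` (mN/min), `h_max` (nm).
#' @param tip a [berkovich_tip()].
#' @param m_unload unload power-law exponent.
#' @param creep additional creep depth accumulated over the hold (nm).
#' @param elastic logical; reversible limit.
#' @param noise list with `load` (mN SD) and `depth` (nm SD).
#' @param sample_rate sampling frequency, Hz.
#' @param epsilon Oliver-Pharr geometry factor used in the inverse design.
#' @param seed integer seed.
#' @param id identifier.
#' @return object of class `indentation_curve` with `data` (time, load,
#'   depth), logical `segments`, the `protocol` and the generating
#'   `truth`.
#' @export
generate_indentation_curve <- function(E_true, H_true,
                                       protocol = list(load_rate = 100,
                                                       hold_time = 30,
                                                       unload_rate = 400,
                                                       h_max = 1000),
                                       tip = berkovich_tip(),
                                       m_unload = 1.5, creep = 0,
                                       elastic = FALSE,
                                       noise = list(load = 0, depth = 0),
                                       sample_rate = 20, epsilon = 0.75,
                                       seed = NULL, id = "indent") {
  stopifnot(E_true > 0, H_true > 0)
  if (!is.null(seed)) set.seed(seed)
  h_max <- protocol$h_max
  H_gpa <- H_true / 1000
  E_r <- 1 / (1 / E_true + (1 - tip$nu_tip^2) / tip$E_tip)
  # h_c from h_c = h_max - eps*P_max/S with P_max = H A, S = 2 E_r sqrt(A/pi)
  h_c <- h_max / (1 + epsilon / 2 * sqrt(tip$area_coeff * pi) * H_gpa / E_r)
  A <- tip$area(h_c)                       # nm^2
  P_max <- H_gpa * A * 1e-6                # mN
  S <- 2 * E_r * 1e-6 * sqrt(A / pi)       # mN/nm
  if (elastic) {
    m_unload <- 2
    h_f <- 0
  } else {
    h_f <- h_max - m_unload * P_max / S
    if (h_f < 0) stop("inconsistent E/H pair: negative residual depth")
  }
  t_load <- P_max / (protocol$load_rate / 60)
  tl <- sort(unique(c(seq(0, t_load, by = 1 / sample_rate), t_load)))
  Pl <- protocol$load_rate / 60 * tl
  hl <- h_max * sqrt(Pl / P_max)
  th <- seq(0, protocol$hold_time, by = 1 / sample_rate)
  th <- sort(unique(c(th, protocol$hold_time)))
  Ph <- rep(P_max, length(th))
  hh <- h_max + creep * sqrt(th / max(protocol$hold_time, 1e-9))
  h_top <- max(hh)
  t_unl <- P_max / (protocol$unload_rate / 60)
  tu <- sort(unique(c(seq(0, t_unl, by = 1 / sample_rate), t_unl)))
  Pu <- P_max - protocol$unload_rate / 60 * tu
  Pu[Pu < 0] <- 0
  hu <- h_f + (h_top - h_f) * (Pu / P_max)^(1 / m_unload)
  time <- c(tl, t_load + th[-1], t_load + protocol$hold_time + tu[-1])
  load <- c(Pl, Ph[-1], Pu[-1])
  depth <- c(hl, hh[-1], hu[-1])
  n_l <- length(tl); n_h <- length(th) - 1; n_u <- length(tu) - 1
  seg <- list(load = c(rep(TRUE, n_l), rep(FALSE, n_h + n_u)),
              hold = c(rep(FALSE, n_l), rep(TRUE, n_h), rep(FALSE, n_u)),
              unload = c(rep(FALSE, n_l + n_h), rep(TRUE, n_u)))
  load <- load + rnorm(length(load), 0, noise$load %||% 0)
  depth <- depth + rnorm(length(depth), 0, noise$depth %||% 0)
  structure(list(
    data = data.frame(time = time, load = load, depth = depth),
    segments = seg, protocol = protocol,
    truth = list(E_ind = E_true, H_IT = H_true, P_max = P_max,
                 stiffness = S, h_c = h_c, h_f = h_f, m = m_unload),
    id = id
  ), class = "indentation_curve")
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat(sprintf(
    "Indentation curve '%s': %d samples, P_max %.2f mN, depth %.0f nm\n",
    x$id, nrow(x$data), max(x$data$load), max(x$data$depth)))
  invisible(x)
}

#' Generate a calibrated micro-CT phantom
#'
#' Cortical-shell phantom: a cylindrical annulus of homogeneous density
#' `tmd_true` (the cortex) embedded in a soft background, converted to raw
#' grey values through the inverse of the linear calibration. The masked
#' mean density equals `tmd_true` exactly before noise.
#'
#' @param tmd_true tissue mineral density, mgHA/cm3 (> 0).
#' @param shape voxel dimensions (nx, ny, nz).
#' @param voxel_size voxel edge in micrometers.
#' @param calibration named vector `c(slope, intercept)` of the grey ->
#'   density map.
#' @param background background density, mgHA/cm3.
#' @param noise Gaussian density noise SD, mgHA/cm3.
#' @param seed integer seed.
#' @param id biopsy identifier.
#' @return object of class `microct_volume`: raw `grey` array, logical
#'   `mask`, `voxel_size`, `calibration`, `truth`.
#' @export
generate_microct_volume <- function(tmd_true, shape = c(40, 40, 10),
                                    voxel_size = 10,
                                    calibration = c(slope = 0.5,
                                                    intercept = -50),
                                    background = 100, noise = 0,
                                    seed = NULL, id = "biopsy") {
  stopifnot(tmd_true > 0, length(shape) == 3)
  if (!is.null(seed)) set.seed(seed)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`))
  ring <- r >= 0.25 * nx & r <= 0.45 * nx
  mask <- array(rep(ring, nz), dim = shape)
  if (!any(mask)) stop("degenerate phantom: empty cortical mask")
  density <- array(background, dim = shape)
  density[mask] <- tmd_true
  if (noise > 0) density <- density + rnorm(length(density), 0, noise)
  grey <- (density - calibration[["intercept"]]) / calibration[["slope"]]
  structure(list(grey = grey, mask = mask, voxel_size = voxel_size,
                 calibration = calibration,
                 truth = list(tmd = tmd_true), id = id),
            class = "microct_volume")
}
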