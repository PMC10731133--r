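# End-to-end orchestration: generate -> analyze -> model -> report.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a cohort with raw records, runs every analysis stage
#' (tensile extraction, qPRS, Oliver-Pharr with per-osteon aggregation,
#' TMD), fits the tensile multilinear models, the strength-modulus
#' correlation and the combined indentation model, runs the group
#' statistics, and builds the loading-mode comparison of the measured
#' tension summaries against the bundled compression reference. All
#' intermediates are returned and, when `output_dir` is given, persisted
#' as delimited text together with a manifest (config hash + seed).
#'
#' @param config a [cohort_config()].
#' @param output_dir optional directory for the artifacts.
#' @param constants elastic constants for the shape-function stage.
#' @param calibration Raman orientation calibration (must match the
#'   generator's).
#' @param shape_grid angle grid for the indentation-modulus profile.
#' @param verbose print stage progress.
#' @return object of class `pipeline_run` with the cohort, measured site
#'   table, model fits, statistics, comparison table and manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL,
                         constants = elastic_constants(),
                         calibration = raman_calibration(),
                         shape_grid = seq(0, 90, by = 10),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  say("generating cohort (seed %d)", config$seed)
  cohort <- stage("generate", generate_cohort(config, level = "raw"))
  sites <- cohort$sites

  say("tensile analysis (%d sites)", nrow(sites))
  tens <- stage("tensile", lapply(seq_len(nrow(sites)), function(i) {
    extract_tensile_properties(cohort$raw$sites[[i]]$tensile,
                               fst = sites$fst[i])
  }))
  say("qPRS analysis")
  raman <- stage("raman", lapply(cohort$raw$sites, function(b) {
    analyze_polarized_scan(b$raman, calibration = calibration)
  }))
  say("indentation analysis")
  indent <- stage("indent", lapply(cohort$raw$sites, function(b) {
    aggregate_osteon(lapply(b$indents, analyze_indentation))
  }))
  say("micro-CT TMD")
  tmd <- stage("tmd", vapply(cohort$raw$volumes, function(v) {
    cal <- calibrate_volume(v$grey, v$calibration[["slope"]],
                            v$calibration[["intercept"]],
                            voxel_size = v$voxel_size, mask = v$mask)
    as.numeric(compute_tmd(cal))
  }, numeric(1)))

  measured <- data.frame(
    site_id = sites$site_id, biopsy_id = sites$biopsy_id,
    group = sites$group, fst = sites$fst,
    E_loading_meas = vapply(tens, `[[`, numeric(1), "E_loading"),
    sigma_ult_meas = vapply(tens, `[[`, numeric(1), "sigma_ult"),
    eps_ult_meas = vapply(tens, `[[`, numeric(1), "eps_ult"),
    failure_class = vapply(tens, `[[`, character(1), "failure_class"),
    theta_meas = vapply(raman, `[[`, numeric(1), "theta_mean"),
    theta_sd_meas = vapply(raman, `[[`, numeric(1), "theta_sd"),
    dbm_meas = vapply(raman, `[[`, numeric(1), "dbm"),
    E_ind_meas = vapply(indent, `[[`, numeric(1), "E_ind"),
    H_IT_meas = vapply(indent, `[[`, numeric(1), "H_IT"),
    W_el_meas = vapply(indent, `[[`, numeric(1), "W_el"),
    W_tot_meas = vapply(indent, `[[`, numeric(1), "W_tot"),
    tmd_meas = unname(tmd[sites$biopsy_id]))

  say("models")
  models <- stage("model", {
    profile <- indentation_modulus_profile(constants, shape_grid)
    shape <- fit_shape_function(profile$theta, profile$modulus, constants)
    list(
      shape = shape,
      tensile_E = fit_tensile_model(data.frame(
        value = measured$E_loading_meas, fst = measured$fst,
        tmd = measured$tmd_meas)),
      tensile_sigma = fit_tensile_model(data.frame(
        value = measured$sigma_ult_meas, fst = measured$fst,
        tmd = measured$tmd_meas)),
      correlation = correlate_strength_modulus(data.frame(
        sigma_ult = measured$sigma_ult_meas,
        E_loading = measured$E_loading_meas)),
      combined = fit_combined_model(data.frame(
        E_ind = measured$E_ind_meas,
        theta = pmin(pmax(measured$theta_meas, 0), 90),
        dbm = measured$dbm_meas), shape)
    )
  })

  say("group statistics")
  stat_props <- c("E_loading_meas", "sigma_ult_meas", "eps_ult_meas",
                  "E_ind_meas", "H_IT_meas", "W_el_meas", "W_tot_meas",
                  "dbm_meas", "theta_meas", "theta_sd_meas")
  stats <- stage("stats", lapply(setNames(stat_props, stat_props),
                                 function(p) {
    lrt <- suppressWarnings(lrt_group_effect(measured[[p]],
                                             measured$group,
                                             measured$biopsy_id))
    dunn <- dunn_posthoc(measured[[p]], measured$group)
    list(lrt = lrt, dunn = dunn)
  }))

  say("loading-mode comparison")
  tension_means <- do.call(rbind, lapply(
    list(c("strength", "sigma_ult_meas"),
         c("strain", "eps_ult_meas"),
         c("modulus", "E_loading_meas")),
    function(pp) {
      agg <- tapply(measured[[pp[2]]], measured$group, mean)
      data.frame(property = pp[1], group = names(agg),
                 mean = as.numeric(agg))
    }))
  ref <- reference_loading_mode_means()
  comparison <- stage("comparison", loading_mode_comparison(
    tension_means, ref[ref$mode == "compression", ]))

  run <- structure(list(
    config = config, cohort = cohort, measured = measured,
    models = models, stats = stats, comparison = comparison,
    tmd = tmd,
    manifest = list(seed = config$seed,
                    preset = config$preset,
                    n_sites = nrow(measured),
                    config_hash = config_hash(config),
                    created = "run")),
    class = "pipeline_run")
  if (!is.null(output_dir)) persist_run(run, output_dir)
  run
}

config_hash <- function(config) {
  x <- deparse(config[c("preset", "groups", "noise", "coupling", "seed")])
  f <- tempfile()
  writeLines(x, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

persist_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  site_tab <- merge(run$cohort$sites, run$measured,
                    by = c("site_id", "biopsy_id", "group", "fst"))
  write_site_table(site_tab, file.path(output_dir, "sites.csv"))
  write.csv(run$cohort$biopsies, file.path(output_dir, "biopsies.csv"),
            row.names = FALSE)
  write.csv(run$comparison, file.path(output_dir, "comparison.csv"),
            row.names = FALSE)
  writeLines(write_report(run), file.path(output_dir, "report.txt"))
  jsonlite::write_json(run$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run (%s preset, seed %d): %d sites\n",
              x$config$preset, x$config$seed, nrow(x$measured)))
  cat(sprintf("  combined model R2 = %.3f; tensile adj R2 (E) = %.3f\n",
              x$models$combined$r_squared,
              x$models$tensile_E$adj_r_squared))
  invisible(x)
}

#' Human-readable run report
#'
#' Group descriptives (mean +/- SD, one-decimal convention), model
#' coefficients, likelihood-ratio and post hoc p-values, and the
#' loading-mode comparison table of a completed run.
#'
#' @param run a `pipeline_run`.
#' @return character vector of report lines.
#' @export
write_report <- function(run) {
  m <- run$measured
  fmt <- function(x, d = 1) sprintf("%.*f", d, round_half_away(x, d))
  lines <- c("Bone ECM micromechanics synthetic-cohort report",
             sprintf("seed %d, preset '%s', %d sites, config %s",
                     run$config$seed, run$config$preset, nrow(m),
                     run$manifest$config_hash),
             "", "Group descriptives (mean +/- SD):")
  props <- c(sigma_ult_meas = "sigma_ult [MPa]",
             eps_ult_meas = "eps_ult [-]",
             E_loading_meas = "E_loading [GPa]",
             E_ind_meas = "E_ind [GPa]", H_IT_meas = "H_IT [MPa]",
             W_el_meas = "W_el [pJ]", W_tot_meas = "W_tot [pJ]",
             dbm_meas = "v1PO4/amide I [-]",
             theta_meas = "theta_MCF [deg]")
  for (p in names(props)) {
    dg <- if (p == "eps_ult_meas") 3 else 1
    row <- tapply(m[[p]], m$group, function(v)
      sprintf("%s +/- %s", fmt(mean(v), dg), fmt(sd(v), dg)))
    lines <- c(lines, sprintf("  %-18s %s", props[[p]],
                              paste(sprintf("%s: %s", names(row), row),
                                    collapse = "  ")))
    lrt <- run$stats[[p]]
    if (!is.null(lrt)) {
      lines <- c(lines, sprintf("  %-18s LRT p = %.3g", "", lrt$lrt$p_value))
    }
  }
  if (length(run$tmd)) {
    lines <- c(lines, "", "TMD per biopsy [mgHA/cm3]:",
               sprintf("  %s: %s", names(run$tmd), fmt(run$tmd)))
  } else {
    lines <- c(lines, "", "TMD section absent (no volumes in this run)")
  }
  cm <- run$models$combined
  lines <- c(lines, "",
             "Combined indentation model E_ind = alpha + beta*DBM + deltaE*f(theta):",
             sprintf("  alpha = %.2f GPa, beta = %.2f GPa/DBM, deltaE = %.2f GPa",
                     cm$alpha, cm$beta, cm$deltaE),
             sprintf("  R2 = %.3f, adj R2 = %.3f, F p = %.3g",
                     cm$r_squared, cm$adj_r_squared, cm$f_p_value),
             "",
             sprintf("Tensile models: adj R2 (E_loading) = %.3f (F p = %.3g), adj R2 (sigma_ult) = %.3f (F p = %.3g)",
                     run$models$tensile_E$adj_r_squared,
                     run$models$tensile_E$f_p_value,
                     run$models$tensile_sigma$adj_r_squared,
                     run$models$tensile_sigma$f_p_value),
             sprintf("Strength-modulus correlation: R2 = %.3f (p = %.3g)",
                     run$models$correlation$r_squared,
                     run$models$correlation$p_value),
             "", "Loading-mode comparison (tension vs compression, % change):")
  cmp <- run$comparison
  for (i in seq_len(nrow(cmp))) {
    lines <- c(lines, sprintf(
      "  %-9s %-8s %-9s tension %s vs compression %s: %s%%",
      cmp$property[i], cmp$group[i], cmp$type[i],
      signif(cmp$tension[i], 4), signif(cmp$compression[i], 4),
      fmt(cmp$relative_change[i])))
  }
  lines
}
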