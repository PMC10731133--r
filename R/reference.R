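# Bundled reference study conditions: published summary statistics for dry
# human iliac-crest cortical bone ECM from one healthy control and two
# osteogenesis imperfecta (OI type I, OI type III) biopsies. These values
# parameterize the default synthetic cohort and the tension-vs-compression
# comparison.

#' Reference cohort parameters
#'
#' Group-level means and standard deviations of the micromechanical,
#' spectroscopic and densitometric parameters of the reference cohort
#' (one transiliac biopsy per group; 8, 7 and 8 osteonal sites for the
#' healthy control, OI type I and OI type III groups). These are the
#' default targets of the synthetic cohort generator.
#'
#' Units: `E_loading` and `E_ind` GPa, `sigma_ult` MPa, `eps_ult` unitless,
#' `H_IT` MPa, `W_el` and `W_tot` pJ, `tmd` mgHA/cm3, `theta` and
#' `theta_sd` degrees, `dbm` unitless (v1PO4/amide I area ratio).
#'
#' @return data frame, one row per group, columns `<param>_mean` and
#'   `<param>_sd` plus `n_sites`, `n_biopsies`, `tmd` and the fracture
#'   surface type frequencies `fst_axial`, `fst_mixed`, `fst_transversal`.
#' @export
reference_cohort_params <- function() {
  data.frame(
    group = c("healthy", "oi1", "oi3"),
    label = c("Healthy control", "OI type I", "OI type III"),
    n_biopsies = c(1L, 1L, 1L),
    n_sites = c(8L, 7L, 8L),
    sigma_ult_mean = c(242, 359, 247),
    sigma_ult_sd = c(53, 111, 25),
    eps_ult_mean = c(0.022, 0.023, 0.020),
    eps_ult_sd = c(0.004, 0.005, 0.002),
    E_loading_mean = c(14.8, 20.4, 16.7),
    E_loading_sd = c(1.8, 4.4, 1.7),
    E_ind_mean = c(17.2, 24.9, 21.9),
    E_ind_sd = c(2.2, 1.5, 0.6),
    H_IT_mean = c(524, 907, 758),
    H_IT_sd = c(49, 137, 33),
    W_el_mean = c(1149, 1952, 1727),
    W_el_sd = c(159, 348, 183),
    W_tot_mean = c(5633, 8591, 7538),
    W_tot_sd = c(478, 1128, 392),
    tmd = c(869.8, 989.9, 979.9),
    dbm_mean = c(2.60, 3.12, 3.22),
    dbm_sd = c(0.63, 0.26, 0.19),
    theta_mean = c(39.4, 30.3, 41.8),
    theta_sd = c(14.3, 6.3, 5.4),
    theta_sd_mean = c(10.6, 11.9, 12.4),
    theta_sd_sd = c(3.6, 4.1, 4.7),
    fst_axial = c(4 / 8, 5 / 7, 0 / 8),
    fst_mixed = c(2 / 8, 1 / 7, 6 / 8),
    fst_transversal = c(2 / 8, 1 / 7, 2 / 8),
    stringsAsFactors = FALSE
  )
}

#' Reference loading-mode summary means
#'
#' Published group means of strength, strain and loading modulus for the
#' reference cohort under microtensile loading and, on the same three
#' biopsies, under micropillar compression (ultimate and, where defined,
#' 0.2 percent offset yield values). Input to
#' [loading_mode_comparison()].
#'
#' @return data frame with columns `property` (`strength` MPa, `strain`
#'   unitless, `modulus` GPa), `group`, `mode` (`tension`/`compression`),
#'   `type` (`ultimate`/`yield`) and `mean`.
#' @export
reference_loading_mode_means <- function() {
  g <- c("healthy", "oi1", "oi3")
  rbind(
    data.frame(property = "strength", group = g, mode = "tension",
               type = "ultimate", mean = c(242, 359, 247)),
    data.frame(property = "strength", group = g, mode = "compression",
               type = "ultimate", mean = c(584, 753, 770)),
    data.frame(property = "strength", group = g, mode = "compression",
               type = "yield", mean = c(359, 455, 397)),
    data.frame(property = "strain", group = g, mode = "tension",
               type = "ultimate", mean = c(0.022, 0.023, 0.020)),
    data.frame(property = "strain", group = g, mode = "compression",
               type = "ultimate", mean = c(0.067, 0.078, 0.142)),
    data.frame(property = "strain", group = g, mode = "compression",
               type = "yield", mean = c(0.023, 0.028, 0.024)),
    data.frame(property = "modulus", group = g, mode = "tension",
               type = "ultimate", mean = c(14.8, 20.4, 16.7)),
    data.frame(property = "modulus", group = g, mode = "compression",
               type = "ultimate", mean = c(16.8, 17.6, 17.9))
  )
}
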