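#' Configuration for the synthetic linked-cohort generator
#'
#' Bundles every parameter of the generator: cohort size and composition,
#' exposure and diagnosis-coding prevalences, per-stratum risk-factor
#' distributions, entry/follow-up structure, competing non-CVD mortality,
#' missingness rates, and the sex-specific excess event risk carried by the
#' exposed (mental-health service contact) group. Defaults emulate a large
#' primary-care risk-assessment cohort linked to specialist mental-health
#' contact records: ~5.8% exposure prevalence, ~15.5% of the exposed with a
#' recorded functional-psychosis (F20-F31) diagnosis, ~36.2% of exposed
#' persons with no diagnosis coded at all, staggered accelerating entry over
#' a 12.2-year study window giving a mean realized follow-up of about 4.5
#' years, censoring at non-CVD death, and excess risk factors 1.64 (women)
#' and 1.29 (men).
#'
#' @param n_total Number of persons to generate.
#' @param seed Integer seed; identical `(config, seed)` pairs regenerate
#'   byte-identical tables.
#' @param sex_split Proportion female.
#' @param smi_prevalence Proportion with qualifying mental-health service
#'   contact in the 5 years before index.
#' @param psychosis_fraction_of_smi Proportion of the exposed with any
#'   recorded F20-F31 diagnosis.
#' @param missing_diagnosis_fraction Probability that a contact's diagnosis
#'   code is missing.
#' @param excess_mode `"risk_ratio"` (the excess factor multiplies the
#'   cumulative event risk, so the observed:predicted ratio equals the
#'   factor by construction) or `"hazard_ratio"` (the factor multiplies the
#'   hazard, i.e. `exp(LP)`).
#' @param excess_factor_female,excess_factor_male Positive multipliers
#'   applied to exposed persons' event risk (or hazard).
#' @param followup_max_years Maximum administrative follow-up.
#' @param entry_window_years Length of the entry (accrual) window; study
#'   end is this long after study start.
#' @param accrual_shape Power governing how entry concentrates late in the
#'   window (entry = window * U^shape with U uniform; shape < 1 means
#'   accelerating uptake). The default is tuned so mean realized follow-up
#'   is about 4.5 years when `entry_window_years = followup_max_years = 12.2`.
#' @param noncvd_death_rate Constant per-year hazard of non-CVD death
#'   (independent censoring).
#' @param missing_smoking,missing_tchdl,missing_bmi Missingness
#'   probabilities applied to the released person table.
#' @param prior_cvd_rate,prior_renal_rate Probabilities of the exclusion
#'   flags.
#' @param out_of_age_fraction Fraction of generated persons outside the
#'   30-74-year eligibility range (exercises the age filter).
#' @param baseline_shape Weibull shape of the baseline survival used to
#'   extend the equation's `S0(horizon)` to arbitrary times
#'   (`S0(t) = S0(h)^((t/h)^shape)`); 1 gives a constant baseline hazard.
#' @param decoy_contact_rate Probability that an unexposed person carries a
#'   non-qualifying contact (outside the 5-year window, or a
#'   non-face-to-face setting inside it).
#' @param contacts_per_exposed Mean number of additional qualifying
#'   contacts per exposed person beyond the guaranteed one.
#' @param study_start ISO date of the first possible index assessment.
#' @param strata Per-stratum (sex x exposure) distribution parameters;
#'   see [default_strata()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_total,
                       seed = 1L,
                       sex_split = 0.44,
                       smi_prevalence = 0.058,
                       psychosis_fraction_of_smi = 0.155,
                       missing_diagnosis_fraction = 0.362,
                       excess_mode = c("risk_ratio", "hazard_ratio"),
                       excess_factor_female = 1.64,
                       excess_factor_male = 1.29,
                       followup_max_years = 12.2,
                       entry_window_years = 12.2,
                       accrual_shape = 0.64,
                       noncvd_death_rate = 0.004,
                       missing_smoking = 2 / 495388,
                       missing_tchdl = 2659 / 495388,
                       missing_bmi = 0.197,
                       prior_cvd_rate = 0.120,
                       prior_renal_rate = 0.012,
                       out_of_age_fraction = 27581 / 522969,
                       baseline_shape = 1,
                       decoy_contact_rate = 0.03,
                       contacts_per_exposed = 3,
                       study_start = "2004-10-20",
                       strata = default_strata()) {
  cfg <- list(n_total = n_total, seed = as.integer(seed), sex_split = sex_split,
              smi_prevalence = smi_prevalence,
              psychosis_fraction_of_smi = psychosis_fraction_of_smi,
              missing_diagnosis_fraction = missing_diagnosis_fraction,
              excess_mode = match.arg(excess_mode),
              excess_factor_female = excess_factor_female,
              excess_factor_male = excess_factor_male,
              followup_max_years = followup_max_years,
              entry_window_years = entry_window_years,
              accrual_shape = accrual_shape,
              noncvd_death_rate = noncvd_death_rate,
              missing_smoking = missing_smoking,
              missing_tchdl = missing_tchdl,
              missing_bmi = missing_bmi,
              prior_cvd_rate = prior_cvd_rate,
              prior_renal_rate = prior_renal_rate,
              out_of_age_fraction = out_of_age_fraction,
              baseline_shape = baseline_shape,
              decoy_contact_rate = decoy_contact_rate,
              contacts_per_exposed = contacts_per_exposed,
              study_start = as.character(study_start),
              strata = strata)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_prop <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_cfg(sprintf("`%s` must be a proportion in [0, 1].", field))
  }
  if (!is.numeric(cfg$n_total) || length(cfg$n_total) != 1L ||
      is.na(cfg$n_total) || cfg$n_total < 1)
    stop_cfg("`n_total` must be a positive count.")
  for (f in c("sex_split", "smi_prevalence", "psychosis_fraction_of_smi",
              "missing_diagnosis_fraction", "missing_smoking", "missing_tchdl",
              "missing_bmi", "prior_cvd_rate", "prior_renal_rate",
              "out_of_age_fraction", "decoy_contact_rate")) {
    chk_prop(f)
  }
  for (f in c("excess_factor_female", "excess_factor_male")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop_cfg(sprintf("`%s` must be a positive multiplier.", f))
  }
  for (f in c("followup_max_years", "entry_window_years", "accrual_shape",
              "baseline_shape")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop_cfg(sprintf("`%s` must be positive.", f))
  }
  if (cfg$noncvd_death_rate < 0)
    stop_cfg("`noncvd_death_rate` must be a non-negative per-year hazard.")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> n = %s, seed = %d, exposure = %.3f, ",
                     "excess (%s) F = %.2f / M = %.2f\n"),
              format(x$n_total, big.mark = ","), x$seed, x$smi_prevalence,
              x$excess_mode, x$excess_factor_female, x$excess_factor_male))
  invisible(x)
}

#' Read or write a simulation configuration document
#'
#' @param path JSON (`.json`) or YAML (`.yaml`/`.yml`) file.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  strata <- raw$strata
  raw$strata <- NULL
  args <- raw
  if (!is.null(strata)) {
    args$strata <- lapply(strata, function(s) lapply(s, unlist))
  }
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @param cfg A [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  doc <- unclass(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path, precision = 15L)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Default per-stratum distribution parameters
#'
#' One entry per sex-by-exposure stratum (`F_smi`, `F_gen`, `M_smi`,
#' `M_gen`), each holding: age-band probabilities over 30-44 / 45-54 /
#' 55-64 / 65-74; prioritised-ethnicity probabilities (Maori, Pacific,
#' Indian, Chinese/other Asian, European/other); deprivation-quintile
#' probabilities; smoking-category probabilities (never, past, current);
#' rates of diabetes, atrial fibrillation, family history and the three
#' baseline medication classes; and normal (mean, sd) parameters for SBP,
#' TC:HDL and BMI. Magnitudes reflect a 30-74-year primary-care
#' risk-assessment population in which the exposed group is younger, more
#' deprived and smokes more, while most other risk factors are similar
#' between groups.
#'
#' @return Named list of stratum parameter lists.
#' @export
default_strata <- function() {
  list(
    F_smi = list(
      age_bands = c(0.138, 0.398, 0.353, 0.111),
      ethnicity = c(0.276, 0.090, 0.043, 0.057, 0.534),
      deprivation = c(0.160, 0.161, 0.179, 0.204, 0.296),
      smoking = c(0.547, 0.162, 0.291),
      diabetes = 0.141, af = 0.008, family_history = 0.122,
      lipid_lowering = 0.141, bp_lowering = 0.225, antithrombotic = 0.077,
      sbp = c(125.7, 17.6), tchdl = c(3.86, 1.23), bmi = c(29.5, 7.4)),
    F_gen = list(
      age_bands = c(0.070, 0.310, 0.430, 0.190),
      ethnicity = c(0.132, 0.126, 0.080, 0.114, 0.548),
      deprivation = c(0.223, 0.198, 0.182, 0.185, 0.212),
      smoking = c(0.736, 0.148, 0.116),
      diabetes = 0.116, af = 0.008, family_history = 0.118,
      lipid_lowering = 0.156, bp_lowering = 0.264, antithrombotic = 0.094,
      sbp = c(128.6, 17.6), tchdl = c(3.71, 1.08), bmi = c(29.2, 7.2)),
    M_smi = list(
      age_bands = c(0.363, 0.434, 0.153, 0.050),
      ethnicity = c(0.316, 0.144, 0.043, 0.034, 0.463),
      deprivation = c(0.111, 0.132, 0.168, 0.217, 0.372),
      smoking = c(0.417, 0.167, 0.416),
      diabetes = 0.084, af = 0.011, family_history = 0.089,
      lipid_lowering = 0.111, bp_lowering = 0.140, antithrombotic = 0.058,
      sbp = c(127.1, 16.3), tchdl = c(4.45, 1.42), bmi = c(29.5, 6.3)),
    M_gen = list(
      age_bands = c(0.216, 0.407, 0.250, 0.127),
      ethnicity = c(0.112, 0.121, 0.090, 0.102, 0.575),
      deprivation = c(0.229, 0.202, 0.182, 0.182, 0.205),
      smoking = c(0.664, 0.185, 0.151),
      diabetes = 0.095, af = 0.012, family_history = 0.098,
      lipid_lowering = 0.148, bp_lowering = 0.192, antithrombotic = 0.089,
      sbp = c(128.8, 16.1), tchdl = c(4.39, 1.24), bmi = c(29.0, 5.6)))
}
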