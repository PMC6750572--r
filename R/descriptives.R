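#' Stratified descriptive table of demographics and risk factors
#'
#' Emits, for each sex-by-exposure stratum (all exposed, the
#' schizophrenia/bipolar subgroup, and the unexposed), counts and
#' percentages for categorical variables and mean (SD) for continuous
#' ones: age bands, prioritised ethnicity, deprivation quintile, family
#' history, diabetes, atrial fibrillation, baseline medications, smoking
#' categories, BMI bands (<25, 25-29, 30-34, 35-39, 40+, missing),
#' TC:HDL > 4, elevated blood pressure (SBP > 120 mmHg or DBP > 90 mmHg),
#' and CVD events over follow-up. Percentages are computed on the stratum
#' total (including missing values) and rounded half-up to one decimal;
#' an empty stratum reports zero counts with undefined (`NA`)
#' percentages.
#'
#' @param data Eligible-person tibble carrying exposure flags (`smi`,
#'   `psychosis`) and an `ethnicity` column, as produced by
#'   [build_cohort()].
#' @return A `descriptive_table` tibble with columns `sex`, `group`,
#'   `variable`, `level`, `n`, `pct`, `mean`, `sd`.
#' @export
descriptive_table <- function(data) {
  strata <- list(
    list(group = "MH treatment past 5 years", sel = function(d) d$smi),
    list(group = "Schizophrenia/bipolar", sel = function(d) d$psychosis),
    list(group = "No MH treatment", sel = function(d) !d$smi))
  out <- list()
  for (sx in c("F", "M")) {
    for (st in strata) {
      sub <- data[data$sex == sx & st$sel(data), , drop = FALSE]
      out[[length(out) + 1L]] <- dplyr::mutate(describe_stratum(sub),
                                               sex = sx, group = st$group,
                                               .before = 1)
    }
  }
  res <- dplyr::bind_rows(out)
  structure(res, class = c("descriptive_table", class(res)))
}

describe_stratum <- function(d) {
  n_tot <- nrow(d)
  cat_row <- function(variable, level, count) {
    tibble::tibble(variable = variable, level = level, n = count,
                   pct = describe_pct(count, n_tot),
                   mean = NA_real_, sd = NA_real_)
  }
  num_row <- function(variable, x) {
    x <- x[!is.na(x)]
    tibble::tibble(variable = variable, level = "mean (SD)",
                   n = length(x), pct = NA_real_,
                   mean = if (length(x)) mean(x) else NA_real_,
                   sd = if (length(x) > 1) sd(x) else NA_real_)
  }
  cat_var <- function(variable, values, levels) {
    dplyr::bind_rows(lapply(levels, function(lv) {
      cat_row(variable, lv, sum(values == lv, na.rm = TRUE))
    }))
  }
  age_band <- cut(d$age_at_index, c(30, 45, 55, 65, 75), right = FALSE,
                  labels = c("30-44", "45-54", "55-64", "65-74"),
                  include.lowest = TRUE)
  bmi_band <- cut(d$bmi, c(-Inf, 25, 30, 35, 40, Inf), right = FALSE,
                  labels = c("<25", "25-29", "30-34", "35-39", "40+"))
  flag_vars <- c("family_history", "diabetes", "atrial_fibrillation",
                 "lipid_lowering", "bp_lowering", "antithrombotic")
  dplyr::bind_rows(
    cat_row("total", "", n_tot),
    cat_var("age_band", as.character(age_band), levels(age_band)),
    cat_var("ethnicity", d$ethnicity, ETH_LEVELS),
    cat_var("deprivation_quintile", as.character(d$deprivation_quintile),
            as.character(1:5)),
    dplyr::bind_rows(lapply(flag_vars, function(v) {
      cat_row(v, "yes", sum(d[[v]], na.rm = TRUE))
    })),
    cat_var("smoking", d$smoker_status, c("past", "current")),
    num_row("bmi", d$bmi),
    cat_var("bmi_band", as.character(bmi_band), levels(bmi_band)),
    cat_row("bmi_band", "missing", sum(is.na(d$bmi))),
    num_row("tchdl", d$tchdl),
    cat_row("tchdl_gt4", "yes", sum(d$tchdl > 4, na.rm = TRUE)),
    num_row("sbp", d$sbp),
    num_row("dbp", d$dbp),
    cat_row("elevated_bp", "yes", sum(d$sbp > 120 | d$dbp > 90, na.rm = TRUE)),
    cat_row("cvd_events", "yes",
            if ("event_type" %in% names(d)) sum(d$event_type == "cvd") else 0L))
}
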