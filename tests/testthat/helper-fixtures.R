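# Shared fixtures and independent oracles, all built in code.

# Independent product-limit oracle: a plain loop over distinct event times,
# with Greenwood's variance. Deliberately avoids survival::survfit so it can
# stand as a cross-check of km_curve().
hand_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- as.logical(event)[ord]
  ts <- sort(unique(time[event]))
  s <- 1; gsum <- 0
  out <- data.frame(time = ts, surv = NA_real_, var = NA_real_)
  for (i in seq_along(ts)) {
    t <- ts[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n_risk)
    gsum <- gsum + d / (n_risk * (n_risk - d))
    out$surv[i] <- s
    out$var[i] <- s^2 * gsum
  }
  out
}

# A fully specified scoreable person record.
make_record <- function(n = 1, sex = "F", age = 55, sbp = 128, tchdl = 4,
                        smoker = "never", id = sprintf("R%03d", seq_len(n))) {
  tibble::tibble(
    person_id = id, sex = sex, age_at_index = age, sbp = sbp, dbp = sbp - 48,
    tchdl = tchdl, smoker_status = smoker, diabetes = FALSE,
    atrial_fibrillation = FALSE, family_history = FALSE,
    ethnicity = "European/other", deprivation_quintile = 1L,
    bp_lowering = FALSE, lipid_lowering = FALSE, antithrombotic = FALSE)
}

# Minimal person table for the exclusion cascade.
make_persons <- function(n, age = 50, prior_cvd = FALSE, prior_renal = FALSE,
                         smoker = "never", tchdl = 4,
                         index_date = as.Date("2010-01-01")) {
  tibble::tibble(
    person_id = sprintf("P%04d", seq_len(n)),
    sex = rep_len(c("F", "M"), n),
    age_at_index = rep_len(age, n),
    prior_cvd = rep_len(prior_cvd, n),
    prior_renal_failure = rep_len(prior_renal, n),
    smoker_status = rep_len(smoker, n),
    tchdl = rep_len(tchdl, n),
    ethnicity_records = "European/other",
    index_date = rep_len(index_date, n))
}

# A three-term equation whose linear predictor is easy to sum by hand.
tiny_equation <- function(s0 = 0.97) {
  cmp <- list(
    baseline_survival = s0,
    terms = list(
      list(name = "age", source = "age_at_index", coefficient = 0.1, center = 50),
      list(name = "sbp", coefficient = 0.02, center = 120),
      list(name = "smoker_current", transform = "indicator",
           source = "smoker_status", level = "current", coefficient = 0.7,
           center = 0)))
  risk_equation(female = cmp, male = cmp, horizon_years = 5)
}

# Small default-structured cohort for pipeline-level tests.
small_cohort <- function(n = 2000, seed = 42, ...) {
  generate_cohort(sim_config(n_total = n, seed = seed, ...))
}
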