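#' Prioritised-ethnicity vocabulary, highest priority first
#'
#' Categories used for prioritised ethnicity, ordered by priority:
#' Maori, Pacific, Indian, Chinese/other Asian, then the residual
#' European/other group.
#' @format Character vector of length 5.
#' @export
ETH_LEVELS <- c("Maori", "Pacific", "Indian", "Chinese/other Asian",
                "European/other")

SMOKING_LEVELS <- c("never", "past", "current")

# ICD-10 code palettes used by the generator. The F20-F31 family marks the
# functional-psychosis subgroup; the decoy palette deliberately brackets it
# (F10-F19 substance use, F32+ mood/anxiety) to exercise the range predicate.
PSYCHOSIS_CODES <- c("F20", "F20.0", "F22", "F23", "F25", "F25.1", "F28",
                     "F29", "F30", "F31", "F31.6")
OTHER_MH_CODES <- c("F10", "F19.2", "F32", "F32.1", "F33", "F40", "F41.1",
                    "F43", "F60")

#' Generate a linked synthetic person/contact cohort
#'
#' Draws `config$n_total` persons with demographics and risk factors per
#' stratum, assigns the exposure (specialist mental-health contact in the 5
#' years before index) and its functional-psychosis subgroup, generates the
#' linked service-contact table (qualifying contacts plus non-qualifying
#' decoys and post-index contacts), simulates time-to-event outcomes under
#' the supplied risk equation with the configured sex-specific excess risk
#' in the exposed group, and finally applies the configured missingness to
#' smoking, TC:HDL and BMI. Generation is a pure function of
#' `(config, equation)`: the same pair regenerates identical tables.
#'
#' @param config A [sim_config()].
#' @param equation A [risk_equation()] used as the generating truth for
#'   event times (default [default_risk_equation()]).
#' @return A list with elements `persons` (one row per person) and
#'   `contacts` (zero or more rows per person), both tibbles.
#' @examples
#' cohort <- generate_cohort(sim_config(n_total = 500, seed = 42))
#' dplyr::count(cohort$persons, event_type)
#' @export
generate_cohort <- function(config, equation = default_risk_equation()) {
  validate_sim_config(config)
  gen <- with_seed(derive_seed(config$seed, "simulate"), {
    persons <- gen_persons(config)
    contacts <- gen_contacts(persons, config)
    list(persons = persons, contacts = contacts)
  })
  persons <- simulate_outcomes(gen$persons, equation, config,
                               exposed = gen$persons$.smi)
  # release table: mask per configured missingness, drop truth columns
  persons$smoker_status[persons$.miss_smoking] <- NA_character_
  persons$tchdl[persons$.miss_tchdl] <- NA_real_
  persons$bmi[persons$.miss_bmi] <- NA_real_
  persons <- persons[, !startsWith(names(persons), "."), drop = FALSE]
  list(persons = tibble::as_tibble(persons), contacts = gen$contacts)
}

#' Simulate time-to-event outcomes for a person table
#'
#' Event times are drawn by inverse-transform sampling from the true
#' cumulative risk implied by the equation. The baseline survival is
#' Weibull-extended from the equation horizon,
#' `S0(t) = S0(h)^((t/h)^k)` with `k = config$baseline_shape`, so risk is
#' defined at every time. In `risk_ratio` mode an exposed person's true
#' cumulative risk is `min(1, m * (1 - S0(t)^exp(LP)))` with `m` the sex's
#' excess factor; in `hazard_ratio` mode `m` multiplies `exp(LP)` inside
#' the exponent. Independent non-CVD death times are exponential with the
#' configured hazard; administrative censoring occurs at
#' `min(followup_max_years, study end - entry)`. `event_type` records the
#' first of the three to occur.
#'
#' @param persons Person tibble with complete predictor values (the
#'   generator scores on pre-missingness values).
#' @param equation Generating [risk_equation()].
#' @param config A [sim_config()].
#' @param exposed Logical vector marking persons carrying the excess risk
#'   (default none).
#' @return `persons` with `event_time_years` and `event_type`
#'   (`"cvd"`, `"noncvd_death"`, `"censored"`) populated.
#' @export
simulate_outcomes <- function(persons, equation, config, exposed = NULL) {
  n <- nrow(persons)
  exposed <- exposed %||% rep(FALSE, n)
  stopifnot(length(exposed) == n)
  if (equation$horizon_years > config$followup_max_years)
    stop_cfg("equation horizon exceeds `followup_max_years`; risk beyond follow-up is undefined.")

  scoring <- persons
  scoring$ethnicity <- prioritized_ethnicity(persons$ethnicity_records)
  lp <- linear_predictor(scoring, equation)

  h <- equation$horizon_years
  k <- config$baseline_shape
  s0h <- ifelse(persons$sex == "F", equation$female$baseline_survival,
                equation$male$baseline_survival)
  lambda <- -log(s0h) / h^k
  m <- ifelse(exposed,
              ifelse(persons$sex == "F", config$excess_factor_female,
                     config$excess_factor_male),
              1)

  with_seed(derive_seed(config$seed, "outcomes"), {
    u <- runif(n)
    rate <- lambda * exp(lp)
    if (config$excess_mode == "risk_ratio") {
      q <- u / m
      cvd_time <- ifelse(q >= 1 | rate == 0, Inf, (-log1p(-q) / rate)^(1 / k))
    } else {
      cvd_time <- ifelse(rate == 0, Inf, (-log1p(-u) / (rate * m))^(1 / k))
    }
    death_time <- if (config$noncvd_death_rate > 0) {
      rexp(n, config$noncvd_death_rate)
    } else {
      rep(Inf, n)
    }
    study_end <- as.Date(config$study_start) +
      round(config$entry_window_years * DAYS_PER_YEAR)
    admin <- pmin(config$followup_max_years,
                  years_between(persons$index_date, study_end))
    t_obs <- pmin(cvd_time, death_time, admin)
    # truncate (not round) to 1e-4 years so recorded follow-up never
    # exceeds the administrative horizon and CSVs round-trip losslessly
    persons$event_time_years <- floor(t_obs * 1e4) / 1e4
    persons$event_type <- ifelse(cvd_time <= t_obs, "cvd",
                                 ifelse(death_time <= t_obs, "noncvd_death",
                                        "censored"))
  })
  persons
}

# --- internals ---------------------------------------------------------------

draw_by_stratum <- function(stratum, draw) {
  res <- rep(NA, length(stratum))
  for (st in sort(unique(stratum))) {
    idx <- which(stratum == st)
    res[idx] <- draw(st, length(idx))
  }
  res
}

gen_persons <- function(cfg) {
  n <- as.integer(cfg$n_total)
  S <- cfg$strata
  sex <- ifelse(runif(n) < cfg$sex_split, "F", "M")
  smi <- runif(n) < cfg$smi_prevalence
  stratum <- paste0(sex, ifelse(smi, "_smi", "_gen"))

  # age: in-range persons draw a 10-year band per stratum, uniform within;
  # a configured fraction falls outside 30-74 to exercise the age filter
  band_lo <- c(30, 45, 55, 65)
  band_hi <- c(45, 55, 65, 75)
  band <- draw_by_stratum(stratum, function(st, k) {
    sample.int(4L, k, replace = TRUE, prob = S[[st]]$age_bands)
  })
  age <- band_lo[band] + runif(n) * (band_hi[band] - band_lo[band])
  out_age <- runif(n) < cfg$out_of_age_fraction
  n_out <- sum(out_age)
  if (n_out) {
    young <- runif(n_out) < 0.5
    age[out_age] <- ifelse(young, 18 + runif(n_out) * 12, 75 + runif(n_out) * 15)
  }
  age <- round(age, 1)

  eth <- draw_by_stratum(stratum, function(st, k) {
    sample(ETH_LEVELS, k, replace = TRUE, prob = S[[st]]$ethnicity)
  })
  eth_records <- make_eth_records(eth)

  depr <- draw_by_stratum(stratum, function(st, k) {
    sample.int(5L, k, replace = TRUE, prob = S[[st]]$deprivation)
  })
  smoking <- draw_by_stratum(stratum, function(st, k) {
    sample(SMOKING_LEVELS, k, replace = TRUE, prob = S[[st]]$smoking)
  })
  draw_flag <- function(field) {
    draw_by_stratum(stratum, function(st, k) runif(k) < S[[st]][[field]])
  }
  diabetes <- draw_flag("diabetes")
  af <- draw_flag("af")
  famhist <- draw_flag("family_history")
  lipid <- draw_flag("lipid_lowering")
  bp_med <- draw_flag("bp_lowering")
  antithrombotic <- draw_flag("antithrombotic")
  draw_norm <- function(field, lo, hi) {
    v <- draw_by_stratum(stratum, function(st, k) {
      p <- S[[st]][[field]]
      rnorm(k, p[1], p[2])
    })
    pmin(pmax(v, lo), hi)
  }
  # recorded at clinical precision (also keeps CSV round-trips lossless)
  sbp <- round(draw_norm("sbp", 80, 220))
  dbp <- round(pmin(pmax(sbp - 48 + rnorm(n, 0, 8), 40), sbp - 5))
  tchdl <- round(draw_norm("tchdl", 1.5, 12), 2)
  bmi <- round(draw_norm("bmi", 15, 60), 1)

  prior_cvd <- runif(n) < cfg$prior_cvd_rate
  prior_renal <- runif(n) < cfg$prior_renal_rate

  # staggered, accelerating entry over the accrual window
  entry_years <- cfg$entry_window_years * runif(n)^cfg$accrual_shape
  index_date <- as.Date(cfg$study_start) + floor(entry_years * DAYS_PER_YEAR)

  psychosis <- smi & (runif(n) < cfg$psychosis_fraction_of_smi)

  tibble::tibble(
    person_id = sprintf("P%07d", seq_len(n)),
    sex = sex,
    age_at_index = age,
    ethnicity_records = eth_records,
    deprivation_quintile = depr,
    smoker_status = smoking,
    diabetes = diabetes,
    atrial_fibrillation = af,
    family_history = famhist,
    sbp = sbp,
    dbp = dbp,
    tchdl = tchdl,
    bmi = bmi,
    bp_lowering = bp_med,
    lipid_lowering = lipid,
    antithrombotic = antithrombotic,
    prior_cvd = prior_cvd,
    prior_renal_failure = prior_renal,
    index_date = index_date,
    .smi = smi,
    .psychosis = psychosis,
    .miss_smoking = runif(n) < cfg$missing_smoking,
    .miss_tchdl = runif(n) < cfg$missing_tchdl,
    .miss_bmi = runif(n) < cfg$missing_bmi)
}

# Raw ethnicity record strings: the true category always present, sometimes
# with an extra record of equal or lower priority (so prioritisation must
# pick the right one regardless of order), occasionally a free-text variant
# of the residual group.
make_eth_records <- function(eth) {
  n <- length(eth)
  pri <- match(eth, ETH_LEVELS)
  extra_draw <- runif(n)
  extra_pick <- runif(n)
  order_draw <- runif(n)
  vapply(seq_len(n), function(i) {
    recs <- eth[i]
    if (extra_draw[i] < 0.3) {
      lower <- ETH_LEVELS[seq(pri[i], 5L)]
      extra <- lower[1L + floor(extra_pick[i] * length(lower))]
      if (extra == "European/other" && extra_pick[i] < 0.15) extra <- "Other European"
      recs <- if (order_draw[i] < 0.5) c(extra, recs) else c(recs, extra)
    }
    paste(recs, collapse = ";")
  }, character(1))
}

gen_contacts <- function(persons, cfg) {
  smi_idx <- which(persons$.smi)
  psych <- persons$.psychosis
  window_days <- floor(5 * DAYS_PER_YEAR)  # 1826: half-open 5-year lookback

  rows <- list()
  # guaranteed + extra qualifying contacts for every exposed person
  n_qual <- 1L + stats::rpois(length(smi_idx), cfg$contacts_per_exposed)
  owner <- rep(smi_idx, n_qual)
  back <- sample.int(window_days, length(owner), replace = TRUE)
  rows$qual <- tibble::tibble(
    idx = owner,
    contact_date = persons$index_date[owner] - back,
    setting = sample(c("inpatient", "community_face_to_face"), length(owner),
                     replace = TRUE, prob = c(0.15, 0.85)))
  # decoys for exposed: stale contacts and non-face-to-face in-window contacts
  old <- smi_idx[runif(length(smi_idx)) < 0.2]
  rows$old <- tibble::tibble(
    idx = old,
    contact_date = persons$index_date[old] - window_days -
      sample.int(window_days, length(old), replace = TRUE),
    setting = sample(c("inpatient", "community_face_to_face"), length(old),
                     replace = TRUE, prob = c(0.15, 0.85)))
  oth <- smi_idx[runif(length(smi_idx)) < 0.1]
  rows$other <- tibble::tibble(
    idx = oth,
    contact_date = persons$index_date[oth] -
      sample.int(window_days, length(oth), replace = TRUE),
    setting = "other")
  # post-index contacts (never affect exposure; may carry diagnoses)
  post <- smi_idx[runif(length(smi_idx)) < 0.15]
  rows$post <- tibble::tibble(
    idx = post,
    contact_date = persons$index_date[post] +
      sample.int(730L, length(post), replace = TRUE) - 1L,
    setting = sample(c("inpatient", "community_face_to_face"), length(post),
                     replace = TRUE, prob = c(0.1, 0.9)))
  # unexposed decoys: either stale, or in-window but not face-to-face
  un_idx <- which(!persons$.smi)
  dec <- un_idx[runif(length(un_idx)) < cfg$decoy_contact_rate]
  if (length(dec)) {
    stale <- runif(length(dec)) < 0.5
    rows$decoy <- tibble::tibble(
      idx = dec,
      contact_date = persons$index_date[dec] - ifelse(
        stale,
        window_days + sample.int(window_days, length(dec), replace = TRUE),
        sample.int(window_days, length(dec), replace = TRUE)),
      setting = ifelse(stale,
                       sample(c("inpatient", "community_face_to_face"),
                              length(dec), replace = TRUE, prob = c(0.15, 0.85)),
                       "other"))
  }

  contacts <- dplyr::bind_rows(rows)
  nc <- nrow(contacts)
  if (nc == 0L) {
    return(tibble::tibble(person_id = character(), contact_date = as.Date(character()),
                          setting = character(), diagnosis_code = character()))
  }
  # contact-level diagnosis coding: missing completely at random; coded
  # contacts draw from the owner's diagnostic palette
  is_psych <- psych[contacts$idx]
  code <- ifelse(is_psych,
                 sample(PSYCHOSIS_CODES, nc, replace = TRUE),
                 sample(OTHER_MH_CODES, nc, replace = TRUE))
  code[runif(nc) < cfg$missing_diagnosis_fraction] <- NA_character_
  contacts$diagnosis_code <- code
  # psychosis coding is near-complete in practice: guarantee each psychosis
  # person at least one surviving F20-F31 code
  lost <- setdiff(which(psych), contacts$idx[is_psych & !is.na(code)])
  if (length(lost)) {
    first_row <- match(lost, contacts$idx)
    contacts$diagnosis_code[first_row] <-
      sample(PSYCHOSIS_CODES, length(lost), replace = TRUE)
  }
  contacts$person_id <- persons$person_id[contacts$idx]
  contacts <- contacts[order(contacts$person_id, contacts$contact_date), ]
  tibble::as_tibble(contacts[, c("person_id", "contact_date", "setting",
                                 "diagnosis_code")])
}
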