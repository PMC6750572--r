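#' Cohort flow accounting
#'
#' Records the eligibility cascade: total assessed, those aged 30-74 at
#' index, then sequential exclusions for prior CVD (including heart
#' failure) or renal failure, missing smoking status, and missing
#' cholesterol (TC:HDL). `final_eligible` is always the in-age count minus
#' the three exclusion counts; construction fails if any count is negative
#' or the subtraction goes negative.
#'
#' @param assessed_total,in_age_range,excluded_prior_cvd_or_renal,excluded_missing_smoking,excluded_missing_cholesterol
#'   Stage counts.
#' @return An object of class `cohort_flow`.
#' @examples
#' cohort_flow(522969, 495388, 65147, 0, 0)
#' @export
cohort_flow <- function(assessed_total, in_age_range,
                        excluded_prior_cvd_or_renal,
                        excluded_missing_smoking,
                        excluded_missing_cholesterol) {
  counts <- c(assessed_total = assessed_total, in_age_range = in_age_range,
              excluded_prior_cvd_or_renal = excluded_prior_cvd_or_renal,
              excluded_missing_smoking = excluded_missing_smoking,
              excluded_missing_cholesterol = excluded_missing_cholesterol)
  if (any(counts < 0)) stop_data("cohort_flow counts must be non-negative.")
  if (in_age_range > assessed_total)
    stop_data("in_age_range cannot exceed assessed_total.")
  final <- in_age_range - excluded_prior_cvd_or_renal -
    excluded_missing_smoking - excluded_missing_cholesterol
  if (final < 0) stop_data("exclusions exceed the in-age-range count.")
  structure(as.list(c(counts, final_eligible = final)), class = "cohort_flow")
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat("Cohort flow\n")
  cat(sprintf("  assessed:                 %9d\n", x$assessed_total))
  cat(sprintf("  aged 30-74 at index:      %9d\n", x$in_age_range))
  cat(sprintf("  - prior CVD/renal:        %9d\n", x$excluded_prior_cvd_or_renal))
  cat(sprintf("  - missing smoking:        %9d\n", x$excluded_missing_smoking))
  cat(sprintf("  - missing cholesterol:    %9d\n", x$excluded_missing_cholesterol))
  cat(sprintf("  final eligible:           %9d\n", x$final_eligible))
  invisible(x)
}

#' @export
tidy.cohort_flow <- function(x, ...) {
  tibble::tibble(stage = names(unclass(x)), count = unlist(unclass(x), use.names = FALSE))
}

#' Apply the eligibility cascade
#'
#' Eligibility requires age 30-74 inclusive at index, no prior CVD
#' (including heart failure) or renal failure, and non-missing smoking
#' status and TC:HDL. Exclusions are counted in that order; a person
#' failing several rules is counted once, at the first rule failed.
#'
#' @param persons Person tibble with `age_at_index`, `prior_cvd`,
#'   `prior_renal_failure`, `smoker_status`, `tchdl`.
#' @return A list with `eligible` (the filtered tibble) and `flow`
#'   (a [cohort_flow()]).
#' @export
apply_exclusions <- function(persons) {
  need <- c("age_at_index", "prior_cvd", "prior_renal_failure")
  for (col in need) {
    if (!col %in% names(persons)) stop_data(sprintf("missing column `%s`.", col))
    bad <- is.na(persons[[col]])
    if (any(bad)) {
      stop_data(sprintf("null `%s` for persons: %s.", col,
                        paste(head(persons$person_id[bad], 5), collapse = ", ")))
    }
  }
  # "aged 30 to 74" inclusive: completed age 30-74, i.e. 30 <= age < 75
  in_age <- persons$age_at_index >= 30 & persons$age_at_index < 75
  aged <- persons[in_age, , drop = FALSE]
  ex_cvd <- aged$prior_cvd | aged$prior_renal_failure
  ex_smoke <- !ex_cvd & is.na(aged$smoker_status)
  ex_chol <- !ex_cvd & !ex_smoke & is.na(aged$tchdl)
  flow <- cohort_flow(
    assessed_total = nrow(persons),
    in_age_range = nrow(aged),
    excluded_prior_cvd_or_renal = sum(ex_cvd),
    excluded_missing_smoking = sum(ex_smoke),
    excluded_missing_cholesterol = sum(ex_chol))
  list(eligible = aged[!(ex_cvd | ex_smoke | ex_chol), , drop = FALSE],
       flow = flow)
}

#' Ascertain mental-health service exposure from contact records
#'
#' A person is exposed (`smi = TRUE`) if any inpatient or face-to-face
#' community contact falls in the half-open five-year window before the
#' index assessment: `index - 5y <= contact_date < index`, with the gap
#' measured in exact days / 365.25. Same-day and later contacts never
#' qualify, nor do contacts in other settings.
#'
#' @param persons Person tibble with `person_id` and `index_date`.
#' @param contacts Contact tibble with `person_id`, `contact_date`,
#'   `setting`.
#' @return Tibble `person_id`, `smi`, one row per person in `persons`.
#' @export
ascertain_smi <- function(persons, contacts) {
  unknown <- !contacts$person_id %in% persons$person_id
  if (any(unknown)) {
    stop_data(sprintf("contacts reference unknown person ids: %s.",
                      paste(head(unique(contacts$person_id[unknown]), 5),
                            collapse = ", ")))
  }
  idx <- as.Date(persons$index_date[match(contacts$person_id, persons$person_id)])
  gap_years <- years_between(contacts$contact_date, idx)
  qualifies <- contacts$setting %in% c("inpatient", "community_face_to_face") &
    gap_years > 0 & gap_years <= 5
  tibble::tibble(
    person_id = persons$person_id,
    smi = persons$person_id %in% contacts$person_id[qualifies])
}

# ICD-10 mental-health code family: two digits after "F", sub-codes after
# the decimal ignored. Malformed codes are reported once and treated as
# missing, never fatal.
icd_f_family <- function(code) {
  fam <- rep(NA_integer_, length(code))
  ok <- !is.na(code) & grepl("^F[0-9]{2}(\\..*)?$", code)
  fam[ok] <- as.integer(substr(code[ok], 2, 3))
  malformed <- !is.na(code) & !ok
  if (any(malformed)) {
    warn(sprintf("%d malformed diagnosis code(s) treated as missing (e.g. %s).",
                 sum(malformed),
                 paste(head(unique(code[malformed]), 3), collapse = ", ")))
  }
  fam
}

#' Flag the functional-psychosis subgroup
#'
#' Among the exposed, marks persons with any contact -- at any date,
#' including after the index assessment, and in any setting -- whose
#' diagnosis code falls in the ICD-10 family F20-F31 inclusive (matching
#' on the two-digit family, sub-codes ignored). Psychiatric diagnoses are
#' substantially under-coded in routine data, so absence of a code leaves
#' `psychosis = FALSE`.
#'
#' @param flags Tibble from [ascertain_smi()].
#' @param contacts Contact tibble with `diagnosis_code`.
#' @return `flags` with logical columns `psychosis` and
#'   `smi_non_psychosis` added (`psychosis` implies `smi`).
#' @export
ascertain_psychosis <- function(flags, contacts) {
  fam <- icd_f_family(contacts$diagnosis_code)
  psych_ids <- unique(contacts$person_id[!is.na(fam) & fam >= 20 & fam <= 31])
  flags$psychosis <- flags$smi & flags$person_id %in% psych_ids
  flags$smi_non_psychosis <- flags$smi & !flags$psychosis
  flags
}

#' Prioritised ethnicity from multiple raw records
#'
#' Collapses each person's ordered list of raw ethnicity records to a
#' single category by fixed priority: Maori > Pacific > Indian >
#' Chinese/other Asian > European/other. Records not matching a named
#' priority group fall into the residual European/other category. The
#' result does not depend on record order.
#'
#' @param records Character vector of `";"`-separated raw records, or a
#'   list of character vectors.
#' @return Character vector of categories (one of [ETH_LEVELS]).
#' @examples
#' prioritized_ethnicity("Pacific;Maori") # "Maori"
#' @export
prioritized_ethnicity <- function(records) {
  if (is.character(records)) records <- strsplit(records, ";", fixed = TRUE)
  vapply(records, function(r) {
    r <- trimws(r[!is.na(r) & nzchar(trimws(r))])
    if (!length(r)) stop_data("a person has no ethnicity records.")
    pri <- match(r, ETH_LEVELS)
    pri[is.na(pri)] <- 5L  # residual group
    ETH_LEVELS[min(pri)]
  }, character(1))
}

#' Build the analysis-ready eligible cohort
#'
#' Runs the eligibility cascade, ascertains exposure and the psychosis
#' subgroup from the contact table, and attaches prioritised ethnicity and
#' an `exposure_group` label (`"psychosis-SMI"`, `"non-psychosis-SMI"`,
#' `"none"`).
#'
#' @inheritParams ascertain_smi
#' @return List with `eligible` (flagged tibble) and `flow`
#'   ([cohort_flow()]).
#' @export
build_cohort <- function(persons, contacts) {
  unknown <- !contacts$person_id %in% persons$person_id
  if (any(unknown)) {
    stop_data(sprintf("contacts reference unknown person ids: %s.",
                      paste(head(unique(contacts$person_id[unknown]), 5),
                            collapse = ", ")))
  }
  built <- apply_exclusions(persons)
  contacts <- contacts[contacts$person_id %in% built$eligible$person_id, ,
                       drop = FALSE]
  flags <- ascertain_psychosis(ascertain_smi(built$eligible, contacts), contacts)
  eligible <- dplyr::left_join(built$eligible, flags, by = "person_id")
  eligible$ethnicity <- prioritized_ethnicity(eligible$ethnicity_records)
  eligible$exposure_group <- ifelse(
    eligible$smi, ifelse(eligible$psychosis, "psychosis-SMI", "non-psychosis-SMI"),
    "none")
  list(eligible = tibble::as_tibble(eligible), flow = built$flow)
}
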