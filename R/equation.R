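#' Declarative sex-specific Cox-form risk equation
#'
#' A `risk_equation` holds, for each sex, a set of centred predictor terms
#' with coefficients, optional pairwise interaction terms, and the baseline
#' survival at a fixed prediction horizon. Absolute risk at the horizon is
#' `1 - S0(h)^exp(LP)` where `LP` is the centred linear predictor.
#' Coefficients are configuration, not code: equations round-trip through
#' JSON or YAML documents so production coefficient sets can be dropped in
#' without touching the package.
#'
#' Each term is a list with fields `name` (unique label), `transform`
#' (`"identity"`, `"log"` or `"indicator"`), `coefficient`, `center`, and
#' for indicator terms `source` (the person-table column) and `level` (the
#' value coded 1). Identity/log terms read the column named by `source`
#' (defaulting to `name`).
#'
#' @param female,male Per-sex component lists, each with elements
#'   `baseline_survival` (S0 at the horizon, in (0, 1]), `terms` (list of
#'   term lists) and optional `interactions` (list of
#'   `list(terms = c(a, b), coefficient = beta)`).
#' @param horizon_years Prediction horizon in years (default 5).
#' @return An object of class `risk_equation`.
#' @seealso [predicted_risk()], [read_risk_equation()], [default_risk_equation()]
#' @export
risk_equation <- function(female, male, horizon_years = 5) {
  eq <- structure(
    list(schema_version = 1L,
         horizon_years = horizon_years,
         female = normalize_eq_sex(female),
         male = normalize_eq_sex(male)),
    class = "risk_equation")
  validate_risk_equation(eq)
  eq
}

normalize_eq_sex <- function(x) {
  x$interactions <- x$interactions %||% list()
  x$terms <- lapply(x$terms, function(tm) {
    tm$transform <- tm$transform %||% "identity"
    tm$center <- tm$center %||% 0
    tm$source <- tm$source %||% tm$name
    tm
  })
  x
}

validate_risk_equation <- function(eq) {
  if (!is.numeric(eq$horizon_years) || eq$horizon_years <= 0)
    stop_cfg("`horizon_years` must be a positive number.")
  for (sex in c("female", "male")) {
    cmp <- eq[[sex]]
    s0 <- cmp$baseline_survival
    if (!is.numeric(s0) || s0 <= 0 || s0 > 1)
      stop_cfg(sprintf("baseline_survival for %s must lie in (0, 1].", sex))
    nms <- vapply(cmp$terms, `[[`, character(1), "name")
    if (anyDuplicated(nms))
      stop_cfg(sprintf("duplicate term names in %s equation.", sex))
    for (tm in cmp$terms) {
      if (!tm$transform %in% c("identity", "log", "indicator"))
        stop_cfg(sprintf("unknown transform '%s' for term '%s'.", tm$transform, tm$name))
      if (!is.finite(tm$coefficient))
        stop_cfg(sprintf("non-finite coefficient for term '%s'.", tm$name))
      if (tm$transform == "indicator" && is.null(tm$level))
        stop_cfg(sprintf("indicator term '%s' needs a `level`.", tm$name))
    }
    for (ia in cmp$interactions) {
      if (length(ia$terms) != 2L || !all(ia$terms %in% nms))
        stop_cfg("every interaction must reference two existing main terms.")
      if (!is.finite(ia$coefficient))
        stop_cfg("non-finite interaction coefficient.")
    }
  }
  invisible(eq)
}

#' @export
print.risk_equation <- function(x, ...) {
  cat("<risk_equation> horizon:", x$horizon_years, "years\n")
  for (sex in c("female", "male")) {
    cmp <- x[[sex]]
    cat(sprintf("  %s: %d terms, %d interactions, S0(h) = %.4f\n",
                sex, length(cmp$terms), length(cmp$interactions),
                cmp$baseline_survival))
  }
  invisible(x)
}

#' Read or write a risk-equation specification file
#'
#' Equations are stored as JSON or YAML documents (chosen by file
#' extension) with an explicit `schema_version`; a written file reads back
#' to an identical equation.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_risk_equation()` returns a [risk_equation()];
#'   `write_risk_equation()` returns `path` invisibly.
#' @export
read_risk_equation <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(raw$schema_version) || as.integer(raw$schema_version) != 1L)
    stop_cfg("unsupported or missing schema_version in equation file.")
  unlist1 <- function(x) if (is.list(x) && length(x) == 1L && !is.list(x[[1]])) x[[1]] else x
  tidy_sex <- function(cmp) {
    list(
      baseline_survival = as.numeric(unlist1(cmp$baseline_survival)),
      terms = lapply(cmp$terms, function(tm) {
        tm <- lapply(tm, unlist1)
        tm$coefficient <- as.numeric(tm$coefficient)
        tm$center <- as.numeric(tm$center %||% 0)
        tm
      }),
      interactions = lapply(cmp$interactions %||% list(), function(ia) {
        list(terms = as.character(unlist(ia$terms)),
             coefficient = as.numeric(unlist1(ia$coefficient)))
      }))
  }
  risk_equation(female = tidy_sex(raw$female), male = tidy_sex(raw$male),
                horizon_years = as.numeric(unlist1(raw$horizon_years)))
}

#' @rdname read_risk_equation
#' @param eq A [risk_equation()].
#' @export
write_risk_equation <- function(eq, path) {
  stopifnot(inherits(eq, "risk_equation"))
  doc <- unclass(eq)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path, precision = 15L)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# Term vocabulary shared by the default equation and the synthetic generator.
default_terms <- function(sex) {
  female <- sex == "female"
  list(
    list(name = "age", source = "age_at_index",
         coefficient = if (female) 0.078 else 0.070, center = 55),
    list(name = "sbp", coefficient = 0.012, center = 128),
    list(name = "tchdl", coefficient = 0.16, center = if (female) 3.8 else 4.4),
    list(name = "smoker_past", transform = "indicator", source = "smoker_status",
         level = "past", coefficient = 0.12, center = 0),
    list(name = "smoker_current", transform = "indicator", source = "smoker_status",
         level = "current", coefficient = if (female) 0.60 else 0.50, center = 0),
    list(name = "diabetes", coefficient = 0.50, center = 0),
    list(name = "atrial_fibrillation", coefficient = 0.90, center = 0),
    list(name = "family_history", coefficient = 0.15, center = 0),
    list(name = "eth_maori", transform = "indicator", source = "ethnicity",
         level = "Maori", coefficient = 0.30, center = 0),
    list(name = "eth_pacific", transform = "indicator", source = "ethnicity",
         level = "Pacific", coefficient = 0.25, center = 0),
    list(name = "eth_indian", transform = "indicator", source = "ethnicity",
         level = "Indian", coefficient = 0.35, center = 0),
    list(name = "eth_asian", transform = "indicator", source = "ethnicity",
         level = "Chinese/other Asian", coefficient = -0.25, center = 0),
    list(name = "dep_q2", transform = "indicator", source = "deprivation_quintile",
         level = "2", coefficient = 0.05, center = 0),
    list(name = "dep_q3", transform = "indicator", source = "deprivation_quintile",
         level = "3", coefficient = 0.10, center = 0),
    list(name = "dep_q4", transform = "indicator", source = "deprivation_quintile",
         level = "4", coefficient = 0.15, center = 0),
    list(name = "dep_q5", transform = "indicator", source = "deprivation_quintile",
         level = "5", coefficient = 0.25, center = 0),
    list(name = "bp_lowering", coefficient = 0.25, center = 0),
    list(name = "lipid_lowering", coefficient = 0.10, center = 0),
    list(name = "antithrombotic", coefficient = 0.15, center = 0))
}

#' Bundled illustrative risk equation
#'
#' A sex-specific 5-year equation over the standard primary-prevention
#' predictor set (age, systolic blood pressure, TC:HDL ratio, smoking
#' category, diabetes, atrial fibrillation, family history, prioritised
#' ethnicity, deprivation quintile, and baseline medications). The
#' coefficients are illustrative only -- tuned to give realistic risk
#' distributions for a 30-74-year primary-care cohort -- and are NOT the
#' production coefficients of any published equation; users validating a
#' real equation should load their own specification with
#' [read_risk_equation()].
#'
#' @return A [risk_equation()] with a 5-year horizon.
#' @export
default_risk_equation <- function() {
  risk_equation(
    female = list(baseline_survival = 0.979, terms = default_terms("female")),
    male = list(baseline_survival = 0.968, terms = default_terms("male")),
    horizon_years = 5)
}
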