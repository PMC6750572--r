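#' Write / read the cohort tables
#'
#' Persons and contacts are exchanged as UTF-8 CSV with a header row and
#' ISO-8601 dates, the format every pipeline stage consumes.
#'
#' @param cohort List with `persons` and `contacts` tibbles.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns the two file paths invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "persons.csv")
  cp <- file.path(dir, "contacts.csv")
  readr::write_csv(cohort$persons, pp)
  readr::write_csv(cohort$contacts, cp)
  invisible(c(persons = pp, contacts = cp))
}

#' @rdname write_cohort
#' @param persons_path,contacts_path CSV paths as written by
#'   `write_cohort()`.
#' @export
read_cohort <- function(persons_path, contacts_path) {
  persons <- readr::read_csv(persons_path, show_col_types = FALSE,
                             progress = FALSE)
  contacts <- readr::read_csv(contacts_path, show_col_types = FALSE,
                              progress = FALSE,
                              col_types = readr::cols(
                                person_id = readr::col_character(),
                                contact_date = readr::col_date(),
                                setting = readr::col_character(),
                                diagnosis_code = readr::col_character()))
  list(persons = persons, contacts = contacts)
}

log_stage <- function(log_path, stage, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  message(line)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> build -> score -> survival ->
#' calibrate -> describe, writing every artifact plus a run manifest to
#' `out_dir`. Calibration is computed separately within each analysis
#' population (exposed and unexposed, each for both sexes combined and
#' per sex), with deciles formed within the population. A population too
#' small to decile (fewer than 10 persons, e.g. under a degenerate
#' zero-prevalence configuration) is reported in the summary with an
#' explicit `insufficient` flag rather than failing. A second run from
#' the same configuration and seed reproduces identical outputs.
#'
#' @param config A [sim_config()] (used to simulate), or `NULL` when
#'   `persons_path`/`contacts_path` are supplied.
#' @param equation A [risk_equation()].
#' @param out_dir Output directory.
#' @param seed Optional integer overriding `config$seed`.
#' @param persons_path,contacts_path Optional input CSVs; when given, the
#'   simulate stage is skipped.
#' @return Invisibly, a list with `eligible`, `flow`, `calibration`
#'   (list of [calibration_table()]s), `summary` (tibble of mean ratios),
#'   `curves`, `descriptive` and `manifest`.
#' @export
run_pipeline <- function(config = NULL, equation = default_risk_equation(),
                         out_dir, seed = NULL,
                         persons_path = NULL, contacts_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  if (file.exists(log_path)) file.remove(log_path)
  stage <- "configure"
  result <- tryCatch({
    if (!is.null(seed) && !is.null(config)) config$seed <- as.integer(seed)

    stage <- "simulate"
    if (is.null(persons_path)) {
      if (is.null(config)) stop_cfg("either a config or input paths are required.")
      cohort <- generate_cohort(config, equation)
      write_cohort(cohort, out_dir)
      log_stage(log_path, stage, sprintf("generated %d persons, %d contacts",
                                         nrow(cohort$persons), nrow(cohort$contacts)))
    } else {
      cohort <- read_cohort(persons_path, contacts_path)
      log_stage(log_path, stage, sprintf("loaded %d persons, %d contacts",
                                         nrow(cohort$persons), nrow(cohort$contacts)))
    }

    stage <- "build"
    built <- build_cohort(cohort$persons, cohort$contacts)
    eligible <- built$eligible
    log_stage(log_path, stage, sprintf(
      "%d assessed -> %d eligible (excluded: %d age, %d prior CVD/renal, %d missing smoking, %d missing cholesterol)",
      built$flow$assessed_total, built$flow$final_eligible,
      built$flow$assessed_total - built$flow$in_age_range,
      built$flow$excluded_prior_cvd_or_renal,
      built$flow$excluded_missing_smoking,
      built$flow$excluded_missing_cholesterol))
    jsonlite::write_json(unclass(built$flow), file.path(out_dir, "flow.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(eligible, file.path(out_dir, "eligible.csv"))

    stage <- "score"
    scores <- score_cohort(eligible, equation)
    eligible$predicted_risk <- scores$predicted_risk
    readr::write_csv(scores, file.path(out_dir, "scores.csv"))
    log_stage(log_path, stage, sprintf("scored %d persons", nrow(scores)))

    stage <- "survival"
    curves <- age_adjusted_curves(eligible)
    readr::write_csv(tibble::as_tibble(curves), file.path(out_dir, "curves.csv"))
    log_stage(log_path, stage, sprintf("age-standardized curves for %d groups",
                                       length(unique(curves$group))))

    stage <- "calibrate"
    horizon <- equation$horizon_years
    pops <- list()
    for (grp in list(c("SMI", TRUE), c("no-MH", FALSE))) {
      for (sx in c("all", "F", "M")) {
        sel <- eligible$smi == as.logical(grp[2])
        if (sx != "all") sel <- sel & eligible$sex == sx
        pops[[paste(grp[1], sx, sep = ", ")]] <- eligible[sel, , drop = FALSE]
      }
    }
    tables <- list()
    summaries <- list()
    for (nm in names(pops)) {
      sub <- pops[[nm]]
      if (nrow(sub) < 10L) {
        summaries[[nm]] <- tibble::tibble(population = nm, horizon = horizon,
                                          n = nrow(sub), mean_ratio = NA_real_,
                                          weighted_mean_ratio = NA_real_,
                                          zero_event_deciles = NA_integer_,
                                          insufficient = TRUE)
        next
      }
      ct <- calibration_table(sub, horizon = horizon, population = nm)
      tables[[nm]] <- ct
      summaries[[nm]] <- dplyr::mutate(glance(ct), insufficient = FALSE)
    }
    summary_tbl <- dplyr::bind_rows(summaries)
    cal_rows <- dplyr::bind_rows(lapply(names(tables), function(nm) {
      dplyr::mutate(tidy(tables[[nm]]), population = nm, .before = 1)
    }))
    readr::write_csv(cal_rows, file.path(out_dir, "calibration.csv"))
    jsonlite::write_json(
      lapply(split(summary_tbl, summary_tbl$population), function(r) {
        list(mean_ratio = r$mean_ratio, weighted_mean_ratio = r$weighted_mean_ratio,
             n = r$n, insufficient = r$insufficient)
      }),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    log_stage(log_path, stage, sprintf("calibrated %d populations (%d insufficient)",
                                       nrow(summary_tbl), sum(summary_tbl$insufficient)))

    stage <- "describe"
    desc <- descriptive_table(eligible)
    readr::write_csv(tibble::as_tibble(desc), file.path(out_dir, "descriptive.csv"))
    log_stage(log_path, stage, sprintf("descriptive table: %d rows", nrow(desc)))

    stage <- "manifest"
    files <- c("persons.csv", "contacts.csv", "flow.json", "eligible.csv",
               "scores.csv", "curves.csv", "calibration.csv", "summary.json",
               "descriptive.csv")
    files <- files[file.exists(file.path(out_dir, files))]
    manifest <- list(
      package_version = as.character(utils::packageVersion("cvdcalib")),
      seed = if (!is.null(config)) config$seed else NA_integer_,
      config_hash = if (!is.null(config)) rlang::hash(unclass(config)) else NA_character_,
      files = as.list(unname(Map(function(f) {
        list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
      }, files))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(eligible = eligible, flow = built$flow, calibration = tables,
         summary = summary_tbl, curves = curves, descriptive = desc,
         manifest = manifest)
  }, error = function(e) {
    log_stage(log_path, stage, paste("ERROR:", conditionMessage(e)))
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)), parent = e)
  })
  invisible(result)
}
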