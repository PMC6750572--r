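#' Assign deciles of predicted risk
#'
#' Rank-based partition into 10 near-equal groups: persons are ordered by
#' (risk, id) -- the id breaking ties stably -- and rank r of n receives
#' decile `ceiling(10 r / n)`, so group sizes differ by at most one and
#' mean predicted risk is non-decreasing across deciles.
#'
#' @param risk Numeric predicted risks.
#' @param id Tie-break identifiers (default input position).
#' @return Integer vector of decile labels (1-10) aligned with the input.
#' @export
decile_assign <- function(risk, id = seq_along(risk)) {
  n <- length(risk)
  if (n < 10L) stop_data("at least 10 persons are needed to form deciles.")
  ord <- order(risk, id)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  as.integer(ceiling(10 * rank / n))
}

#' Decile calibration of predicted against observed risk
#'
#' Splits the population into deciles of predicted risk and compares, per
#' decile, the mean predicted risk at the horizon with the Kaplan-Meier
#' observed risk of the decile's members at the same horizon (censoring-
#' aware). The per-decile ratio is observed / mean predicted, so values
#' above 1 mean the equation underestimates risk. A decile with zero
#' events gets observed risk 0 and ratio 0, flagged in `zero_events`
#' rather than dropped.
#'
#' @param data Tibble with one row per person.
#' @param risk,time,event Column names (defaults `"predicted_risk"`,
#'   `"event_time_years"`, `"event_type"`; the event column may be logical
#'   or the `event_type` coding where `"cvd"` is the event).
#' @param horizon Risk horizon in years (default 5).
#' @param population Label stored with the table (e.g. `"women, SMI"`).
#' @return A `calibration_table`: tibble with columns `decile`, `n`,
#'   `mean_predicted`, `observed`, `lower`, `upper`, `ratio`,
#'   `zero_events`; the summary mean ratio is available via
#'   [mean_ratio()] or [glance()].
#' @examples
#' cohort <- generate_cohort(sim_config(n_total = 2000, seed = 7))
#' eq <- default_risk_equation()
#' built <- build_cohort(cohort$persons, cohort$contacts)
#' scored <- dplyr::mutate(built$eligible, predicted_risk = predicted_risk(built$eligible, eq))
#' ct <- calibration_table(scored)
#' mean_ratio(ct)
#' @export
calibration_table <- function(data, risk = "predicted_risk",
                              time = "event_time_years", event = "event_type",
                              horizon = 5, population = "all") {
  pr <- data[[risk]]
  tt <- data[[time]]
  ev <- data[[event]]
  if (!is.logical(ev)) ev <- ev == "cvd"
  if (length(pr) < 10L) stop_data("at least 10 persons are needed for calibration.")
  id <- if ("person_id" %in% names(data)) data$person_id else seq_along(pr)
  dec <- decile_assign(pr, id)
  rows <- lapply(1:10, function(d) {
    sel <- dec == d
    km <- km_curve(tt[sel], ev[sel])
    obs <- suppressWarnings(risk_at(km, horizon))
    mp <- mean(pr[sel])
    tibble::tibble(decile = d, n = sum(sel), mean_predicted = mp,
                   observed = obs$risk, lower = obs$lower, upper = obs$upper,
                   ratio = if (obs$risk > 0) obs$risk / mp else 0,
                   zero_events = sum(ev[sel]) == 0L)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("calibration_table", class(out)),
            horizon = horizon, population = population)
}

#' Mean observed:predicted ratio across deciles
#'
#' The headline calibration summary: the unweighted arithmetic mean of the
#' 10 per-decile observed:predicted ratios. Values above 1 quantify the
#' degree of risk underestimation by the equation.
#'
#' @param table A [calibration_table()].
#' @param weighted If `TRUE`, return the person-weighted mean instead
#'   (emitted for comparison; the headline statistic is unweighted).
#' @return A single number.
#' @export
mean_ratio <- function(table, weighted = FALSE) {
  stopifnot(inherits(table, "calibration_table"))
  if (weighted) {
    sum(table$n * table$ratio) / sum(table$n)
  } else {
    mean(table$ratio)
  }
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
tidy.calibration_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.calibration_table <- function(x, ...) {
  tibble::tibble(population = attr(x, "population"),
                 horizon = attr(x, "horizon"),
                 n = sum(x$n),
                 mean_ratio = mean_ratio(x),
                 weighted_mean_ratio = mean_ratio(x, weighted = TRUE),
                 zero_event_deciles = sum(x$zero_events))
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Calibration table (%s, %g-year horizon); mean observed:predicted ratio = %.3f\n",
              attr(x, "population"), attr(x, "horizon"), mean_ratio(x)))
  NextMethod()
}
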