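#' Evaluate the centred linear predictor of a Cox-form equation
#'
#' Computes `LP = sum_j beta_j (x_j - c_j) + interactions` for each row of
#' a person table, selecting the female or male coefficient set from each
#' person's `sex` ("F"/"M"). Indicator terms compare their source column
#' with the configured level; log terms take the natural log of the source
#' before centring.
#'
#' @param data Person tibble with a `sex` column and every predictor column
#'   the equation references (non-null for all rows).
#' @param eq A [risk_equation()].
#' @return Numeric vector of linear predictors, one per row.
#' @export
linear_predictor <- function(data, eq) {
  stopifnot(inherits(eq, "risk_equation"))
  if (!"sex" %in% names(data)) stop_data("person table lacks a `sex` column.")
  n <- nrow(data)
  lp <- numeric(n)
  for (sx in c("F", "M")) {
    idx <- which(data$sex == sx)
    if (!length(idx)) next
    cmp <- if (sx == "F") eq$female else eq$male
    lp[idx] <- lp_one_sex(data[idx, , drop = FALSE], cmp)
  }
  lp
}

lp_one_sex <- function(rows, cmp) {
  vals <- lapply(cmp$terms, function(tm) term_value(rows, tm) - tm$center)
  names(vals) <- vapply(cmp$terms, `[[`, character(1), "name")
  lp <- numeric(nrow(rows))
  for (i in seq_along(vals)) lp <- lp + cmp$terms[[i]]$coefficient * vals[[i]]
  for (ia in cmp$interactions) {
    lp <- lp + ia$coefficient * vals[[ia$terms[1]]] * vals[[ia$terms[2]]]
  }
  lp
}

term_value <- function(rows, tm) {
  src <- tm$source
  if (!src %in% names(rows))
    stop_cfg(sprintf("equation term '%s' references unknown predictor column '%s'.",
                     tm$name, src))
  x <- rows[[src]]
  if (anyNA(x)) {
    ids <- if ("person_id" %in% names(rows)) {
      paste(head(rows$person_id[is.na(x)], 5), collapse = ", ")
    } else {
      paste(head(which(is.na(x)), 5), collapse = ", ")
    }
    stop_data(sprintf("missing value for predictor '%s' (persons: %s).", src, ids))
  }
  switch(tm$transform,
         identity = as.numeric(x),
         log = log(as.numeric(x)),
         indicator = as.numeric(as.character(x) == as.character(tm$level)))
}

#' Absolute predicted risk at the equation horizon
#'
#' `risk = 1 - S0(h)^exp(LP)`: the Cox-form absolute risk at the fixed
#' horizon, with `S0(h)` the sex-specific baseline survival. The result
#' lies in `[0, 1)` and is strictly increasing in the linear predictor.
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of probabilities.
#' @examples
#' eq <- default_risk_equation()
#' cohort <- generate_cohort(sim_config(n_total = 100, seed = 1))
#' head(predicted_risk(cohort$persons, eq))
#' @export
predicted_risk <- function(data, eq) {
  lp <- linear_predictor(data, eq)
  s0 <- ifelse(data$sex == "F", eq$female$baseline_survival,
               eq$male$baseline_survival)
  1 - s0^exp(lp)
}

#' Score a cohort table
#'
#' @inheritParams linear_predictor
#' @param persons Person tibble (must carry `person_id`).
#' @return A tibble with columns `person_id` and `predicted_risk`, one row
#'   per input row, in input order.
#' @export
score_cohort <- function(persons, eq) {
  if (nrow(persons) == 0L) {
    return(tibble::tibble(person_id = character(), predicted_risk = numeric()))
  }
  tibble::tibble(person_id = persons$person_id,
                 predicted_risk = predicted_risk(persons, eq))
}
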