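#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rexp rnorm runif sd
#' @importFrom utils head
NULL

# Round half away from zero (the convention of printed clinical tables),
# unlike base round()'s round-half-even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage as printed in descriptive tables
#'
#' Computes `100 * num / denom` rounded half-up to one decimal place, the
#' rounding convention of printed cohort description tables. Returns `NA`
#' when the denominator is zero rather than dividing by zero.
#'
#' @param num Numerator count (vectorised).
#' @param denom Denominator count.
#' @param digits Decimal places to keep (default 1).
#' @return Numeric vector of percentages on the 0-100 scale.
#' @examples
#' describe_pct(28734, 495388) # 5.8
#' describe_pct(4456, 28734)   # 15.5
#' @export
describe_pct <- function(num, denom, digits = 1) {
  out <- 100 * num / denom
  out[!is.finite(out)] <- NA_real_
  round_half_up(out, digits)
}

# Days-per-year convention used for every date difference in the package.
DAYS_PER_YEAR <- 365.25

years_between <- function(from, to) {
  as.numeric(difftime(as.Date(to), as.Date(from), units = "days")) / DAYS_PER_YEAR
}

# Derive a stage-specific seed from the run seed so pipeline stages are
# individually reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, outcomes = 23L, build = 37L, score = 41L,
               survival = 53L, calibrate = 67L, describe = 79L)
  off <- offsets[[stage]] %||% 97L
  as.integer((as.double(seed) * 101 + off) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_cfg <- function(msg, ...) abort(msg, class = "cvdcalib_config_error", ...)
stop_data <- function(msg, ...) abort(msg, class = "cvdcalib_data_error", ...)
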