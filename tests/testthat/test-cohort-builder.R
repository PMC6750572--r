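test_that("age eligibility is inclusive of 30 and 74 and excludes beyond", {
  persons <- make_persons(4, age = c(29.9, 30, 74.9, 75))
  res <- apply_exclusions(persons)
  expect_equal(res$flow$in_age_range, 2)
  expect_setequal(res$eligible$person_id, c("P0002", "P0003"))
  expect_equal(res$flow$final_eligible, 2)
})

test_that("exclusion cascade counts each person once, in rule order", {
  # 8 records: 2 out-of-age, 1 prior CVD, 1 renal, 1 missing smoking,
  # 1 missing cholesterol, 1 failing CVD+smoking (counted at CVD), 1 clean
  persons <- make_persons(8)
  persons$age_at_index <- c(20, 80, 50, 50, 50, 50, 50, 50)
  persons$prior_cvd <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  persons$prior_renal_failure <- c(FALSE, FALSE, FALSE, TRUE, rep(FALSE, 4))
  persons$smoker_status[c(5, 7)] <- NA
  persons$tchdl[6] <- NA
  res <- apply_exclusions(persons)
  # independent per-record evaluation
  in_age <- persons$age_at_index >= 30 & persons$age_at_index <= 74
  first_fail <- vapply(which(in_age), function(i) {
    p <- persons[i, ]
    if (p$prior_cvd || p$prior_renal_failure) "cvd_renal"
    else if (is.na(p$smoker_status)) "smoking"
    else if (is.na(p$tchdl)) "cholesterol"
    else "eligible"
  }, character(1))
  expect_equal(res$flow$in_age_range, sum(in_age))
  expect_equal(res$flow$excluded_prior_cvd_or_renal, sum(first_fail == "cvd_renal"))
  expect_equal(res$flow$excluded_missing_smoking, sum(first_fail == "smoking"))
  expect_equal(res$flow$excluded_missing_cholesterol, sum(first_fail == "cholesterol"))
  expect_equal(res$flow$final_eligible, sum(first_fail == "eligible"))
  expect_equal(nrow(res$eligible), res$flow$final_eligible)
})

test_that("flow conservation holds on random fixtures and exclusion is idempotent", {
  set.seed(20)
  for (i in 1:5) {
    n <- 200
    persons <- make_persons(n,
                            age = runif(n, 20, 85),
                            prior_cvd = runif(n) < 0.2,
                            prior_renal = runif(n) < 0.05)
    persons$smoker_status[runif(n) < 0.1] <- NA
    persons$tchdl[runif(n) < 0.1] <- NA
    res <- apply_exclusions(persons)
    f <- res$flow
    expect_equal(f$in_age_range,
                 f$excluded_prior_cvd_or_renal + f$excluded_missing_smoking +
                   f$excluded_missing_cholesterol + f$final_eligible)
    again <- apply_exclusions(res$eligible)
    expect_identical(again$eligible, res$eligible)
    expect_equal(again$flow$excluded_prior_cvd_or_renal +
                   again$flow$excluded_missing_smoking +
                   again$flow$excluded_missing_cholesterol, 0)
  }
  expect_error(apply_exclusions(make_persons(2, age = c(NA, 50))),
               "age_at_index", class = "cvdcalib_data_error")
})

test_that("exposure window is half-open: [index - 5y, index)", {
  persons <- make_persons(1, index_date = as.Date("2010-06-15"))
  contact <- function(days_before, setting = "community_face_to_face") {
    tibble::tibble(person_id = "P0001",
                   contact_date = as.Date("2010-06-15") - days_before,
                   setting = setting, diagnosis_code = NA_character_)
  }
  expect_true(ascertain_smi(persons, contact(1))$smi)           # interior
  expect_false(ascertain_smi(persons, contact(0))$smi)          # same day
  expect_false(ascertain_smi(persons, contact(floor(5 * 365.25) + 1))$smi)
  expect_true(ascertain_smi(persons, contact(floor(5 * 365.25)))$smi)
  expect_false(ascertain_smi(persons, contact(100, "other"))$smi)
  expect_false(ascertain_smi(persons, contact(-30))$smi)        # post-index
})

test_that("mixed contact fixture matches a brute-force window scan", {
  set.seed(9)
  persons <- make_persons(5, index_date = as.Date("2012-01-01") + c(0, 50, 400, 900, 2000))
  contacts <- tibble::tibble(
    person_id = sample(persons$person_id, 20, TRUE),
    contact_date = as.Date("2004-01-01") + sample.int(4000, 20),
    setting = sample(c("inpatient", "community_face_to_face", "other"), 20, TRUE),
    diagnosis_code = NA_character_)
  got <- ascertain_smi(persons, contacts)
  oracle <- vapply(seq_len(5), function(i) {
    any(vapply(seq_len(20), function(j) {
      if (contacts$person_id[j] != persons$person_id[i]) return(FALSE)
      gap <- as.numeric(persons$index_date[i] - contacts$contact_date[j]) / 365.25
      contacts$setting[j] %in% c("inpatient", "community_face_to_face") &&
        gap > 0 && gap <= 5
    }, logical(1)))
  }, logical(1))
  expect_equal(got$smi, oracle)
  bad <- dplyr::mutate(contacts[1, ], person_id = "ghost")
  expect_error(ascertain_smi(persons, bad), "unknown person",
               class = "cvdcalib_data_error")
})

test_that("psychosis requires an F20-F31 code on any contact, any date", {
  persons <- make_persons(3, index_date = as.Date("2010-01-01"))
  base <- ascertain_smi(persons, tibble::tibble(
    person_id = persons$person_id,
    contact_date = as.Date("2009-06-01"),
    setting = "community_face_to_face",
    diagnosis_code = NA_character_))
  expect_true(all(base$smi))
  # post-index F25 qualifies; all-null codes do not
  contacts <- tibble::tibble(
    person_id = c("P0001", "P0001", "P0002"),
    contact_date = as.Date(c("2009-06-01", "2011-03-01", "2009-06-01")),
    setting = c("community_face_to_face", "other", "community_face_to_face"),
    diagnosis_code = c(NA, "F25", NA))
  flags <- ascertain_psychosis(base, contacts)
  expect_equal(flags$psychosis, c(TRUE, FALSE, FALSE))
  expect_equal(flags$smi_non_psychosis, c(FALSE, TRUE, TRUE))
})

test_that("the F-code family range is F20-F31 inclusive, enumerated", {
  persons <- make_persons(15, index_date = as.Date("2010-01-01"))
  codes <- paste0("F", 19:33)
  contacts <- tibble::tibble(
    person_id = persons$person_id,
    contact_date = as.Date("2009-06-01"),
    setting = "inpatient",
    diagnosis_code = codes)
  flags <- ascertain_psychosis(ascertain_smi(persons, contacts), contacts)
  fam <- 19:33
  expect_equal(flags$psychosis, fam >= 20 & fam <= 31)
  # sub-codes after the decimal are ignored; malformed codes warn, non-fatal
  contacts$diagnosis_code <- c("F20.9", "F31.74", "garbled", paste0("F", 32:43))
  expect_warning(
    flags2 <- ascertain_psychosis(ascertain_smi(persons, contacts), contacts),
    "malformed")
  expect_equal(which(flags2$psychosis), 1:2)
})

test_that("prioritised ethnicity is the max under the priority order, order-free", {
  expect_equal(prioritized_ethnicity("Pacific;Maori"), "Maori")
  expect_equal(prioritized_ethnicity("European/other"), "European/other")
  expect_equal(prioritized_ethnicity("Some free text"), "European/other")
  perms <- expand.grid(a = ETH_LEVELS, b = ETH_LEVELS, stringsAsFactors = FALSE)
  got <- prioritized_ethnicity(paste(perms$a, perms$b, sep = ";"))
  oracle <- apply(perms, 1, function(r) {
    ETH_LEVELS[min(match(r, ETH_LEVELS))]
  })
  expect_equal(got, unname(oracle))
  expect_error(prioritized_ethnicity(""), "ethnicity",
               class = "cvdcalib_data_error")
})

test_that("cohort_flow validates its arithmetic", {
  f <- cohort_flow(100, 90, 10, 2, 3)
  expect_equal(f$final_eligible, 75)
  expect_equal(tidy(f)$count, c(100, 90, 10, 2, 3, 75))
  expect_error(cohort_flow(100, 110, 0, 0, 0), class = "cvdcalib_data_error")
  expect_error(cohort_flow(100, 90, 95, 0, 0), class = "cvdcalib_data_error")
})
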