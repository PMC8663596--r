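test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_admissions = -1), "n_admissions",
               class = "sbdhrisk_config_error")
  dp <- default_demographic_prevalences()
  dp$age_group <- c("18-39" = 0.5, "40-64" = 0.3, ">64" = 0.1)
  expect_error(cohort_config(demographic_prevalences = dp),
               "age_group", class = "sbdhrisk_config_error")
  cp <- default_clinical_prevalences()
  expect_error(cohort_config(clinical_prevalences = cp[-1]),
               "clinical_prevalences", class = "sbdhrisk_config_error")
  expect_error(cohort_config(structured_sbdh_coding_rate = 1.5),
               "structured_sbdh_coding_rate", class = "sbdhrisk_config_error")
  expect_error(cohort_config(true_log_odds = c(not_a_term = 0.5)),
               "not_a_term", class = "sbdhrisk_config_error")
})

test_that("a null outcome model yields ~50% prevalence", {
  b <- generate_cohort(null_config(n = 1000, seed = 11),
                       include_notes = FALSE)
  prev <- mean(b$truth$od_outcome)
  half_width <- 2.576 * sqrt(0.25 / 1000)
  expect_lt(abs(prev - 0.5), half_width)
})

test_that("identical configurations give identical cohorts, different seeds differ", {
  cfg <- null_config(n = 120, seed = 5)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$notes, b2$notes)
  expect_identical(b1$diagnoses, b2$diagnoses)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  p1 <- write_cohort(b1, d1)
  p2 <- write_cohort(b2, d2)
  for (f in names(p1)) {
    expect_identical(readBin(p1[[f]], "raw", file.size(p1[[f]])),
                     readBin(p2[[f]], "raw", file.size(p2[[f]])))
  }
  b3 <- generate_cohort(null_config(n = 120, seed = 6))
  expect_false(identical(b1$truth$od_outcome, b3$truth$od_outcome))
})

test_that("a single binary term recovers its configured odds ratio at scale", {
  cfg <- cohort_config(
    n_admissions = 200000,
    true_log_odds = c(drug_use_disorder = log(8.17)),
    seed = 31)
  b <- generate_cohort(cfg, include_notes = FALSE)
  flag <- b$truth$drug_use_disorder
  y <- b$truth$od_outcome
  a <- sum(flag & y); bb <- sum(flag & !y)
  cc <- sum(!flag & y); dd <- sum(!flag & !y)
  est <- crude_or(a, bb, cc, dd)
  se <- sqrt(1 / a + 1 / bb + 1 / cc + 1 / dd)
  expect_lt(abs(log(est$or) - log(8.17)), 3.3 * se)
})

test_that("marginal covariate prevalences match the configuration at scale", {
  cfg <- cohort_config(n_admissions = 100000, seed = 987)
  b <- generate_cohort(cfg, include_notes = FALSE)
  tr <- b$truth
  n <- nrow(tr)
  # ~46 levels are checked simultaneously: hold the family-wise error at 1%
  z_fw <- qnorm(1 - 0.01 / (2 * 46))
  check <- function(observed_p, p) {
    expect_lt(abs(observed_p - p), z_fw * sqrt(p * (1 - p) / n) + 1e-12)
  }
  for (v in names(cfg$demographic_prevalences)) {
    for (l in names(cfg$demographic_prevalences[[v]])) {
      check(mean(tr[[v]] == l), cfg$demographic_prevalences[[v]][[l]])
    }
  }
  for (v in names(cfg$clinical_prevalences)) {
    check(mean(tr[[v]]), cfg$clinical_prevalences[[v]])
  }
  for (v in names(cfg$sbdh_truth_prevalences)) {
    for (l in names(cfg$sbdh_truth_prevalences[[v]])) {
      check(mean(tr[[v]] == l), cfg$sbdh_truth_prevalences[[v]][[l]])
    }
  }
})

test_that("rendered notes verbalize documented statuses in the right sections", {
  cfg <- null_config(n = 60, seed = 21)
  b <- generate_cohort(cfg)
  # negated smoking template lands in the discharge summary Social History
  ds <- b$notes[b$notes$note_type == "discharge_summary", ]
  tr <- b$truth[match(ds$admission_id, b$truth$admission_id), ]
  none_idx <- which(tr$smoking == "none")
  expect_gt(length(none_idx), 0)
  for (i in none_idx) {
    sec <- extract_sections(ds[i, ])
    expect_true(grepl("smok|tobacco", sec$body[sec$header == "Social History"],
                      ignore.case = TRUE))
  }
  # history phrasing for former illicit drug use
  former_idx <- which(tr$illicit_drug_use == "former")
  for (i in former_idx) {
    sec <- extract_sections(ds[i, ])
    expect_match(sec$body[sec$header == "Social History"],
                 "(?i)(h/o|history|past)", perl = TRUE)
  }
})

test_that("all-unknown admissions produce sections without SBDH sentences", {
  prev <- list(
    housing_insecurity = c(no = 0, yes = 0, unknown = 1),
    unemployment = c(no = 0, yes = 0, unknown = 1),
    social_isolation = c(no = 0, yes = 0, unknown = 1),
    alcohol_use = c(none = 0, former = 0, current = 0, unknown = 1),
    smoking = c(none = 0, former = 0, current = 0, unknown = 1),
    illicit_drug_use = c(none = 0, former = 0, current = 0, unknown = 1))
  cfg <- cohort_config(n_admissions = 30, sbdh_truth_prevalences = prev,
                       true_log_odds = setNames(numeric(0), character(0)),
                       intercept = qlogis(0.5), seed = 3)
  b <- generate_cohort(cfg)
  for (i in seq_len(nrow(b$notes))) {
    sec <- extract_sections(b$notes[i, ])
    for (body in sec$body) {
      expect_identical(nrow(annotate_section(body)), 0L)
    }
  }
})

test_that("cohort files round-trip losslessly, including awkward text", {
  cfg <- null_config(n = 10, seed = 9)
  b <- generate_cohort(cfg)
  b$notes$text[1] <- "Line one.\n\"Quoted\", with comma\nand a backslash \\ too."
  dir <- tempfile()
  write_cohort(b, dir)
  back <- read_cohort(dir)
  expect_identical(back$notes$text, b$notes$text)
  expect_identical(back$notes$chart_time, b$notes$chart_time)
  expect_identical(back$admissions$admission_id, b$admissions$admission_id)
  expect_identical(back$admissions$age_years, b$admissions$age_years)
  expect_identical(back$diagnoses$icd9_code, b$diagnoses$icd9_code)
  expect_identical(back$truth$od_outcome, b$truth$od_outcome)
})

test_that("an empty cohort writes valid files with headers and no rows", {
  cfg <- null_config(n = 0)
  b <- generate_cohort(cfg)
  dir <- tempfile()
  paths <- write_cohort(b, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(dir)
  expect_identical(nrow(back$admissions), 0L)
  expect_identical(nrow(back$diagnoses), 0L)
  expect_identical(nrow(back$notes), 0L)
  expect_named(back$admissions,
               c("admission_id", "patient_id", "age_years", "gender", "race",
                 "marital_status", "insurance", "admit_time",
                 "discharge_time"))
})

test_that("the intercept calibration hits the target marginal prevalence", {
  cfg <- cohort_config(n_admissions = 200000, seed = 55)
  b <- generate_cohort(cfg, include_notes = FALSE)
  # combined Monte-Carlo error of calibration (1e6 draws) and realization
  expect_lt(abs(mean(b$truth$od_outcome) - 0.0035), 3e-4)
})

test_that("the template bank precondition is enforced", {
  tb <- default_template_bank()
  tb$smoking$negated <- tb$smoking$negated[1:2]
  expect_error(render_notes(generate_cohort(null_config(5))$truth,
                            templates = tb),
               "smoking", class = "sbdhrisk_config_error")
})
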