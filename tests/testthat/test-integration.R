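make_notes <- function(ids) {
  tibble::tibble(
    note_id = paste0("N", seq_along(ids)), admission_id = ids,
    note_type = "discharge_summary",
    chart_time = "2004-01-01T00:00:00",
    text = "Social History:\nNo alcohol use.\n")
}

test_that("inclusion criteria fire once each and the report balances", {
  admissions <- tibble::tibble(
    admission_id = c("A1", "A2", "A3"),
    age_years = c(17L, 30L, 30L))
  notes <- make_notes(c("A1", "A3"))
  res <- apply_inclusion_criteria(admissions, notes)
  r <- res$report
  expect_identical(r$n_input, 3L)
  expect_identical(r$n_excluded_age, 1L)
  expect_identical(r$n_excluded_no_note, 1L)
  expect_identical(r$n_final, 1L)
  expect_identical(res$admissions$admission_id, "A3")
  expect_identical(r$n_input - r$n_excluded_age - r$n_excluded_no_note,
                   r$n_final)
})

test_that("fully eligible cohorts report zero exclusions; age 18 is retained", {
  admissions <- tibble::tibble(admission_id = c("A1", "A2"),
                               age_years = c(18L, 50L))
  res <- apply_inclusion_criteria(admissions, make_notes(c("A1", "A2")))
  expect_identical(res$report$n_excluded_age, 0L)
  expect_identical(res$report$n_excluded_no_note, 0L)
  expect_identical(res$report$n_final, 2L)
  expect_true("A1" %in% res$admissions$admission_id)
})

test_that("structured yes overrides NLP no/unknown; NLP stands otherwise", {
  nlp <- tibble::tibble(
    variable = sbdh_vars,
    status = c("no", "yes", "unknown", "current", "unknown", "none"),
    provenance = c("nlp", "nlp", "absent", "nlp", "absent", "nlp"))
  structured <- tibble::tibble(
    housing_insecurity = "yes", unemployment = "absent",
    social_isolation = "yes")
  merged <- merge_sbdh(nlp, structured)
  expect_identical(merged$status[merged$variable == "housing_insecurity"],
                   "yes")
  expect_identical(merged$provenance[merged$variable == "housing_insecurity"],
                   "structured")
  expect_identical(merged$status[merged$variable == "unemployment"], "yes")
  expect_identical(merged$provenance[merged$variable == "unemployment"],
                   "nlp")
  expect_identical(merged$status[merged$variable == "social_isolation"],
                   "yes")
  # substance-use variables are NLP-only
  expect_identical(merged$status[merged$variable == "alcohol_use"], "current")
  # idempotence and monotonicity toward positive findings
  expect_identical(merge_sbdh(merged, structured), merged)
  all_absent <- tibble::tibble(housing_insecurity = "absent",
                               unemployment = "absent",
                               social_isolation = "absent")
  expect_identical(merge_sbdh(merged, all_absent)$status, merged$status)
})

test_that("silent sources merge to unknown", {
  nlp <- tibble::tibble(variable = sbdh_vars, status = "unknown",
                        provenance = "absent")
  structured <- tibble::tibble(housing_insecurity = "absent",
                               unemployment = "absent",
                               social_isolation = "absent")
  merged <- merge_sbdh(nlp, structured)
  expect_true(all(merged$status == "unknown"))
  expect_true(all(merged$provenance == "absent"))
})

test_that("the analysis table enforces level sets and reference coding", {
  cfg <- null_config(n = 80, seed = 13)
  b <- generate_cohort(cfg)
  res <- integrate_cohort(b$admissions, b$diagnoses, b$notes)
  tab <- res$analysis_table
  expect_identical(nrow(tab), res$filter_report$n_final)
  expect_identical(levels(tab$age_group), c("18-39", "40-64", ">64"))
  expect_identical(levels(tab$insurance),
                   c("private", "Medicaid", "Medicare", "government_other",
                     "self_pay"))
  expect_identical(levels(tab$alcohol_use),
                   c("none", "former", "current", "unknown"))
  expect_identical(levels(tab$housing_insecurity), c("no", "yes", "unknown"))
  # prevalence summary partitions n_final within every variable
  prev <- prevalence_table(tab)
  categorical <- setdiff(unique(prev$variable),
                         c("drug_use_disorder", "bipolar_disorder",
                           "tobacco_use_disorder",
                           "major_depressive_disorder",
                           "alcohol_use_disorder", "cirrhosis", "copd",
                           "renal_insufficiency"))
  for (v in categorical) {
    sub <- prev[prev$variable == v, ]
    expect_identical(sum(sub$overall_n), nrow(tab))
    expect_identical(sum(sub$od_n), sum(tab$outcome))
  }

  bad <- b$admissions
  bad$insurance[1] <- "gold_plan"
  expect_error(
    integrate_cohort(bad, b$diagnoses, b$notes),
    "insurance", class = "sbdhrisk_data_error")
})

test_that("with perfect extraction the analysis rows equal the ground truth", {
  cfg <- null_config(n = 250, seed = 77)
  b <- generate_cohort(cfg)
  res <- integrate_cohort(b$admissions, b$diagnoses, b$notes)
  tab <- res$analysis_table
  tt <- b$truth[match(tab$admission_id, b$truth$admission_id), ]
  expect_identical(as.character(tab$age_group), tt$age_group)
  expect_identical(as.character(tab$gender), tt$gender)
  expect_identical(as.character(tab$race), tt$race)
  expect_identical(as.character(tab$marital_status), tt$marital_status)
  expect_identical(as.character(tab$insurance), tt$insurance)
  expect_identical(tab$outcome, tt$od_outcome)
  for (v in c("drug_use_disorder", "copd")) {
    expect_identical(tab[[v]], tt[[v]])
  }
  rec <- recovery_rate(b$truth, res$profiles, tab$admission_id)
  expect_identical(rec[["hits"]], rec[["total"]])
})

test_that("a silent-notes admission is all-unknown in the analysis table", {
  admissions <- tibble::tibble(
    admission_id = "A1", patient_id = "P1", age_years = 40L,
    gender = "male", race = "White", marital_status = "married",
    insurance = "private", admit_time = "2004-01-01T00:00:00",
    discharge_time = "2004-01-05T00:00:00")
  notes <- tibble::tibble(
    note_id = "N1", admission_id = "A1", note_type = "discharge_summary",
    chart_time = "2004-01-02T00:00:00",
    text = "Social History:\n\nMedications:\nnone\n")
  diagnoses <- tibble::tibble(admission_id = character(0),
                              icd9_code = character(0))
  res <- integrate_cohort(admissions, diagnoses, notes)
  tab <- res$analysis_table
  for (v in sbdh_vars) {
    expect_identical(as.character(tab[[v]]), "unknown")
  }
  expect_false(tab$outcome)
})
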