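#' Configuration for the synthetic ICU cohort generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. The defaults reproduce the statistical structure the
#' downstream analysis assumes: marginal covariate prevalences equal to the
#' overall cohort proportions of the source study population, an outcome
#' generated from a logistic model whose default coefficients are the natural
#' logs of the published adjusted odds ratios, and an intercept calibrated so
#' that the marginal prevalence of nonfatal overdose is approximately 0.35%.
#'
#' @param n_admissions Number of admissions to simulate.
#' @param demographic_prevalences Named list of named probability vectors for
#'   `age_group`, `gender`, `race`, `marital_status` and `insurance`; each must
#'   sum to 1.
#' @param clinical_prevalences Named probability vector over the 8 clinical
#'   comorbidity flags.
#' @param sbdh_truth_prevalences Named list of categorical distributions over
#'   each SBDH variable's statuses, including `"unknown"` as the probability
#'   that the status is simply not documented anywhere.
#' @param true_log_odds Named vector of true log odds ratios of the
#'   outcome-generating model. Names are either a clinical flag name
#'   (e.g. `"drug_use_disorder"`) or `"variable:level"` for categorical terms
#'   (e.g. `"insurance:Medicaid"`). Terms not listed have coefficient 0.
#' @param intercept Intercept of the outcome model on the log-odds scale, or
#'   `NULL` (default) to calibrate it numerically to `target_prevalence`.
#' @param target_prevalence Marginal outcome prevalence used when calibrating
#'   the intercept. Default 0.0035 (0.35%).
#' @param structured_sbdh_coding_rate Probability that a true positive social
#'   SBDH status also receives an ICD-9 code in the diagnoses table. The small
#'   default emulates the near-absence of structured SBDH coding.
#' @param note_type_availability Named probability vector: per note type, the
#'   probability an admission has at least one note of that type.
#' @param duplicate_note_rate Probability that an available note type gets a
#'   second, later note (exercises the last-note-per-type rule).
#' @param minor_rate Fraction of admissions generated with age below 18, to
#'   exercise the age exclusion.
#' @param drug_correlation Optional correlation knob: probability that an
#'   admission with a `drug_use_disorder` flag has its `illicit_drug_use`
#'   truth forced to `"current"`. Default 0 (full independence).
#' @param seed Integer seed; identical configurations produce byte-identical
#'   cohorts.
#'
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_admissions = 48869,
                          demographic_prevalences = default_demographic_prevalences(),
                          clinical_prevalences = default_clinical_prevalences(),
                          sbdh_truth_prevalences = default_sbdh_truth_prevalences(),
                          true_log_odds = default_true_log_odds(),
                          intercept = NULL,
                          target_prevalence = 0.0035,
                          structured_sbdh_coding_rate = 0.02,
                          note_type_availability = c(discharge_summary = 0.95,
                                                     social_work = 0.30,
                                                     rehab_services = 0.10),
                          duplicate_note_rate = 0.15,
                          minor_rate = 0.01,
                          drug_correlation = 0,
                          seed = 1L) {
  config <- structure(
    list(
      n_admissions = n_admissions,
      demographic_prevalences = demographic_prevalences,
      clinical_prevalences = clinical_prevalences,
      sbdh_truth_prevalences = sbdh_truth_prevalences,
      true_log_odds = true_log_odds,
      intercept = intercept,
      target_prevalence = target_prevalence,
      structured_sbdh_coding_rate = structured_sbdh_coding_rate,
      note_type_availability = note_type_availability,
      duplicate_note_rate = duplicate_note_rate,
      minor_rate = minor_rate,
      drug_correlation = drug_correlation,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(config)
}

#' Validate a cohort configuration
#'
#' Checks every invariant of the configuration and fails with a
#' `sbdhrisk_config_error` naming the offending field.
#'
#' @param config A `"cohort_config"` object.
#' @return The validated configuration, invisibly usable downstream.
#' @export
validate_cohort_config <- function(config) {
  if (!is.numeric(config$n_admissions) || length(config$n_admissions) != 1L ||
      is.na(config$n_admissions) || config$n_admissions < 0 ||
      config$n_admissions != floor(config$n_admissions)) {
    abort("`n_admissions` must be a single nonnegative integer.",
          class = "sbdhrisk_config_error")
  }
  for (v in names(.demographic_levels)) {
    p <- config$demographic_prevalences[[v]]
    if (is.null(p)) {
      abort(sprintf("`demographic_prevalences` is missing `%s`.", v),
            class = "sbdhrisk_config_error")
    }
    .assert_distribution(p, paste0("demographic_prevalences$", v),
                         .demographic_levels[[v]])
  }
  cp <- config$clinical_prevalences
  if (!setequal(names(cp), .clinical_vars)) {
    abort("`clinical_prevalences` must name exactly the 8 clinical variables.",
          class = "sbdhrisk_config_error")
  }
  for (v in .clinical_vars) .assert_scalar_prob(cp[[v]],
                                               paste0("clinical_prevalences$", v))
  for (v in .sbdh_vars) {
    p <- config$sbdh_truth_prevalences[[v]]
    if (is.null(p)) {
      abort(sprintf("`sbdh_truth_prevalences` is missing `%s`.", v),
            class = "sbdhrisk_config_error")
    }
    .assert_distribution(p, paste0("sbdh_truth_prevalences$", v),
                         .sbdh_levels[[v]])
  }
  tlo <- config$true_log_odds
  if (length(tlo) && (is.null(names(tlo)) || anyNA(tlo) || !is.numeric(tlo))) {
    abort("`true_log_odds` must be a named, non-missing numeric vector.",
          class = "sbdhrisk_config_error")
  }
  bad <- setdiff(names(tlo), .model_term_names())
  if (length(bad)) {
    abort(sprintf("`true_log_odds` has unrecognized terms: %s.",
                  paste(bad, collapse = ", ")),
          class = "sbdhrisk_config_error")
  }
  if (!is.null(config$intercept) &&
      (!is.numeric(config$intercept) || length(config$intercept) != 1L ||
       is.na(config$intercept))) {
    abort("`intercept` must be NULL or a single finite number.",
          class = "sbdhrisk_config_error")
  }
  .assert_scalar_prob(config$target_prevalence, "target_prevalence")
  .assert_scalar_prob(config$structured_sbdh_coding_rate,
                      "structured_sbdh_coding_rate")
  av <- config$note_type_availability
  if (!setequal(names(av), .note_types)) {
    abort("`note_type_availability` must name the 3 note types.",
          class = "sbdhrisk_config_error")
  }
  for (v in .note_types) .assert_scalar_prob(av[[v]],
                                             paste0("note_type_availability$", v))
  .assert_scalar_prob(config$duplicate_note_rate, "duplicate_note_rate")
  .assert_scalar_prob(config$minor_rate, "minor_rate")
  .assert_scalar_prob(config$drug_correlation, "drug_correlation")
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      is.na(config$seed)) {
    abort("`seed` must be a single integer.", class = "sbdhrisk_config_error")
  }
  config
}

#' Default marginal prevalences of the demographic variables
#'
#' Overall-cohort proportions of the emulated ICU study population.
#'
#' @return Named list of probability vectors.
#' @export
default_demographic_prevalences <- function() {
  list(
    age_group = c("18-39" = 0.0965, "40-64" = 0.3863, ">64" = 0.5172),
    gender = c(male = 0.5614, female = 0.4386),
    race = c(White = 0.7174, Black = 0.0961, Hispanic = 0.0340,
             other = 0.1525),
    marital_status = c(married = 0.4784, divorced = 0.0750, widowed = 0.1436,
                       single = 0.2523, unknown = 0.0507),
    insurance = c(private = 0.3145, Medicaid = 0.0881, Medicare = 0.5600,
                  government_other = 0.0271, self_pay = 0.0103)
  )
}

#' Default prevalences of the 8 clinical comorbidity flags
#' @return Named probability vector.
#' @export
default_clinical_prevalences <- function() {
  c(drug_use_disorder = 0.0306, bipolar_disorder = 0.0206,
    tobacco_use_disorder = 0.0670, major_depressive_disorder = 0.0061,
    alcohol_use_disorder = 0.0843, cirrhosis = 0.0497,
    copd = 0.1161, renal_insufficiency = 0.1669)
}

#' Default ground-truth status distributions of the six SBDH variables
#'
#' `"unknown"` is the probability that the status is not documented in any
#' note (suppressed documentation), mirroring the large undocumented fractions
#' observed in real ICU notes.
#'
#' @return Named list of categorical distributions.
#' @export
default_sbdh_truth_prevalences <- function() {
  list(
    housing_insecurity = c(no = 0.5549, yes = 0.0082, unknown = 0.4369),
    unemployment = c(no = 0.2593, yes = 0.0728, unknown = 0.6679),
    social_isolation = c(no = 0.4911, yes = 0.1335, unknown = 0.3754),
    alcohol_use = c(none = 0.3147, former = 0.0477, current = 0.2896,
                    unknown = 0.3480),
    smoking = c(none = 0.2857, former = 0.2462, current = 0.1423,
                unknown = 0.3258),
    illicit_drug_use = c(none = 0.2846, former = 0.0279, current = 0.0367,
                         unknown = 0.6508)
  )
}

#' Default true log odds ratios of the outcome-generating model
#'
#' One coefficient per non-reference model term; the defaults are the natural
#' logs of the published multivariable adjusted odds ratios, so that fitting
#' the generating model on a large simulated cohort should recover them.
#'
#' @return Named numeric vector of log odds ratios.
#' @export
default_true_log_odds <- function() {
  log(c(
    "age_group:40-64" = 0.65, "age_group:>64" = 0.16,
    "gender:female" = 1.13,
    "race:Black" = 0.51, "race:Hispanic" = 0.69, "race:other" = 0.59,
    "marital_status:divorced" = 1.56, "marital_status:widowed" = 0.76,
    "marital_status:single" = 1.03, "marital_status:unknown" = 2.85,
    "insurance:Medicaid" = 2.26, "insurance:Medicare" = 1.34,
    "insurance:government_other" = 1.90, "insurance:self_pay" = 1.83,
    "drug_use_disorder" = 8.17, "bipolar_disorder" = 2.69,
    "tobacco_use_disorder" = 0.53, "major_depressive_disorder" = 2.57,
    "alcohol_use_disorder" = 0.64, "cirrhosis" = 1.65,
    "copd" = 1.65, "renal_insufficiency" = 0.62,
    "housing_insecurity:yes" = 0.98, "housing_insecurity:unknown" = 0.89,
    "unemployment:yes" = 1.10, "unemployment:unknown" = 0.73,
    "social_isolation:yes" = 0.97, "social_isolation:unknown" = 1.01,
    "alcohol_use:former" = 0.66, "alcohol_use:current" = 1.11,
    "alcohol_use:unknown" = 1.05,
    "smoking:former" = 0.92, "smoking:current" = 1.40,
    "smoking:unknown" = 1.12,
    "illicit_drug_use:former" = 2.09, "illicit_drug_use:current" = 2.06,
    "illicit_drug_use:unknown" = 1.05
  ))
}

# every legal model term name: categorical "var:level" (non-reference levels)
# plus the binary clinical flags
.model_term_names <- function() {
  cat_terms <- unlist(lapply(names(.demographic_levels), function(v) {
    paste0(v, ":", .demographic_levels[[v]][-1])
  }))
  sbdh_terms <- unlist(lapply(.sbdh_vars, function(v) {
    paste0(v, ":", .sbdh_levels[[v]][-1])
  }))
  c(cat_terms, .clinical_vars, sbdh_terms)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_admissions:", x$n_admissions, "\n")
  cat("  seed:", x$seed, "\n")
  cat("  intercept:",
      if (is.null(x$intercept)) {
        sprintf("calibrated at generation (target prevalence %.4f)",
                x$target_prevalence)
      } else {
        format(x$intercept)
      }, "\n")
  cat("  model terms with nonzero true log odds:",
      sum(x$true_log_odds != 0), "\n")
  invisible(x)
}
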