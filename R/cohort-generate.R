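# intercepts calibrated once per distinct covariate/coefficient setting
.calibration_cache <- new.env(parent = emptyenv())

# sample the ground-truth covariates of `n` admissions (no outcome yet)
.sample_truth_covariates <- function(n, config) {
  dp <- config$demographic_prevalences
  draw_cat <- function(p) {
    if (n == 0) return(character(0))
    sample(names(p), n, replace = TRUE, prob = p)
  }
  cov <- tibble::tibble(
    age_group = draw_cat(dp$age_group),
    gender = draw_cat(dp$gender),
    race = draw_cat(dp$race),
    marital_status = draw_cat(dp$marital_status),
    insurance = draw_cat(dp$insurance)
  )
  minor <- runif(n) < config$minor_rate
  age <- integer(n)
  age[minor] <- sample(1:17, sum(minor), replace = TRUE)
  ranges <- list("18-39" = 18:39, "40-64" = 40:64, ">64" = 65:89)
  for (g in names(ranges)) {
    idx <- which(!minor & cov$age_group == g)
    age[idx] <- sample(ranges[[g]], length(idx), replace = TRUE)
  }
  cov$age_years <- age
  for (v in .clinical_vars) {
    cov[[v]] <- runif(n) < config$clinical_prevalences[[v]]
  }
  for (v in .sbdh_vars) {
    cov[[v]] <- draw_cat(config$sbdh_truth_prevalences[[v]])
  }
  if (config$drug_correlation > 0) {
    force_cur <- cov$drug_use_disorder &
      (runif(n) < config$drug_correlation)
    cov$illicit_drug_use[force_cur] <- "current"
  }
  cov
}

# linear predictor (without intercept) of the outcome-generating model
.linear_predictor <- function(cov, true_log_odds) {
  lp <- numeric(nrow(cov))
  for (term in names(true_log_odds)) {
    beta <- true_log_odds[[term]]
    if (beta == 0) next
    if (grepl(":", term, fixed = TRUE)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      lp <- lp + beta * (cov[[parts[1]]] == parts[2])
    } else {
      lp <- lp + beta * cov[[term]]
    }
  }
  lp
}

#' Calibrate the outcome-model intercept to a target marginal prevalence
#'
#' No closed form exists for the intercept that yields a given marginal
#' outcome prevalence under a mixed categorical covariate model, so the
#' intercept is found by root-finding on the Monte-Carlo estimate of
#' `E[plogis(b0 + s)]`, where `s` is the linear predictor without intercept.
#' The covariate draw uses its own fixed internal seed, so calibration is
#' deterministic and independent of the cohort seed; results are cached per
#' distinct configuration.
#'
#' @param config A [cohort_config()] object.
#' @param n_mc Number of Monte-Carlo draws of the linear predictor.
#' @param target Target marginal prevalence; defaults to the configuration's
#'   `target_prevalence`.
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(config, n_mc = 1e6,
                                target = config$target_prevalence) {
  key <- rlang::hash(list(config$demographic_prevalences,
                          config$clinical_prevalences,
                          config$sbdh_truth_prevalences,
                          config$true_log_odds, config$minor_rate,
                          config$drug_correlation, target, n_mc))
  cached <- get0(key, envir = .calibration_cache)
  if (!is.null(cached)) return(cached)
  s <- withr::with_seed(7608014L, {
    cov <- .sample_truth_covariates(n_mc, config)
    .linear_predictor(cov, config$true_log_odds)
  })
  f <- function(b0) mean(plogis(b0 + s)) - target
  root <- stats::uniroot(f, lower = -30, upper = 10, tol = 1e-10)$root
  assign(key, root, envir = .calibration_cache)
  root
}

# concrete synthetic ICD-9 codes emitted by the generator, consistent with
# the default code map shipped in inst/extdata/code_map.yaml
.synthetic_code_pool <- list(
  drug_use_disorder = c("3040", "30400", "30420", "3054", "30560"),
  bipolar_disorder = c("29600", "29640", "29650", "29680"),
  tobacco_use_disorder = c("3051", "30510"),
  major_depressive_disorder = c("29620", "29630", "311"),
  alcohol_use_disorder = c("3030", "30390", "30500"),
  cirrhosis = c("5712", "5715"),
  copd = c("490", "4918", "49121", "496"),
  renal_insufficiency = c("5853", "5859", "586"),
  housing_insecurity = "V600",
  unemployment = "V620",
  social_isolation = c("V603", "V604"),
  nonfatal_od = c("96500", "96501", "96502", "96509", "E8500", "E8501",
                  "E8502"),
  filler = c("4019", "25000", "2720", "53081", "41401", "4280", "2859",
             "78079", "V5861")
)

.generate_diagnoses <- function(truth, config) {
  n <- nrow(truth)
  pieces <- list()
  for (v in .clinical_vars) {
    ids <- truth$admission_id[truth[[v]]]
    if (length(ids)) {
      pieces[[v]] <- tibble::tibble(
        admission_id = ids,
        icd9_code = sample(.synthetic_code_pool[[v]], length(ids),
                           replace = TRUE))
    }
  }
  od_ids <- truth$admission_id[truth$od_outcome]
  if (length(od_ids)) {
    pieces[["od"]] <- tibble::tibble(
      admission_id = od_ids,
      icd9_code = sample(.synthetic_code_pool$nonfatal_od, length(od_ids),
                         replace = TRUE))
  }
  for (v in .sbdh_social_vars) {
    pos <- truth$admission_id[truth[[v]] == "yes"]
    coded <- pos[runif(length(pos)) < config$structured_sbdh_coding_rate]
    if (length(coded)) {
      pieces[[paste0("sbdh_", v)]] <- tibble::tibble(
        admission_id = coded,
        icd9_code = sample(.synthetic_code_pool[[v]], length(coded),
                           replace = TRUE))
    }
  }
  n_filler <- if (n) 1L + stats::rpois(n, 2) else integer(0)
  if (sum(n_filler)) {
    pieces[["filler"]] <- tibble::tibble(
      admission_id = rep(truth$admission_id, n_filler),
      icd9_code = sample(.synthetic_code_pool$filler, sum(n_filler),
                         replace = TRUE))
  }
  out <- dplyr::bind_rows(pieces)
  if (!nrow(out)) {
    out <- tibble::tibble(admission_id = character(0),
                          icd9_code = character(0))
  }
  dplyr::arrange(out, .data$admission_id, .data$icd9_code)
}

.iso_time <- function(secs) {
  format(as.POSIXct(secs, origin = "2001-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%S")
}

#' Generate a synthetic ICU cohort with known ground truth
#'
#' Simulates `n_admissions` independent admissions: demographics, insurance,
#' the 8 clinical comorbidity flags, true SBDH statuses, a nonfatal-overdose
#' outcome drawn from the configured logistic model, an ICD-9 diagnoses table
#' implied by the flags (plus sparse structured SBDH coding), and templated
#' clinical notes in which every documented SBDH status is verbalized in the
#' appropriate note section.
#'
#' @param config A [cohort_config()] object.
#' @param include_notes If `FALSE`, skip note rendering (useful for large
#'   parameter-recovery simulations that fit the model on the truth table
#'   directly).
#' @param templates Template bank for note rendering; see
#'   [default_template_bank()].
#' @param suppress Character vector of SBDH variables whose mentions are
#'   omitted from the rendered notes (used to construct NLP-vs-structured
#'   conflicts).
#' @return A list of class `"cohort_bundle"` with elements `truth`,
#'   `admissions`, `diagnoses`, `notes` (tibbles) and `config`. Identical
#'   configurations yield identical bundles.
#' @export
generate_cohort <- function(config, include_notes = TRUE,
                            templates = default_template_bank(),
                            suppress = NULL) {
  validate_cohort_config(config)
  intercept <- config$intercept %||% calibrate_intercept(config)
  n <- config$n_admissions
  withr::with_seed(config$seed, {
    cov <- .sample_truth_covariates(n, config)
    lp <- intercept + .linear_predictor(cov, config$true_log_odds)
    od <- if (n) rbinom(n, 1, plogis(lp)) == 1 else logical(0)
    # synthetic 12-year admission window; exact dates carry no meaning
    admit_secs <- runif(n, 0, 12 * 365.25 * 86400)
    stay_secs <- runif(n, 2, 20) * 86400
    truth <- dplyr::bind_cols(
      tibble::tibble(
        admission_id = sprintf("A%06d", seq_len(n)),
        patient_id = sprintf("P%06d", seq_len(n))),
      cov,
      tibble::tibble(
        od_outcome = od,
        admit_time = .iso_time(admit_secs),
        discharge_time = .iso_time(admit_secs + stay_secs)))
    diagnoses <- .generate_diagnoses(truth, config)
    notes <- if (include_notes) {
      render_notes(truth, templates = templates,
                   availability = config$note_type_availability,
                   duplicate_rate = config$duplicate_note_rate,
                   seed = NULL, suppress = suppress)
    } else {
      .empty_notes()
    }
    admissions <- truth[, c("admission_id", "patient_id", "age_years",
                            "gender", "race", "marital_status", "insurance",
                            "admit_time", "discharge_time")]
    structure(list(truth = truth, admissions = admissions,
                   diagnoses = diagnoses, notes = notes,
                   intercept = intercept, config = config),
              class = "cohort_bundle")
  })
}

.empty_notes <- function() {
  tibble::tibble(note_id = character(0), admission_id = character(0),
                 note_type = character(0), chart_time = character(0),
                 text = character(0))
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat(sprintf("  %d admissions, %d diagnosis rows, %d notes\n",
              nrow(x$truth), nrow(x$diagnoses), nrow(x$notes)))
  cat(sprintf("  outcome prevalence: %.4f%%\n",
              100 * mean(x$truth$od_outcome)))
  invisible(x)
}
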