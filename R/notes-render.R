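#' Default SBDH sentence template bank
#'
#' Per SBDH variable, templated sentences phrased the way ICU notes document
#' these statuses: affirmative present-tense mentions (`positive`), negated
#' mentions (`negated`), and history-of phrasings (`history`). Substance-use
#' variables map `positive`/`history`/`negated` to statuses
#' current/former/none; for the binary social determinants both `positive`
#' and `history` verbalize a "yes" and `negated` a "no". Templates and the
#' default extraction lexicon are co-designed so that every rendered sentence
#' is recoverable by rule-based extraction.
#'
#' @return A named list of lists of character vectors, class
#'   `"template_bank"`.
#' @export
default_template_bank <- function() {
  structure(list(
    housing_insecurity = list(
      positive = c(
        "The patient is currently homeless.",
        "He has been staying at a local shelter.",
        "Homeless, living out of her car.",
        "Patient reports ongoing housing insecurity."),
      negated = c(
        "She is not homeless and rents her own apartment.",
        "Denies any housing insecurity.",
        "No housing insecurity; he owns his home."),
      history = c(
        "He has a history of homelessness in his twenties.",
        "H/o housing insecurity after an eviction.")),
    unemployment = list(
      positive = c(
        "The patient is currently unemployed.",
        "She has been unemployed since the factory closed.",
        "Unemployed at this time."),
      negated = c(
        "He is not unemployed and works full time as an electrician.",
        "Denies unemployment; currently working two jobs.",
        "No unemployment issues, employed as a teacher."),
      history = c(
        "History of unemployment following the plant closure.",
        "H/o long-term unemployment.")),
    social_isolation = list(
      positive = c(
        "Lives alone in [**Location**] with little support.",
        "The patient lives alone and rarely sees family.",
        "He is socially isolated with minimal community engagement."),
      negated = c(
        "She is not socially isolated; her daughter visits daily.",
        "Denies social isolation.",
        "No social isolation; married and living with spouse."),
      history = c(
        "History of social isolation after retirement.",
        "H/o social isolation while living abroad.")),
    alcohol_use = list(
      positive = c(
        "He drinks two beers nightly.",
        "She has two glasses of wine per night.",
        "Patient reports daily alcohol use.",
        "Drinks a pint of vodka most days."),
      negated = c(
        "She denies any alcohol use.",
        "He does not drink alcohol.",
        "No alcohol use."),
      history = c(
        "He has a history of alcohol abuse.",
        "H/o heavy alcohol use, sober since 2005.",
        "Former drinker, quit several years ago.")),
    smoking = list(
      positive = c(
        "He smokes one pack of cigarettes per day.",
        "She is a current smoker.",
        "Patient smokes half a pack daily."),
      negated = c(
        "She is a nonsmoker.",
        "He denies any tobacco use.",
        "Does not smoke cigarettes.",
        "No smoking history."),
      history = c(
        "The patient has a past history of smoking.",
        "Quit smoking ten years ago.",
        "Former smoker of 30 pack years.")),
    illicit_drug_use = list(
      positive = c(
        "Occasional marijuana use.",
        "Patient reports current cocaine use.",
        "Uses heroin intravenously several times a week."),
      negated = c(
        "Denies cocaine, heroin, or marijuana use.",
        "Does not use recreational drugs.",
        "No illicit drug use."),
      history = c(
        "Has a h/o of cocaine and marijuana abuse.",
        "History of heroin use, now in recovery.",
        "Past use of illicit drugs."))
  ), class = "template_bank")
}

.validate_template_bank <- function(templates) {
  for (v in .sbdh_vars) {
    tb <- templates[[v]]
    if (is.null(tb)) {
      abort(sprintf("template bank is missing variable `%s`.", v),
            class = "sbdhrisk_config_error")
    }
    if (length(tb$positive) < 3 || length(tb$negated) < 3 ||
        length(tb$history) < 2) {
      abort(sprintf(paste0("template bank for `%s` needs >=3 positive, >=3 ",
                           "negated and >=2 history templates."), v),
            class = "sbdhrisk_config_error")
    }
  }
  invisible(templates)
}

.clinical_filler <- c(
  "Hypertension.", "Hyperlipidemia.", "Type 2 diabetes mellitus.",
  "GERD.", "Osteoarthritis.", "Chronic low back pain.")

.generic_filler <- c(
  "Patient admitted for further management.",
  "Vital signs stable on arrival.",
  "Plan discussed with the primary team.",
  "Tolerating a regular diet.",
  "Ambulating with minimal assistance.")

# one sentence per (row, variable); NA where status is unknown or suppressed
.sbdh_sentence_matrix <- function(rows, vars, templates, suppress) {
  n <- nrow(rows)
  m <- matrix(NA_character_, nrow = n, ncol = length(vars),
              dimnames = list(NULL, vars))
  for (v in vars) {
    if (v %in% suppress) next
    status <- rows[[v]]
    pools <- if (.is_substance_var(v)) {
      list(current = templates[[v]]$positive,
           former = templates[[v]]$history,
           none = templates[[v]]$negated)
    } else {
      list(yes = c(templates[[v]]$positive, templates[[v]]$history),
           no = templates[[v]]$negated)
    }
    for (s in names(pools)) {
      idx <- which(status == s)
      if (length(idx)) {
        m[idx, v] <- sample(pools[[s]], length(idx), replace = TRUE)
      }
    }
  }
  m
}

.join_sentences <- function(m) {
  m[is.na(m)] <- ""
  joined <- do.call(paste, c(as.data.frame(m, stringsAsFactors = FALSE),
                             list(sep = " ")))
  stringr::str_squish(joined)
}

.render_note_text <- function(rows, type, templates, suppress) {
  n <- nrow(rows)
  filler <- function() sample(.generic_filler, n, replace = TRUE)
  cfiller <- function() sample(.clinical_filler, n, replace = TRUE)
  if (type == "discharge_summary") {
    sbdh <- .join_sentences(
      .sbdh_sentence_matrix(rows, .sbdh_vars, templates, suppress))
    paste0(
      "Admission Date: ", rows$admit_time,
      "  Discharge Date: ", rows$discharge_time, "\n\n",
      "Chief Complaint:\n", filler(), "\n\n",
      "History of Present Illness:\n", filler(), "\n\n",
      "Past Medical History:\n", cfiller(), " ", cfiller(), "\n\n",
      "Social History:\n", sbdh, "\n\n",
      "Medications:\n", filler(), "\n\n",
      "Hospital Course:\n", filler(), "\n")
  } else if (type == "social_work") {
    social <- .join_sentences(
      .sbdh_sentence_matrix(rows, .sbdh_social_vars, templates, suppress))
    substance <- .join_sentences(
      .sbdh_sentence_matrix(rows, .sbdh_substance_vars, templates, suppress))
    paste0(
      "Social Work Note\n\n",
      "Patient/Family Assessment:\n", social, "\n\n",
      "Past Medical History:\n", cfiller(), "\n\n",
      "Past Addictions History:\n", substance, "\n\n",
      "Plan:\n", filler(), "\n")
  } else if (type == "rehab_services") {
    sbdh <- .join_sentences(
      .sbdh_sentence_matrix(rows, .sbdh_vars, templates, suppress))
    paste0(
      "Rehabilitation Services Note\n\n",
      "Treatment:\n", filler(), "\n\n",
      "Sexual and Social History:\n", sbdh, "\n\n",
      "Goals:\n", filler(), "\n")
  } else {
    abort(sprintf("unknown note type `%s`.", type),
          class = "sbdhrisk_config_error")
  }
}

#' Render templated clinical notes from ground-truth SBDH statuses
#'
#' Produces discharge summaries, social work notes and rehabilitation service
#' notes whose SBDH-relevant sections verbalize every documented
#' (non-"unknown") truth status with a sentence drawn from the template bank;
#' "unknown" statuses produce no mention. A fraction of available note types
#' receives a second, strictly later note so the last-note-per-type rule is
#' exercised.
#'
#' @param truth Truth tibble as produced by [generate_cohort()] (needs the six
#'   SBDH columns, `admission_id`, `admit_time`, `discharge_time`).
#' @param templates Template bank; see [default_template_bank()].
#' @param availability Named probability per note type that an admission has
#'   that note.
#' @param duplicate_rate Probability an available note type gets a second
#'   note.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state (as
#'   done inside [generate_cohort()]).
#' @param suppress Character vector of SBDH variables never verbalized
#'   (creates NLP-silent admissions for merge-precedence experiments).
#' @return Tibble of notes: `note_id`, `admission_id`, `note_type`,
#'   `chart_time` (ISO-8601), `text`.
#' @export
render_notes <- function(truth, templates = default_template_bank(),
                         availability = c(discharge_summary = 0.95,
                                          social_work = 0.30,
                                          rehab_services = 0.10),
                         duplicate_rate = 0.15, seed = NULL,
                         suppress = NULL) {
  .validate_template_bank(templates)
  run <- function() {
    n <- nrow(truth)
    if (n == 0) return(.empty_notes())
    admit_secs <- as.numeric(as.POSIXct(truth$admit_time,
                                        format = "%Y-%m-%dT%H:%M:%S",
                                        tz = "UTC"))
    disch_secs <- as.numeric(as.POSIXct(truth$discharge_time,
                                        format = "%Y-%m-%dT%H:%M:%S",
                                        tz = "UTC"))
    out <- list()
    for (type in .note_types) {
      has <- runif(n) < availability[[type]]
      dup <- has & (runif(n) < duplicate_rate)
      idx <- c(which(has), which(dup))
      copy <- c(rep(1L, sum(has)), rep(2L, sum(dup)))
      if (!length(idx)) next
      rows <- truth[idx, ]
      # the second copy is always strictly later within the stay
      frac <- ifelse(copy == 1L, runif(length(idx), 0.10, 0.60),
                     runif(length(idx), 0.61, 0.95))
      out[[type]] <- tibble::tibble(
        note_id = sprintf("N-%s-%s-%d", rows$admission_id,
                          substr(type, 1, 2), copy),
        admission_id = rows$admission_id,
        note_type = type,
        chart_time = .iso_time(
          admit_secs[idx] + frac * (disch_secs[idx] - admit_secs[idx]) -
            as.numeric(as.POSIXct("2001-01-01", tz = "UTC"))),
        text = .render_note_text(rows, type, templates, suppress))
    }
    if (!length(out)) return(.empty_notes())
    dplyr::arrange(dplyr::bind_rows(out), .data$admission_id,
                   .data$note_type, .data$note_id)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
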