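#' Apply the cohort inclusion criteria
#'
#' Retains admissions aged at least 18 years at admission that have at least
#' one note among the three SBDH-relevant types. Exclusions are accounted in
#' a fixed order — age first, then note availability — so each admission is
#' counted exactly once and the report satisfies
#' `n_input - n_excluded_age - n_excluded_no_note = n_final`.
#'
#' @param admissions Admissions tibble with `admission_id` and `age_years`.
#' @param notes Notes tibble with `admission_id` and `note_type`.
#' @return List with the filtered `admissions` and a `report` of class
#'   `"cohort_filter_report"` (`n_input`, `n_excluded_age`,
#'   `n_excluded_no_note`, `n_final`).
#' @export
apply_inclusion_criteria <- function(admissions, notes) {
  if (anyNA(admissions$age_years)) {
    abort("`age_years` must be present on every admission.",
          class = "sbdhrisk_data_error")
  }
  n_input <- nrow(admissions)
  adult <- admissions$age_years >= 18
  noted_ids <- unique(notes$admission_id[notes$note_type %in% .note_types])
  has_note <- admissions$admission_id %in% noted_ids
  keep <- adult & has_note
  report <- structure(list(
    n_input = n_input,
    n_excluded_age = sum(!adult),
    n_excluded_no_note = sum(adult & !has_note),
    n_final = sum(keep)
  ), class = "cohort_filter_report")
  list(admissions = admissions[keep, , drop = FALSE], report = report)
}

#' @export
print.cohort_filter_report <- function(x, ...) {
  cat("<cohort_filter_report>\n")
  cat(sprintf("  input admissions:        %d\n", x$n_input))
  cat(sprintf("  excluded, age < 18:      %d\n", x$n_excluded_age))
  cat(sprintf("  excluded, no note:       %d\n", x$n_excluded_no_note))
  cat(sprintf("  final cohort:            %d\n", x$n_final))
  invisible(x)
}

.merge_one <- function(nlp_status, nlp_prov, structured_status) {
  if (identical(structured_status, "yes")) {
    if (identical(nlp_status, "yes")) {
      # idempotent: a value already attributed to the structured source (or
      # to both) keeps its provenance on re-merge
      prov <- if (nlp_prov %in% c("structured", "merged")) nlp_prov else
        "merged"
      list(status = "yes", provenance = prov)
    } else {
      # structured "yes" overrides an NLP "no" or "unknown"
      list(status = "yes", provenance = "structured")
    }
  } else {
    list(status = nlp_status, provenance = nlp_prov)
  }
}

#' Merge NLP-derived and structured SBDH for one admission
#'
#' For the three social determinants, a structured (ICD-9 coded) "yes" takes
#' precedence over an NLP "no" or "unknown"; otherwise the NLP value stands.
#' Substance-use variables have no structured counterpart and come from NLP
#' alone. The result is "unknown" only when both sources are silent.
#' Provenance records which source(s) produced each value (`nlp`,
#' `structured`, `merged`, or `absent` for unknown). The operation is
#' idempotent and monotone toward positive findings.
#'
#' @param nlp_profile Tibble (`variable`, `status`, `provenance`) from
#'   [aggregate_admission()].
#' @param structured One-row tibble from [map_admission()] (uses the three
#'   structured SBDH columns).
#' @return Merged profile tibble in the same shape as `nlp_profile`.
#' @export
merge_sbdh <- function(nlp_profile, structured) {
  out <- nlp_profile
  for (v in .sbdh_social_vars) {
    i <- which(out$variable == v)
    m <- .merge_one(out$status[i], out$provenance[i], structured[[v]][[1]])
    out$status[i] <- m$status
    out$provenance[i] <- m$provenance
  }
  out
}

#' Merge NLP and structured SBDH across the cohort
#'
#' @param profiles Long tibble of NLP profiles (`admission_id`, `variable`,
#'   `status`, `provenance`).
#' @param structured Tibble from [map_cohort()].
#' @return Long tibble of merged profiles.
#' @export
merge_sbdh_cohort <- function(profiles, structured) {
  struct_long <- structured |>
    dplyr::select(dplyr::all_of(c("admission_id", .sbdh_social_vars))) |>
    tidyr::pivot_longer(dplyr::all_of(.sbdh_social_vars),
                        names_to = "variable",
                        values_to = "structured_status")
  out <- profiles |>
    dplyr::left_join(struct_long, by = c("admission_id", "variable"))
  override <- !is.na(out$structured_status) &
    out$structured_status == "yes" & out$status != "yes"
  both <- !is.na(out$structured_status) &
    out$structured_status == "yes" & out$status == "yes"
  out$status[override] <- "yes"
  out$provenance[override] <- "structured"
  out$provenance[both] <- ifelse(
    out$provenance[both] %in% c("structured", "merged"),
    out$provenance[both], "merged")
  out$structured_status <- NULL
  out
}

#' Assemble the admission-level analysis table
#'
#' One row per included admission with the outcome, treatment-coded
#' demographic factors (reference levels: age 18-39, male, White, married,
#' private insurance), the 8 clinical flags, and the six merged SBDH
#' variables with `"unknown"` retained as an explicitly modeled level
#' (reference levels "no"/"none").
#'
#' @param admissions Filtered admissions tibble (demographics + insurance).
#' @param truth_demographics Tibble with `admission_id`, `age_group`,
#'   `gender`, `race`, `marital_status` — usually the admissions table itself
#'   if it carries `age_group`, else derived from `age_years`.
#' @param structured Tibble from [map_cohort()] (clinical flags + outcome).
#' @param merged_profiles Long tibble of merged SBDH profiles.
#' @return Tibble of class `"analysis_table"`, one row per admission.
#' @export
build_analysis_table <- function(admissions, structured, merged_profiles,
                                 truth_demographics = NULL) {
  adm <- admissions
  if (!"age_group" %in% names(adm)) {
    adm$age_group <- dplyr::case_when(
      adm$age_years <= 39 ~ "18-39",
      adm$age_years <= 64 ~ "40-64",
      TRUE ~ ">64")
  }
  if (!is.null(truth_demographics)) {
    adm <- adm |>
      dplyr::select(-dplyr::any_of(c("age_group", "gender", "race",
                                     "marital_status"))) |>
      dplyr::left_join(truth_demographics, by = "admission_id")
  }
  wide_sbdh <- merged_profiles |>
    dplyr::select(dplyr::all_of(c("admission_id", "variable", "status"))) |>
    tidyr::pivot_wider(names_from = "variable", values_from = "status")
  out <- adm |>
    dplyr::select(dplyr::all_of(c("admission_id", "age_group", "gender",
                                  "race", "marital_status", "insurance"))) |>
    dplyr::left_join(structured |>
                       dplyr::select(dplyr::all_of(c("admission_id",
                                                     .clinical_vars,
                                                     "nonfatal_od"))),
                     by = "admission_id") |>
    dplyr::left_join(wide_sbdh, by = "admission_id") |>
    dplyr::rename(outcome = "nonfatal_od")
  # validate level sets and fix treatment coding
  level_sets <- c(.demographic_levels, .sbdh_levels)
  for (v in names(level_sets)) {
    bad <- is.na(out[[v]]) | !out[[v]] %in% level_sets[[v]]
    if (any(bad)) {
      abort(sprintf(
        "admission %s has value `%s` outside the declared levels of `%s`.",
        out$admission_id[which(bad)[1]], out[[v]][which(bad)[1]], v),
        class = "sbdhrisk_data_error")
    }
    out[[v]] <- factor(out[[v]], levels = level_sets[[v]])
  }
  for (v in .clinical_vars) {
    if (anyNA(out[[v]])) {
      abort(sprintf("admission %s is missing clinical flag `%s`.",
                    out$admission_id[which(is.na(out[[v]]))[1]], v),
            class = "sbdhrisk_data_error")
    }
  }
  class(out) <- c("analysis_table", class(out))
  out
}

#' Run the full extraction-and-integration pipeline on cohort files
#'
#' Convenience wrapper: inclusion criteria, NLP extraction from notes,
#' ICD-9 structured mapping, precedence merge, and analysis-table assembly.
#'
#' @param admissions,diagnoses,notes Cohort input tibbles (see
#'   [read_cohort()]).
#' @param rules,lexicon,code_map Pipeline configuration objects.
#' @param labeler Optional labeler override.
#' @return List with `analysis_table`, `filter_report`, `profiles` (merged,
#'   long), `structured`, and `nlp_profiles`.
#' @export
integrate_cohort <- function(admissions, diagnoses, notes,
                             rules = default_section_rules(),
                             lexicon = default_lexicon(),
                             code_map = default_code_map(),
                             labeler = NULL) {
  filt <- apply_inclusion_criteria(admissions, notes)
  kept <- filt$admissions
  kept_notes <- notes[notes$admission_id %in% kept$admission_id, ,
                      drop = FALSE]
  nlp <- extract_sbdh_profiles(kept_notes, rules, lexicon, labeler,
                               admission_ids = kept$admission_id)
  structured <- map_cohort(
    diagnoses[diagnoses$admission_id %in% kept$admission_id, , drop = FALSE],
    kept, code_map)
  merged <- merge_sbdh_cohort(nlp, structured)
  table <- build_analysis_table(kept, structured, merged)
  list(analysis_table = table, filter_report = filt$report,
       profiles = merged, structured = structured, nlp_profiles = nlp)
}
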