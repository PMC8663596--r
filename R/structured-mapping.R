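.code_map_groups <- list(
  clinical = .clinical_vars,
  structured_sbdh = .sbdh_social_vars,
  outcome = "nonfatal_od"
)

# ICD-9 codes come dotted ("305.1") or bare ("3051") depending on the source;
# comparison always happens on the bare uppercase form
.normalize_code <- function(x) {
  toupper(gsub(".", "", trimws(x), fixed = TRUE))
}

#' Load an ICD-9 code map from a YAML config file
#'
#' The map names, for each analysis variable, the set of ICD-9 code patterns
#' that raises it: exact codes (`"V600"`, `"305.1"`) or prefix patterns
#' (`"304*"`). Three groups are required — `clinical` (the 8 comorbidity
#' flags), `structured_sbdh` (housing insecurity, unemployment, social
#' isolation) and `outcome` (`nonfatal_od`). The package ships an editable
#' default at `system.file("extdata", "code_map.yaml", package = "sbdhrisk")`;
#' it is a plausible placeholder, meant to be replaced with a validated code
#' list for real analyses.
#'
#' @param path Path to the YAML file; defaults to the shipped map.
#' @return A validated list of class `"code_map"` (patterns normalized to
#'   bare uppercase form).
#' @export
load_code_map <- function(path = system.file("extdata", "code_map.yaml",
                                             package = "sbdhrisk")) {
  raw <- yaml::read_yaml(path)
  map <- list()
  for (group in names(.code_map_groups)) {
    if (is.null(raw[[group]])) {
      abort(sprintf("code map is missing the `%s` group (%s).", group, path),
            class = "sbdhrisk_config_error")
    }
    for (v in .code_map_groups[[group]]) {
      pats <- raw[[group]][[v]]
      if (is.null(pats)) {
        abort(sprintf("code map is missing variable `%s` in group `%s` (%s).",
                      v, group, path),
              class = "sbdhrisk_config_error")
      }
      pats <- as.character(pats)
      bad <- !grepl("^[0-9EVev][0-9.]*\\*?$", pats) & nzchar(pats)
      if (any(bad)) {
        abort(sprintf("code map variable `%s` has invalid pattern(s): %s.",
                      v, paste(pats[bad], collapse = ", ")),
              class = "sbdhrisk_config_error")
      }
      map[[v]] <- .normalize_code(pats[nzchar(pats)])
    }
  }
  structure(map, class = "code_map")
}

#' Default (shipped) ICD-9 code map
#' @return A `"code_map"`.
#' @export
default_code_map <- function() load_code_map()

#' Do any of the codes match a pattern set?
#'
#' Patterns ending in `*` match any code with that prefix; other patterns
#' match exactly. Codes and patterns are compared after stripping periods and
#' uppercasing.
#'
#' @param codes Character vector of ICD-9 codes.
#' @param patterns Character vector of normalized patterns.
#' @return Logical scalar.
#' @export
code_matches <- function(codes, patterns) {
  codes <- .normalize_code(codes)
  for (p in patterns) {
    if (endsWith(p, "*")) {
      if (any(startsWith(codes, substr(p, 1L, nchar(p) - 1L)))) return(TRUE)
    } else if (any(codes == p)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Map one admission's diagnosis codes to structured flags
#'
#' A clinical flag (or the nonfatal-overdose outcome) is `TRUE` iff at least
#' one diagnosis code matches its set. Structured SBDH variables can only
#' assert presence: they yield `"yes"` or `"absent"`, never `"no"`, because
#' the absence of a diagnosis code is not evidence of absence. Insurance is
#' copied from the admissions record.
#'
#' @param codes Character vector of the admission's ICD-9 codes.
#' @param admission A list or one-row data frame with at least `insurance`.
#' @param code_map A `"code_map"`.
#' @return One-row tibble with the 8 clinical flags (logical), 3 structured
#'   SBDH columns (`"yes"`/`"absent"`), `nonfatal_od` (logical) and
#'   `insurance`.
#' @export
map_admission <- function(codes, admission, code_map = default_code_map()) {
  out <- list()
  for (v in .clinical_vars) out[[v]] <- code_matches(codes, code_map[[v]])
  for (v in .sbdh_social_vars) {
    out[[v]] <- if (code_matches(codes, code_map[[v]])) "yes" else "absent"
  }
  out$nonfatal_od <- code_matches(codes, code_map$nonfatal_od)
  out$insurance <- admission$insurance[[1]]
  tibble::as_tibble(out)
}

#' Map a whole diagnoses table to per-admission structured flags
#'
#' Vectorized equivalent of [map_admission()] across the cohort; admissions
#' with no diagnosis rows get all-`FALSE` flags and all-`"absent"` structured
#' SBDH.
#'
#' @param diagnoses Tibble with `admission_id`, `icd9_code`.
#' @param admissions Tibble with `admission_id`, `insurance`.
#' @param code_map A `"code_map"`.
#' @return Tibble with one row per admission in `admissions`.
#' @export
map_cohort <- function(diagnoses, admissions,
                       code_map = default_code_map()) {
  norm <- .normalize_code(diagnoses$icd9_code)
  match_ids <- function(patterns) {
    hit <- rep(FALSE, length(norm))
    for (p in patterns) {
      if (endsWith(p, "*")) {
        hit <- hit | startsWith(norm, substr(p, 1L, nchar(p) - 1L))
      } else {
        hit <- hit | norm == p
      }
    }
    unique(diagnoses$admission_id[hit])
  }
  out <- tibble::tibble(admission_id = admissions$admission_id,
                        insurance = admissions$insurance)
  for (v in .clinical_vars) {
    out[[v]] <- out$admission_id %in% match_ids(code_map[[v]])
  }
  for (v in .sbdh_social_vars) {
    out[[v]] <- ifelse(out$admission_id %in% match_ids(code_map[[v]]),
                       "yes", "absent")
  }
  out$nonfatal_od <- out$admission_id %in% match_ids(code_map$nonfatal_od)
  out[, c("admission_id", .clinical_vars, .sbdh_social_vars, "nonfatal_od",
          "insurance")]
}
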