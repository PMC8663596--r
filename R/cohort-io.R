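.write_jsonl <- function(df, path) {
  if (nrow(df)) {
    # serialize the frame once as a JSON array of row objects, then emit one
    # object per line (ndjson)
    json <- jsonlite::toJSON(df, dataframe = "rows", auto_unbox = TRUE,
                             digits = NA, na = "null")
    lines <- jsonlite::fromJSON(json, simplifyVector = FALSE)
    lines <- vapply(lines, function(rec) {
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
    }, character(1))
  } else {
    lines <- character(0)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

.read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) return(NULL)
  # each line is one JSON object: parse them as a single array
  df <- jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]"),
                           simplifyVector = TRUE)
  tibble::as_tibble(df)
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes the pipeline input files — `admissions.csv`, `diagnoses.csv`
#' (one row per ICD-9 code, codes kept as strings so leading zeros and E/V
#' prefixes survive) and `notes.jsonl` (one JSON record per note with
#' ISO-8601 chart times) — plus the ground truth as a separate
#' `truth.jsonl` that the analysis pipeline never reads.
#'
#' @param bundle A `"cohort_bundle"` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(admissions = file.path(dir, "admissions.csv"),
             diagnoses = file.path(dir, "diagnoses.csv"),
             notes = file.path(dir, "notes.jsonl"),
             truth = file.path(dir, "truth.jsonl"))
  readr::write_csv(bundle$admissions, paths[["admissions"]], progress = FALSE)
  readr::write_csv(bundle$diagnoses, paths[["diagnoses"]], progress = FALSE)
  .write_jsonl(bundle$notes, paths[["notes"]])
  .write_jsonl(bundle$truth, paths[["truth"]])
  paths
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `admissions.csv`, `diagnoses.csv` and
#'   `notes.jsonl` (and optionally `truth.jsonl`).
#' @return A list with tibbles `admissions`, `diagnoses`, `notes` and, when
#'   present, `truth`.
#' @export
read_cohort <- function(dir) {
  admissions <- readr::read_csv(
    file.path(dir, "admissions.csv"), progress = FALSE,
    col_types = readr::cols(
      age_years = readr::col_integer(),
      .default = readr::col_character()))
  diagnoses <- readr::read_csv(
    file.path(dir, "diagnoses.csv"), progress = FALSE,
    col_types = readr::cols(.default = readr::col_character()))
  notes <- .read_jsonl(file.path(dir, "notes.jsonl")) %||% .empty_notes()
  out <- list(admissions = admissions, diagnoses = diagnoses, notes = notes)
  truth_path <- file.path(dir, "truth.jsonl")
  if (file.exists(truth_path)) {
    out$truth <- .read_jsonl(truth_path)
    if (!is.null(out$truth) && "age_years" %in% names(out$truth)) {
      out$truth$age_years <- as.integer(out$truth$age_years)
    }
  }
  out
}
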