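#' Default section extraction rules per note type
#'
#' The SBDH-relevant target sections are: "Social History" in discharge
#' summaries; "Patient/Family Assessment", "Past Addictions History" and
#' "Past Medical History" in social work notes; and "Sexual and Social
#' History" in rehabilitation service notes. Each note type additionally
#' carries a boundary-header list: any recognized header — target or boundary
#' — terminates the preceding section's body, which prevents unrelated note
#' content from leaking into a social-history section.
#'
#' @return A named list (one entry per note type) of
#'   `list(targets = <named list of header patterns>, boundaries = <character
#'   vector>)`, class `"section_ruleset"`.
#' @export
default_section_rules <- function() {
  structure(list(
    discharge_summary = list(
      targets = list("Social History" = "Social History"),
      boundaries = c("Admission Date", "Discharge Date", "Chief Complaint",
                     "History of Present Illness", "Past Medical History",
                     "Medications", "Discharge Medications", "Allergies",
                     "Family History", "Physical Exam", "Hospital Course",
                     "Brief Hospital Course", "Discharge Disposition",
                     "Discharge Diagnosis")),
    social_work = list(
      targets = list("Patient/Family Assessment" = "Patient/Family Assessment",
                     "Past Addictions History" = "Past Addictions History",
                     "Past Medical History" = "Past Medical History"),
      boundaries = c("Plan", "Disposition", "Follow Up", "Narrative")),
    rehab_services = list(
      targets = list("Sexual and Social History" = "Sexual and Social History"),
      boundaries = c("Treatment", "Goals", "Plan", "Activity",
                     "Past Medical History"))
  ), class = "section_ruleset")
}

#' Load a section ruleset from a YAML config file
#'
#' The file maps each note type to `targets` (mapping canonical section name
#' to one or more literal header patterns) and `boundaries` (a list of
#' boundary header patterns). See
#' `system.file("extdata", "section_rules.yaml", package = "sbdhrisk")` for
#' the documented default.
#'
#' @param path Path to the YAML file.
#' @return A `"section_ruleset"`.
#' @export
load_section_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw, function(entry) {
    list(targets = lapply(entry$targets, function(p) as.character(p)),
         boundaries = as.character(entry$boundaries %||% character(0)))
  })
  validate_section_rules(structure(rules, class = "section_ruleset"))
}

#' Validate a section ruleset
#'
#' Checks that the three note types are covered and that the SBDH-relevant
#' target sections required by the pipeline are present.
#'
#' @param rules A `"section_ruleset"`.
#' @return The validated ruleset.
#' @export
validate_section_rules <- function(rules) {
  required <- list(
    discharge_summary = "Social History",
    social_work = c("Patient/Family Assessment", "Past Addictions History",
                    "Past Medical History"),
    rehab_services = "Sexual and Social History")
  for (type in names(required)) {
    if (is.null(rules[[type]])) {
      abort(sprintf("section rules are missing note type `%s`.", type),
            class = "sbdhrisk_config_error")
    }
    missing <- setdiff(required[[type]], names(rules[[type]]$targets))
    if (length(missing)) {
      abort(sprintf("section rules for `%s` must include target(s): %s.",
                    type, paste(missing, collapse = ", ")),
            class = "sbdhrisk_config_error")
    }
  }
  rules
}

# locate every recognized header in `text`: returns a data frame with the
# match start (1-based), match end (inclusive, including consumed colon and
# trailing newline) and the canonical name (NA for boundary headers)
.locate_headers <- function(text, targets, boundaries) {
  # header must be alone on its line (optional colon); content on the same
  # line is not treated as a header
  header_rx <- function(pats) {
    paste0("(?mi)^[ \\t]*(?:",
           paste(vapply(pats, .regex_escape, character(1)), collapse = "|"),
           ")[ \\t]*:?[ \\t]*(\\r?\\n|$)")
  }
  scan <- function(pats, canonical) {
    m <- gregexpr(header_rx(pats), text, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L,
               canonical = canonical, stringsAsFactors = FALSE)
  }
  hits <- lapply(names(targets), function(nm) scan(targets[[nm]], nm))
  if (length(boundaries)) {
    hits <- c(hits, list(scan(boundaries, NA_character_)))
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      canonical = character(0)))
  }
  df <- do.call(rbind, hits)
  # if two patterns match at the same offset, keep the target (non-NA) and,
  # among equals, the longest match
  df <- df[order(df$start, is.na(df$canonical), -df$end), , drop = FALSE]
  df[!duplicated(df$start), , drop = FALSE]
}

.empty_sections_tbl <- tibble::tibble(
  header = character(0), start_offset = integer(0),
  end_offset = integer(0), body = character(0))

#' Extract SBDH-relevant sections from a clinical note
#'
#' A recognized header is a configured pattern at a line start, matched
#' case-insensitively, with an optional trailing colon. One section is
#' returned per matched target header, in document order; its body runs from
#' the character after the header (the header's trailing newline is consumed)
#' to the start of the next recognized header of any kind, or the end of the
#' note. Notes with no matching header yield an empty result.
#'
#' @param note A list or one-row data frame with `note_type` and `text`.
#' @param rules A `"section_ruleset"`; see [default_section_rules()].
#' @return Tibble with columns `header` (canonical name), `start_offset` and
#'   `end_offset` (0-based, half-open, into the note text) and `body`.
#' @export
extract_sections <- function(note, rules = default_section_rules()) {
  type <- note$note_type[[1]]
  if (!type %in% names(rules)) {
    abort(sprintf("no section rules configured for note type `%s`.", type),
          class = "sbdhrisk_config_error")
  }
  text <- note$text[[1]]
  rs <- rules[[type]]
  hdr <- .locate_headers(text, rs$targets, rs$boundaries)
  if (!nrow(hdr)) return(.empty_sections_tbl)
  n_text <- nchar(text)
  body_start <- hdr$end + 1L
  body_end <- c(hdr$start[-1L] - 1L, n_text)
  keep <- !is.na(hdr$canonical) & body_end >= body_start
  if (!any(keep)) return(.empty_sections_tbl)
  tibble::new_tibble(list(
    header = hdr$canonical[keep],
    start_offset = body_start[keep] - 1L,
    end_offset = body_end[keep],
    body = substring(text, body_start[keep], body_end[keep])),
    nrow = sum(keep))
}

#' Select the representative note per admission and note type
#'
#' For each `(admission_id, note_type)` pair, keeps the note with the
#' greatest `chart_time` (the last note typically subsumes the previous
#' ones); ties on chart time are broken deterministically by the
#' lexicographically greatest `note_id`.
#'
#' @param notes Tibble of notes with `admission_id`, `note_type`,
#'   `chart_time` and `note_id`.
#' @return Tibble with one row per `(admission_id, note_type)`.
#' @export
select_representative_notes <- function(notes) {
  if (anyNA(notes$chart_time)) {
    abort("`chart_time` must be present on every note.",
          class = "sbdhrisk_data_error")
  }
  notes |>
    dplyr::group_by(.data$admission_id, .data$note_type) |>
    dplyr::arrange(dplyr::desc(.data$chart_time), dplyr::desc(.data$note_id),
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$admission_id, .data$note_type)
}
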