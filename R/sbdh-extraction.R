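#' Default extraction lexicon for the six SBDH variables
#'
#' Trigger terms per SBDH category (regular expressions, matched
#' case-insensitively), shared negation cues, shared temporality cues, and a
#' token window bounding how far from a trigger a cue may sit within the same
#' sentence. The lexicon is co-designed with [default_template_bank()] so the
#' rule extractor recovers every templated sentence.
#'
#' @return A list of class `"sbdh_lexicon"`.
#' @export
default_lexicon <- function() {
  structure(list(
    categories = list(
      housing_insecurity = c("homeless", "housing insecurity", "\\bshelter"),
      unemployment = c("unemploy"),
      social_isolation = c("lives alone", "lived alone", "socially isolated",
                           "social isolation"),
      alcohol_use = c("alcohol", "\\bwine\\b", "\\bbeers?\\b", "\\bdrinks\\b",
                      "\\bdrink\\b", "\\bdrinker", "\\bvodka\\b",
                      "\\bsober\\b"),
      smoking = c("smok", "cigarette", "\\btobacco"),
      illicit_drug_use = c("cocaine", "marijuana", "heroin",
                           "recreational drug", "illicit drug",
                           "\\bnarcotics\\b")),
    negation = c("\\bdenies\\b", "\\bdeny\\b", "\\bdenied\\b", "\\bno\\b",
                 "\\bnot\\b", "\\bnon", "\\bnever\\b", "\\bwithout\\b",
                 "does not", "doesn't"),
    temporality = c("history of", "\\bh/o\\b", "\\bhx\\b", "\\bformer\\b",
                    "\\bpast\\b", "\\bquit\\b", "used to", "\\bprior\\b",
                    "sober since", "\\bremote\\b"),
    window = 6L
  ), class = "sbdh_lexicon")
}

#' Load an extraction lexicon from a YAML config file
#'
#' @param path YAML file with keys `categories` (per SBDH variable, a list of
#'   trigger regexes), `negation`, `temporality` and `window`.
#' @return A validated `"sbdh_lexicon"`.
#' @export
load_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  lex <- structure(list(
    categories = lapply(raw$categories, as.character),
    negation = as.character(raw$negation),
    temporality = as.character(raw$temporality),
    window = as.integer(raw$window %||% 6L)
  ), class = "sbdh_lexicon")
  validate_lexicon(lex)
}

#' Validate an extraction lexicon
#' @param lexicon A `"sbdh_lexicon"`.
#' @return The validated lexicon.
#' @export
validate_lexicon <- function(lexicon) {
  missing <- setdiff(.sbdh_vars, names(lexicon$categories))
  if (length(missing)) {
    abort(sprintf("lexicon is missing categories: %s.",
                  paste(missing, collapse = ", ")),
          class = "sbdhrisk_config_error")
  }
  for (v in .sbdh_vars) {
    if (!length(lexicon$categories[[v]])) {
      abort(sprintf("lexicon category `%s` needs at least one trigger.", v),
            class = "sbdhrisk_config_error")
    }
  }
  if (!is.numeric(lexicon$window) || lexicon$window < 1) {
    abort("lexicon `window` must be >= 1.", class = "sbdhrisk_config_error")
  }
  lexicon
}

.empty_ann_tbl <- tibble::tibble(
  category = character(0), status = character(0),
  start = integer(0), end = integer(0),
  evidence = character(0), polarity_cue = character(0),
  temporality_cue = character(0))

.empty_annotations <- function() .empty_ann_tbl

# all matches of an alternation of `pats` in `s` (case-insensitive);
# alternatives are tried left to right, so longer variants belong first
.match_alt <- function(s, pats) {
  rx <- paste0("(?:", paste(pats, collapse = "|"), ")")
  m <- gregexpr(rx, s, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) {
    return(list(start = integer(0), end = integer(0)))
  }
  list(start = as.integer(m),
       end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Annotate a section body with SBDH mentions
#'
#' Deterministic rule-based reference extractor. The body is split into
#' sentences at periods and newlines. Within each sentence, every lexicon
#' trigger match produces one annotation; its status is resolved in a fixed
#' order: a negation cue within `window` tokens of the trigger forces
#' none/no; otherwise a temporality cue within the window forces former (or
#' yes, for the binary social determinants); otherwise the mention is read as
#' current/yes.
#'
#' @param body Section body text.
#' @param lexicon A `"sbdh_lexicon"`; see [default_lexicon()].
#' @return Tibble of annotations: `category`, `status`, `start`/`end`
#'   (0-based half-open character offsets into `body`), `evidence`, and the
#'   matched `polarity_cue` / `temporality_cue` (NA when none applied).
#' @export
annotate_section <- function(body, lexicon = default_lexicon()) {
  if (is.na(body) || !nchar(body)) return(.empty_annotations())
  sent <- gregexpr("[^.\n]+", body, perl = TRUE)[[1]]
  if (sent[1] == -1) return(.empty_annotations())
  s_start <- as.integer(sent)
  toks <- gregexpr("\\S+", body, perl = TRUE)[[1]]
  if (toks[1] == -1) return(.empty_annotations())
  tok_start <- as.integer(toks)
  sent_of <- function(pos) findInterval(pos, s_start)
  tok_of <- function(pos) findInterval(pos, tok_start)
  neg <- .match_alt(body, lexicon$negation)
  tmp <- .match_alt(body, lexicon$temporality)
  neg_tok <- tok_of(neg$start)
  neg_sent <- sent_of(neg$start)
  tmp_tok <- tok_of(tmp$start)
  tmp_sent <- sent_of(tmp$start)
  acc_cat <- character(0)
  acc_status <- character(0)
  acc_start <- integer(0)
  acc_end <- integer(0)
  acc_pol <- character(0)
  acc_tmp <- character(0)
  for (cat in names(lexicon$categories)) {
    trig <- .match_alt(body, lexicon$categories[[cat]])
    n_tr <- length(trig$start)
    if (!n_tr) next
    substance <- .is_substance_var(cat)
    status <- character(n_tr)
    pol_cue <- rep(NA_character_, n_tr)
    tmp_cue <- rep(NA_character_, n_tr)
    for (i in seq_len(n_tr)) {
      t_tok <- tok_of(trig$start[i])
      t_sent <- sent_of(trig$start[i])
      near_neg <- which(neg_sent == t_sent &
                          abs(neg_tok - t_tok) <= lexicon$window)
      if (length(near_neg)) {
        status[i] <- if (substance) "none" else "no"
        pol_cue[i] <- substring(body, neg$start[near_neg[1]],
                                neg$end[near_neg[1]])
        next
      }
      near_tmp <- which(tmp_sent == t_sent &
                          abs(tmp_tok - t_tok) <= lexicon$window)
      if (length(near_tmp)) {
        status[i] <- if (substance) "former" else "yes"
        tmp_cue[i] <- substring(body, tmp$start[near_tmp[1]],
                                tmp$end[near_tmp[1]])
      } else {
        status[i] <- if (substance) "current" else "yes"
      }
    }
    acc_cat <- c(acc_cat, rep(cat, n_tr))
    acc_status <- c(acc_status, status)
    acc_start <- c(acc_start, trig$start - 1L)
    acc_end <- c(acc_end, trig$end)
    acc_pol <- c(acc_pol, pol_cue)
    acc_tmp <- c(acc_tmp, tmp_cue)
  }
  if (!length(acc_cat)) return(.empty_annotations())
  ord <- order(acc_start, acc_cat)
  tibble::new_tibble(list(
    category = acc_cat[ord], status = acc_status[ord],
    start = acc_start[ord], end = acc_end[ord],
    evidence = substring(body, acc_start[ord] + 1L, acc_end[ord]),
    polarity_cue = acc_pol[ord], temporality_cue = acc_tmp[ord]),
    nrow = length(acc_cat))
}

#' Aggregate annotations into an admission-level SBDH profile
#'
#' Statuses observed across all of an admission's representative-note
#' sections are merged per category by severity — current > former > none
#' (and yes > no) — extending the prefer-positive-findings principle used
#' when reconciling NLP and structured sources. Categories with no
#' annotation are coded `"unknown"` with provenance `"absent"`.
#'
#' @param annotations Tibble of annotations (from [annotate_section()] or a
#'   registered labeler), possibly spanning several notes.
#' @return An SBDH profile: tibble with one row per variable and columns
#'   `variable`, `status`, `provenance` (`"nlp"` or `"absent"`).
#' @export
aggregate_admission <- function(annotations) {
  status <- character(length(.sbdh_vars))
  prov <- character(length(.sbdh_vars))
  for (i in seq_along(.sbdh_vars)) {
    v <- .sbdh_vars[i]
    st <- annotations$status[annotations$category == v]
    if (!length(st)) {
      status[i] <- "unknown"
      prov[i] <- "absent"
    } else {
      status[i] <- st[which.max(.status_severity[st])]
      prov[i] <- "nlp"
    }
  }
  tibble::tibble(variable = .sbdh_vars, status = status, provenance = prov)
}

# ---- pluggable labeler interface -------------------------------------------

.labeler_registry <- new.env(parent = emptyenv())

#' Register a custom SBDH labeler backend
#'
#' A labeler is any function taking a section body (character scalar) and
#' returning an annotation tibble honoring the [annotate_section()] contract.
#' This is the substitution seam for a learned model; the pipeline behaves
#' identically regardless of backend. Passing `NULL` restores the default
#' rule-based labeler.
#'
#' @param labeler A function, or `NULL` to reset.
#' @return The previously registered labeler (invisibly).
#' @export
register_labeler <- function(labeler = NULL) {
  if (!is.null(labeler) && !is.function(labeler)) {
    abort("`labeler` must be a function or NULL.",
          class = "sbdhrisk_config_error")
  }
  old <- get0("labeler", envir = .labeler_registry)
  assign("labeler", labeler, envir = .labeler_registry)
  invisible(old)
}

#' Retrieve the active SBDH labeler
#'
#' @param lexicon Lexicon used by the default rule backend when no custom
#'   labeler is registered.
#' @return A function mapping a section body to annotations.
#' @export
get_labeler <- function(lexicon = default_lexicon()) {
  get0("labeler", envir = .labeler_registry) %||%
    function(body) annotate_section(body, lexicon)
}

# run the active labeler and enforce its contract
.apply_labeler <- function(body, labeler) {
  anns <- labeler(body)
  if (nrow(anns)) {
    if (any(anns$start < 0 | anns$end > nchar(body) |
            anns$start >= anns$end)) {
      abort("labeler returned annotation spans outside the section bounds.",
            class = "sbdhrisk_contract_error")
    }
    bad <- !anns$category %in% .sbdh_vars
    if (any(bad)) {
      abort(sprintf("labeler returned unknown categories: %s.",
                    paste(unique(anns$category[bad]), collapse = ", ")),
            class = "sbdhrisk_contract_error")
    }
  }
  anns
}

#' Extract admission-level SBDH profiles from notes
#'
#' Full NLP arm of the pipeline: selects the representative note per
#' (admission, note type), extracts the SBDH-relevant sections, annotates
#' each section body with the active labeler, and aggregates to one profile
#' per admission. Admissions present in `notes` but with no SBDH mention get
#' all-unknown profiles.
#'
#' @param notes Tibble of notes.
#' @param rules Section ruleset.
#' @param lexicon Lexicon for the default rule labeler.
#' @param labeler Optional labeler function overriding the registered one.
#' @param admission_ids Optional character vector of admissions to profile
#'   (defaults to those appearing in `notes`).
#' @return Tibble with columns `admission_id`, `variable`, `status`,
#'   `provenance`.
#' @export
extract_sbdh_profiles <- function(notes, rules = default_section_rules(),
                                  lexicon = default_lexicon(),
                                  labeler = NULL,
                                  admission_ids = NULL) {
  labeler <- labeler %||% get_labeler(lexicon)
  reps <- select_representative_notes(notes)
  ids <- admission_ids %||% sort(unique(notes$admission_id))
  ann_list <- vector("list", nrow(reps))
  rep_ids <- reps$admission_id
  rep_types <- reps$note_type
  rep_texts <- reps$text
  for (r in seq_len(nrow(reps))) {
    sections <- extract_sections(list(note_type = rep_types[r],
                                      text = rep_texts[r]), rules)
    if (!nrow(sections)) next
    anns <- dplyr::bind_rows(lapply(sections$body, .apply_labeler, labeler))
    if (nrow(anns)) {
      anns$admission_id <- rep_ids[r]
      ann_list[[r]] <- anns
    }
  }
  all_anns <- dplyr::bind_rows(ann_list)
  grid <- tibble::tibble(
    admission_id = rep(ids, each = length(.sbdh_vars)),
    variable = rep(.sbdh_vars, length(ids)))
  if (!nrow(all_anns)) {
    grid$status <- "unknown"
    grid$provenance <- "absent"
    return(grid)
  }
  best <- all_anns |>
    dplyr::mutate(severity = .status_severity[.data$status]) |>
    dplyr::group_by(.data$admission_id, variable = .data$category) |>
    dplyr::summarise(status = .data$status[which.max(.data$severity)],
                     .groups = "drop")
  out <- dplyr::left_join(grid, best, by = c("admission_id", "variable"))
  out$provenance <- ifelse(is.na(out$status), "absent", "nlp")
  out$status[is.na(out$status)] <- "unknown"
  out
}
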