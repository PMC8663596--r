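#' Prevalence summary of the analysis table
#'
#' Per-variable level counts and percentages, overall and split by outcome
#' group, mirroring the usual descriptive cohort table. Percentages are
#' reported to two decimals.
#'
#' @param analysis_table An `"analysis_table"`.
#' @return Tibble: `variable`, `level`, `overall_n`, `overall_pct`, `od_n`,
#'   `od_pct`, `no_od_n`, `no_od_pct`.
#' @export
prevalence_table <- function(analysis_table) {
  vars <- c(names(.demographic_levels), .clinical_vars, .sbdh_vars)
  n_all <- nrow(analysis_table)
  n_od <- sum(analysis_table$outcome)
  n_no <- n_all - n_od
  pct <- function(x, n) round(100 * x / max(n, 1L), 2)
  out <- list()
  for (v in vars) {
    if (v %in% .clinical_vars) {
      val <- ifelse(analysis_table[[v]], "yes", "no")
      levels_v <- "yes"   # report the positive level only for binary flags
      val <- factor(val, levels = c("yes", "no"))
    } else {
      val <- analysis_table[[v]]
      levels_v <- levels(val)
    }
    for (l in levels_v) {
      hit <- val == l
      out[[paste(v, l)]] <- tibble::tibble(
        variable = v, level = l,
        overall_n = sum(hit), overall_pct = pct(sum(hit), n_all),
        od_n = sum(hit & analysis_table$outcome),
        od_pct = pct(sum(hit & analysis_table$outcome), n_od),
        no_od_n = sum(hit & !analysis_table$outcome),
        no_od_pct = pct(sum(hit & !analysis_table$outcome), n_no))
    }
  }
  dplyr::bind_rows(out)
}

#' Source breakdown of the known SBDH statuses
#'
#' Among non-"unknown" merged SBDH values, the share identified by the NLP
#' arm (provenance `nlp` or `merged`) versus identified only through
#' structured ICD-9 codes (provenance `structured`). This is the quantity
#' behind the observation that structured data contribute a fraction of a
#' percent of all SBDH information.
#'
#' @param merged_profiles Long merged profile tibble.
#' @return List: `n_known`, `n_structured_only`, `n_nlp`, `structured_pct`,
#'   `nlp_pct`.
#' @export
sbdh_source_breakdown <- function(merged_profiles) {
  known <- merged_profiles[merged_profiles$status != "unknown", , drop = FALSE]
  n_known <- nrow(known)
  n_structured <- sum(known$provenance == "structured")
  n_nlp <- n_known - n_structured
  list(n_known = n_known,
       n_structured_only = n_structured,
       n_nlp = n_nlp,
       structured_pct = if (n_known) round(100 * n_structured / n_known, 2) else NA_real_,
       nlp_pct = if (n_known) round(100 * n_nlp / n_known, 2) else NA_real_)
}

#' Crude and adjusted odds-ratio report
#'
#' For every non-reference level of every modeled variable: the crude odds
#' ratio from the level-vs-reference 2x2 table, and the adjusted odds ratio
#' from the multivariable logistic fit, both with Wald 95% CIs. Levels with
#' a zero cell get `NA` crude estimates together with a diagnostic naming
#' the level.
#'
#' @param analysis_table An `"analysis_table"`.
#' @param z Normal quantile for the CIs.
#' @param terms Optional character vector restricting the modeled variables
#'   (useful at small n, where a rare outcome cannot support the full model).
#' @param ... Passed to [fit_logistic()].
#' @return List of class `"or_report"`: `estimates` (tibble), `fit`,
#'   `hl` (Hosmer-Lemeshow on the fitted model), `vif` (named vector),
#'   `zero_cells` (character vector of inestimable levels).
#' @export
or_report <- function(analysis_table, z = 1.959964, terms = NULL, ...) {
  des <- build_design(analysis_table, terms)
  # levels with no observations are inestimable: drop their columns from the
  # fit and surface them as zero-cell diagnostics instead
  constant <- apply(des, 2, function(col) min(col) == max(col))
  fit <- fit_logistic(des[, !constant, drop = FALSE],
                      analysis_table$outcome, ...)
  adj <- adjusted_or(fit, z)
  if (any(constant)) {
    adj <- dplyr::bind_rows(adj, tibble::tibble(
      term = colnames(des)[constant], or = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, kind = "adjusted"))
    adj <- adj[match(colnames(des), adj$term), , drop = FALSE]
  }
  level_sets <- c(.demographic_levels, .sbdh_levels)
  zero_cells <- character(0)
  crude <- list()
  for (term in adj$term) {
    if (grepl(":", term, fixed = TRUE)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      v <- parts[1]
      lvl <- parts[2]
      ref <- level_sets[[v]][1]
      exposed <- analysis_table[[v]] == lvl
      unexposed <- analysis_table[[v]] == ref
    } else {
      exposed <- analysis_table[[term]]
      unexposed <- !exposed
    }
    y <- analysis_table$outcome
    est <- tryCatch(
      crude_or(sum(exposed & y), sum(exposed & !y),
               sum(unexposed & y), sum(unexposed & !y), z = z, term = term),
      sbdhrisk_zero_cell_error = function(e) {
        zero_cells <<- c(zero_cells, term)
        tibble::tibble(term = term, or = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, kind = "crude")
      })
    crude[[term]] <- est
  }
  crude <- dplyr::bind_rows(crude)
  estimates <- dplyr::left_join(
    crude |> dplyr::rename(crude_or = "or", crude_ci_low = "ci_low",
                           crude_ci_high = "ci_high") |>
      dplyr::select(-"kind"),
    adj |> dplyr::rename(aor = "or", aor_ci_low = "ci_low",
                         aor_ci_high = "ci_high") |>
      dplyr::select(-"kind"),
    by = "term")
  hl <- hosmer_lemeshow(fit$fitted, analysis_table$outcome)
  v <- vif(des[, !constant, drop = FALSE])
  structure(list(estimates = estimates, fit = fit, hl = hl, vif = v,
                 zero_cells = zero_cells),
            class = "or_report")
}

#' @export
print.or_report <- function(x, ...) {
  cat("<or_report>\n")
  print(dplyr::mutate(x$estimates,
                      dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2))),
        n = Inf)
  print(x$hl)
  if (length(x$zero_cells)) {
    cat("zero-cell levels (crude OR inestimable):",
        paste(x$zero_cells, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- command-style entry points --------------------------------------------

.write_manifest <- function(dir, step, config_hash, seed, files) {
  sums <- tools::md5sum(files)
  names(sums) <- names(files) %||% basename(files)
  manifest <- list(step = step, config_hash = config_hash, seed = seed,
                   checksums = as.list(sums))
  jsonlite::write_json(manifest, file.path(dir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a cohort and write it to disk
#'
#' Wraps [generate_cohort()] + [write_cohort()] and records a manifest with
#' the configuration hash, seed and file checksums, so a run is fully
#' reproducible from its manifest.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param ... Passed to [generate_cohort()].
#' @return The file paths, invisibly.
#' @export
cmd_simulate <- function(config, out_dir, ...) {
  bundle <- generate_cohort(config, ...)
  paths <- write_cohort(bundle, out_dir)
  .write_manifest(out_dir, "simulate", rlang::hash(unclass(config)),
                  config$seed, paths)
  invisible(paths)
}

#' Extract SBDH profiles and prevalence summaries from cohort files
#'
#' Reads the cohort files in `dir`, applies the inclusion criteria, runs NLP
#' extraction and structured mapping, merges with structured-"yes"
#' precedence, and writes `sbdh_profiles.csv`, `prevalence_summary.csv`,
#' `source_breakdown.json` and `filter_report.json`.
#'
#' @param dir Directory with `admissions.csv`, `diagnoses.csv`,
#'   `notes.jsonl`.
#' @param out_dir Output directory (defaults to `dir`).
#' @param rules,lexicon,code_map Pipeline configuration.
#' @return The integration result (as from [integrate_cohort()]), invisibly.
#' @export
cmd_extract <- function(dir, out_dir = dir,
                        rules = default_section_rules(),
                        lexicon = default_lexicon(),
                        code_map = default_code_map()) {
  cohort <- read_cohort(dir)
  res <- integrate_cohort(cohort$admissions, cohort$diagnoses, cohort$notes,
                          rules, lexicon, code_map)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$profiles, file.path(out_dir, "sbdh_profiles.csv"),
                   progress = FALSE)
  readr::write_csv(prevalence_table(res$analysis_table),
                   file.path(out_dir, "prevalence_summary.csv"),
                   progress = FALSE)
  jsonlite::write_json(sbdh_source_breakdown(res$profiles),
                       file.path(out_dir, "source_breakdown.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(unclass(res$filter_report),
                       file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Fit the association models and write the odds-ratio report
#'
#' Runs integration plus the statistical layer and writes `estimates.csv`
#' (crude and adjusted ORs with 95% CIs) and `diagnostics.json`
#' (log-likelihood, iterations, Hosmer-Lemeshow result, VIFs, zero-cell
#' levels).
#'
#' @inheritParams cmd_extract
#' @param ... Passed to [or_report()] (e.g. `terms`).
#' @return The `"or_report"`, invisibly.
#' @export
cmd_analyze <- function(dir, out_dir = dir,
                        rules = default_section_rules(),
                        lexicon = default_lexicon(),
                        code_map = default_code_map(), ...) {
  cohort <- read_cohort(dir)
  res <- integrate_cohort(cohort$admissions, cohort$diagnoses, cohort$notes,
                          rules, lexicon, code_map)
  rep <- or_report(res$analysis_table, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(rep$estimates, file.path(out_dir, "estimates.csv"),
                   progress = FALSE)
  diagnostics <- list(
    log_likelihood = rep$fit$log_likelihood,
    n_iterations = rep$fit$n_iterations,
    converged = rep$fit$converged,
    hosmer_lemeshow = list(chi2 = rep$hl$chi2, df = rep$hl$df,
                           p_value = rep$hl$p_value),
    vif = as.list(rep$vif),
    zero_cells = rep$zero_cells,
    filter_report = unclass(res$filter_report))
  jsonlite::write_json(diagnostics, file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rep)
}
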