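# shared test fixtures, all built in code

# a configuration with no covariate effects (every coefficient zero)
null_config <- function(n = 1000, intercept = qlogis(0.5), seed = 1) {
  cohort_config(n_admissions = n,
                true_log_odds = setNames(numeric(0), character(0)),
                intercept = intercept, seed = seed)
}

# wide per-admission SBDH status table from a long profile tibble
profiles_wide <- function(profiles) {
  tidyr::pivot_wider(profiles[, c("admission_id", "variable", "status")],
                     names_from = "variable", values_from = "status")
}

sbdh_vars <- c("housing_insecurity", "unemployment", "social_isolation",
               "alcohol_use", "smoking", "illicit_drug_use")

# fraction of documented (non-unknown) truth statuses recovered by the
# pipeline's merged profiles, over the included admissions
recovery_rate <- function(truth, profiles, admission_ids) {
  tt <- truth[truth$admission_id %in% admission_ids, ]
  pw <- profiles_wide(profiles)
  pw <- pw[match(tt$admission_id, pw$admission_id), ]
  total <- 0L
  hits <- 0L
  for (v in sbdh_vars) {
    doc <- tt[[v]] != "unknown"
    total <- total + sum(doc)
    hits <- hits + sum(doc & pw[[v]] == tt[[v]])
  }
  c(hits = hits, total = total)
}

# a complete toy ICD-9 code map written to a temp YAML file
write_toy_code_map <- function(path = tempfile(fileext = ".yaml"),
                               drop = NULL) {
  map <- list(
    clinical = list(
      drug_use_disorder = list("304*"), bipolar_disorder = list("2964"),
      tobacco_use_disorder = list("305.1"),
      major_depressive_disorder = list("311"),
      alcohol_use_disorder = list("303*"), cirrhosis = list("5712"),
      copd = list("496"), renal_insufficiency = list("585*")),
    structured_sbdh = list(
      housing_insecurity = list("V600"), unemployment = list("V620"),
      social_isolation = list("V603")),
    outcome = list(nonfatal_od = list("96500", "E8500")))
  if (!is.null(drop)) {
    for (grp in names(map)) map[[grp]][[drop]] <- NULL
  }
  yaml::write_yaml(map, path)
  path
}
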