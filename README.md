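# sbdhrisk

Risk-factor analysis of nonfatal opioid overdose (OD) in ICU admissions
when the key exposures — social and behavioral determinants of health
(SBDH) — live in free-text notes rather than structured fields.

The package is for epidemiologists and clinical-informatics researchers
working with MIMIC-style ICU data. It implements the full chain:

1. **Synthetic cohort generation** — admissions, ICD-9 diagnoses and
   templated clinical notes with known ground-truth SBDH statuses and an
   outcome drawn from a configurable logistic model (so the pipeline is
   testable end to end without credentialed data access);
2. **Note sectioning** — rule-based extraction of the SBDH-relevant
   sections ("Social History", "Patient/Family Assessment", "Past
   Addictions History", "Past Medical History", "Sexual and Social
   History") and last-note-per-type representative selection;
3. **SBDH extraction** — a deterministic lexicon + negation + temporality
   reference extractor for six variables (housing insecurity,
   unemployment, social isolation, alcohol use, smoking, illicit drug
   use), behind a pluggable labeler interface so a trained model can be
   substituted;
4. **Structured mapping** — ICD-9 code sets (configurable YAML) for 8
   clinical comorbidity flags, structured SBDH, and the nonfatal-OD
   outcome;
5. **Integration** — age/note inclusion criteria, NLP/structured merge
   with structured-"yes" precedence, and an analysis table with "unknown"
   as a modeled level;
6. **Association analysis** — the statistical core, authored in-package:
   crude odds ratios with Wald CIs, multivariable logistic regression by
   IRLS, sequential forward selection (AIC or likelihood-ratio entry),
   Hosmer–Lemeshow goodness of fit, and variance inflation factors.

## The model

For admission *i* with binary outcome *y<sub>i</sub>* (nonfatal OD) and
covariates *x<sub>i</sub>* (age group, gender, race, marital status,
insurance, 8 clinical flags, 6 SBDH variables, treatment-coded against
the reference levels age 18–39 / male / White / married / private /
no–none):

logit Pr(*y<sub>i</sub>* = 1) = β₀ + *x<sub>i</sub>*ᵀβ

Crude OR for a 2×2 table (a, b, c, d) is *ad/bc* with
CI = exp(log OR ± 1.959964·√(1/a + 1/b + 1/c + 1/d)); adjusted ORs are
exp(β̂) with Wald CIs from the inverse observed information. The
Hosmer–Lemeshow statistic uses 10 deciles of fitted risk (df = 8).

## Worked example

A cohort at the emulated study scale (48,869 admissions, outcome
prevalence calibrated to 0.35%), simulate → extract → analyze:

```r
library(sbdhrisk)
cfg <- cohort_config(n_admissions = 48869, seed = 1)
dir <- tempfile()
cmd_simulate(cfg, dir)         # admissions.csv, diagnoses.csv, notes.jsonl + manifest
res <- cmd_extract(dir)        # SBDH profiles, prevalence table, source shares
print(res$filter_report)
rep <- or_report(res$analysis_table)
rep$estimates
```

which prints (seed 1):

```
<cohort_filter_report>
  input admissions:        48869
  excluded, age < 18:      499
  excluded, no note:       1607
  final cohort:            46763

                     term crude_or crude_ci_low crude_ci_high  aor aor_ci_low aor_ci_high
            age_group:>64     0.15         0.10          0.25 0.15       0.09        0.25
       insurance:Medicaid     1.91         1.12          3.24 1.84       1.08        3.16
        drug_use_disorder     7.98         5.30         12.01 8.36       5.51       12.70
         bipolar_disorder     2.12         0.93          4.81 2.19       0.94        5.06
   housing_insecurity:yes     1.82         0.44          7.41 1.71       0.40        7.22
          smoking:current     1.01         0.62          1.65 1.02       0.62        1.67
 illicit_drug_use:current     2.29         1.23          4.27 2.30       1.22        4.32

Hosmer-Lemeshow: chi2(8) = 15.195, p = 0.055 (10 groups)
```

Reading it: the cohort filter report mirrors the inclusion flow (age ≥ 18
and at least one of the three note types). Each row compares one
covariate level against its reference; `crude_or` comes from the plain
2×2 table and `aor` from the multivariable fit. The generating model for
this cohort used the natural logs of published adjusted odds ratios as
true coefficients (e.g. 8.17 for drug use disorder, 2.26 for Medicaid,
0.16 for age > 64), so the fitted `aor` column recovering 8.36, 1.84 and
0.15 shows the whole chain — note rendering, sectioning, extraction,
merge, table assembly, IRLS — preserving the signal. The
Hosmer–Lemeshow p = 0.055 does not reject calibration at the 5% level.

On a laptop-scale cohort (a few thousand admissions) the 0.35% outcome
cannot support the full 37-term model; restrict it, e.g.
`or_report(res$analysis_table, terms = c("age_group", "drug_use_disorder",
"insurance"))`.

A thin command-line wrapper with `simulate` / `extract` / `analyze`
subcommands is installed at
`system.file("cli", "sbdhrisk.R", package = "sbdhrisk")`.

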