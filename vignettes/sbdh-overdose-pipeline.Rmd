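---
title: "Modeling nonfatal opioid overdose risk from notes and codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nonfatal opioid overdose risk from notes and codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbdhrisk)
```

## The problem

Nonfatal opioid overdose (OD) among intensive-care admissions is rare —
around 0.35% of admissions — and several of its strongest candidate risk
factors are social and behavioral determinants of health (SBDH): housing
insecurity, unemployment, social isolation, and alcohol, tobacco and illicit
drug use. SBDH are almost never coded in structured EHR fields; they live in
free text, mostly in discharge summaries, social work notes and
rehabilitation service notes. `sbdhrisk` implements the full analysis chain
for this setting: extract SBDH from note text, reconcile with the sparse
ICD-9-coded SBDH, map clinical comorbidities and the OD outcome from
diagnosis codes, assemble an admission-level table, and estimate crude and
adjusted odds ratios from a multivariable logistic model. Because the ICU
databases this serves are credentialed-access, the package also ships a
fully synthetic cohort generator with known ground truth, so every stage is
testable end to end without restricted data.

## The statistical model

For admission $i$ with outcome $y_i \in \{0,1\}$ and covariate vector $x_i$,

$$\operatorname{logit} \Pr(y_i = 1) = \beta_0 + x_i^\top \beta,$$

with treatment (reference-level) coding: age 18–39, male, White, married,
private insurance, and SBDH "no"/"none" are the reference levels, and
"unknown" (no documentation anywhere) is kept as an explicitly modeled
level rather than dropped or imputed. Admissions are treated as independent
rows even when one patient contributes several admissions; this matches the
design being emulated and is a known limitation (no clustering adjustment).

* **Crude OR**: for a 2×2 exposure-by-outcome table $(a,b,c,d)$,
  $\widehat{OR} = ad/bc$ with Wald interval
  $\exp(\log \widehat{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$, $z = 1.959964$.
  Zero cells raise an error by default; the Haldane 0.5 correction is
  opt-in (`continuity_correction = TRUE`) because silent corrections bias
  small-cell estimates.
* **Adjusted OR**: $\exp(\hat\beta_j)$ from the multivariable fit with Wald
  intervals $\exp(\hat\beta_j \pm z \cdot se_j)$.
* **Fit**: `fit_logistic()` maximizes the Bernoulli log-likelihood by
  Newton–Raphson (equal to Fisher scoring under the canonical logit link,
  i.e. IRLS), with step halving so the likelihood never decreases.
  Convergence is declared when the relative log-likelihood change falls
  below `tol` (default `1e-8`, 50 iterations maximum); the covariance is
  the inverse observed information at the optimum. The log-likelihood is
  computed in the numerically stable form
  $y\eta - \max(\eta,0) - \log(1+e^{-|\eta|})$.
* **Degenerate inputs**: an all-0 or all-1 outcome errors immediately; a
  coefficient exceeding `separation_bound` (default 15 on the log-odds
  scale, far beyond any plausible clinical OR) aborts with a separation
  error rather than returning a meaningless huge estimate; non-convergence
  raises an error carrying the likelihood trace.
* **Forward selection**: `forward_select()` greedily adds, at each step,
  the candidate variable with the best criterion improvement and stops when
  none improves. The selection criterion is AIC by default; a
  likelihood-ratio entry test at $\alpha = 0.05$ is available
  (`criterion = "lrt"`) because the selection procedure's original
  criterion is not pinned down in the literature this emulates. Ties break
  deterministically by candidate name; a failing inner fit is skipped with
  a warning and recorded.
* **Goodness of fit**: `hosmer_lemeshow()` sorts by fitted probability into
  `groups` (default 10) near-equal deciles of risk — observations tied with
  a boundary value stay in the lower group, so the statistic is invariant
  to the sort's tie order — and sums $(O-E)^2/E$ over groups and both
  outcome classes, with $df = groups - 2$.
* **Collinearity**: `vif()` computes $1/(1-R^2_j)$ from least-squares
  regressions of each design column on the others; perfect collinearity is
  reported as `Inf` rather than an error so screens can report it.

## Note sectioning and SBDH extraction

The sectionizer (`extract_sections()`) treats a header as a configured
literal at a line start, matched case-insensitively, with an optional
trailing colon, alone on its line. A section body runs from the character
after the header to the next recognized header of *any* kind — target or
boundary — or the end of the note. The boundary-header list exists so that
content like a medication list never leaks into a "Social History" section.
The SBDH-relevant targets are "Social History" (discharge summaries);
"Patient/Family Assessment", "Past Addictions History", "Past Medical
History" (social work notes); and "Sexual and Social History"
(rehabilitation service notes). When an admission has several notes of one
type, the note with the latest chart time is the representative (ties break
by lexicographically greatest note id — the source convention is silent on
ties, so the rule just has to be deterministic).

The reference extractor (`annotate_section()`) is a deterministic
lexicon-plus-cues rule system standing in for a learned word-level labeler:
sentences are split at periods and newlines; each trigger match is resolved
in a fixed order — a negation cue within a 6-token window of the trigger in
the same sentence forces none/no; otherwise a temporality cue ("history
of", "h/o", "former", "past", "quit", ...) forces former (or yes for the
binary social determinants); otherwise the mention reads as current/yes.
Negation is checked before temporality so "no smoking history" resolves to
none. Any learned model can be substituted through `register_labeler()`;
the pipeline validates the returned spans and behaves identically
regardless of backend.

Admission-level aggregation merges statuses across a patient's
representative notes by severity (current > former > none; yes > no). The
source convention resolves NLP-vs-ICD conflicts toward positive findings;
we extend the same prefer-positive principle to note-vs-note conflicts,
which the convention leaves open. A category with no mention anywhere is
"unknown". The NLP/structured merge then lets a structured (ICD-9 coded)
"yes" override an NLP "no" or "unknown" for the three social determinants;
substance-use variables have no structured counterpart in scope. The merge
is idempotent and monotone toward positive findings, and provenance
(`nlp`/`structured`/`merged`/`absent`) is kept per value so the
source-share of SBDH information can be reported.

Structured mapping normalizes ICD-9 codes by stripping periods before
comparison (sources disagree on dotted form) and supports exact codes and
`prefix*` patterns. Structured SBDH can only assert presence — yes or
absent, never no — because a missing diagnosis code is not evidence of
absence. The shipped `code_map.yaml` is an editable, plausible default; a
real analysis should replace it with a validated code list, which is why
the map is configuration rather than hard-coded truth and why no test
depends on the default's contents.

## What the synthetic cohort emulates

`cohort_config()` defaults define the study conditions:

* marginal covariate prevalences equal to the overall-cohort proportions of
  the emulated ICU population (e.g. 51.72% aged >64, 3.06% drug use
  disorder, 8.81% Medicaid);
* true coefficients equal to the natural logs of the published adjusted
  odds ratios (37 non-reference terms), with the intercept calibrated so
  the marginal OD prevalence is 0.35%;
* sparse structured SBDH coding (`structured_sbdh_coding_rate = 0.02`);
* per-type note availability (0.95 / 0.30 / 0.10 for discharge summary /
  social work / rehab) plus a 15% chance of a second, later note of an
  available type, to exercise the last-note rule;
* a 1% admixture of under-18 admissions to exercise the age exclusion;
* 12 years' worth of synthetic admission timestamps (the dates carry no
  analytic meaning).

Covariates are sampled independently per admission: the emulated study
reports no joint covariate distribution, so independence is the only
defensible default; an optional `drug_correlation` knob can couple illicit
drug use truth to the drug-use-disorder flag. Admissions are independent
(no within-patient correlation), matching the admission-level analysis
being emulated. No closed form links the intercept to the marginal
prevalence under a mixed categorical covariate model, so
`calibrate_intercept()` root-finds on a 1e6-draw Monte-Carlo estimate of
the prevalence with a fixed internal seed (calibration is deterministic and
cached; its Monte-Carlo standard error on the prevalence scale is about
4e-5).

Notes are rendered from a template bank whose sentences are co-designed
with the default lexicon, so every documented (non-"unknown") truth status
is recoverable by the rule extractor — extraction performance on this
synthetic corpus is 100% by construction, an upper bound. That is the
point of the generator: it validates the *plumbing* (sectioning, cue
resolution, aggregation, merge precedence, model recovery), not extractor
generalization. Real notes have paraphrase variety, typos, headers the
rules don't know, copy-forward contradictions and SBDH outside the target
sections; passing tests here say nothing about recall on real text. A
consequence worth knowing: because every true positive is documented, the
structured source can never be the *only* source in the default cohort, so
the structured share of SBDH information is 0% there (the real-data figure
is a fraction of a percent, driven by coded-but-undocumented positives);
the merge-precedence path is therefore tested by explicitly suppressing the
NLP arm (`suppress =` in `render_notes()`/`generate_cohort()`).

## Numerical and design choices

* Timestamps are ISO-8601 strings end to end; lexicographic order equals
  chronological order, which makes the last-note rule and file round-trips
  exact.
* Character offsets in sections and annotations are 0-based half-open, the
  convention of NLP span formats.
* Exclusion accounting order is age first, then note availability, so each
  excluded admission is counted exactly once and
  `n_input − n_excluded_age − n_excluded_no_note = n_final` always holds;
  age at admission (not at first note) decides eligibility, and exactly-18
  is included ("less than 18" excludes).
* Wald CIs use `z = 1.959964` throughout; published crude CIs in this
  problem family are consistent with Wald intervals to roughly 0.2%
  relative, so point estimates reproduce to 2 decimals while CI bounds
  should only be compared at ~1% relative tolerance.
* In `or_report()`, a level with no observations is dropped from the design
  (it would make the information matrix singular) and surfaced in
  `zero_cells` alongside levels whose crude 2×2 table has an empty cell.

## Problem sizes used by the test suite

The suite exercises the generator at n = 100,000 for marginal calibration
and at n = 200,000 across 20 seeds for coefficient recovery (fits of 38
parameters on ~198,000 eligible rows, about 700 events each); the
Hosmer–Lemeshow null calibration uses 1,000 replicates at n = 2,000. These
sizes give per-coefficient Wald standard errors of 0.08–0.5 and a
Monte-Carlo standard error of about 0.7 percentage points on the HL
rejection rate, which is tight enough to detect real miscalibration while
keeping the full suite around five minutes. With 37 coefficients checked
across only 20 seeds, 1–3 coefficients are expected to fall below 18/20
coverage by binomial noise alone even under perfect nominal coverage — the
pooled coverage (≈0.95) is the stable summary; sparse large-coefficient
terms additionally show the usual finite-sample Wald undercoverage.

## Known limitations

* No within-patient clustering: multiple admissions of one patient are
  independent rows, as in the emulated design.
* The rule extractor is a reference implementation; on real notes a trained
  labeler plugged in via `register_labeler()` is the intended path.
* ICD-9 only; the shipped code map is a placeholder to be replaced for any
  real analysis.
* No multiple imputation of missing SBDH ("unknown" is modeled as a level),
  no Firth or penalized regression for sparse cells, no multiple-testing
  adjustment — matching the emulated analysis.

## A minimal run

```{r example, eval = FALSE}
cfg <- cohort_config(n_admissions = 5000, seed = 1)
dir <- tempfile()
cmd_simulate(cfg, dir)
res <- cmd_extract(dir)        # profiles, prevalence table, source shares
rep <- cmd_analyze(dir)        # crude + adjusted ORs, HL, VIFs
rep$estimates
```
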