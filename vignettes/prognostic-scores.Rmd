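---
title: "Prognostic scoring and diagnostic evaluation for inoperable gastric cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic scoring and diagnostic evaluation for inoperable gastric cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcps)
```

## The scientific problem

Patients with inoperable gastric adenocarcinoma — locally advanced
unresectable (stage 3) or metastatic (stage 4) disease — differ widely in
prognosis, and objective prechemotherapy markers of systemic inflammation
and nutritional reserve are attractive, cheap predictors. The Glasgow
Prognostic Score (GPS) combines C-reactive protein (CRP, an acute-phase
inflammation marker) and serum albumin. Prealbumin (transthyretin), with a
circulating half-life of about two days, is a far more responsive
nutritional biomarker than albumin, which motivates an analogous
prealbumin/CRP based prognostic score (PCPS) for predicting metastatic
status.

This package implements the complete analysis around such a score for a
single-centre cohort of 71 patients (43 metastatic, 28 nonmetastatic):

* the scoring rules (GPS, PCPS, the low/high PCPS grouping, PG-SGA triage
  bands);
* ROC analysis of prealbumin with Youden-index cut-point selection;
* full binary diagnostic evaluation with the confidence-interval methods
  that clinical papers in this area actually print;
* group-comparison statistics (pooled t, Mann-Whitney, exact chi-square,
  Kruskal-Wallis);
* a synthetic cohort generator parameterised by the published group
  summaries, so the entire pipeline is testable without patient-level data;
* a rounding-aware reconstruction of exact integer confusion matrices from
  published rounded percentages.

## Scoring rules and boundary conventions

Both scores allocate 0 for two normal markers, 1 for exactly one
abnormality, and 2 for two abnormalities.

| score | marker 1 (abnormal) | marker 2 (abnormal) |
|-------|---------------------|---------------------|
| GPS   | CRP > 10 mg/L       | albumin < 3.5 g/dL  |
| PCPS  | CRP ≥ 10 mg/L       | prealbumin < 0.20 mg/dL |

Two boundary conventions deserve attention because the published
definitions fix them differently for the two scores, and `compute_gps()` /
`compute_pcps()` follow each definition literally:

* **GPS**: CRP exactly 10 mg/L and albumin exactly 3.5 g/dL are *normal*
  (both thresholds inclusive on the normal side).
* **PCPS**: CRP exactly 10 mg/L is *abnormal*, while the published score
  table omits the prealbumin-exactly-0.20 case entirely. We treat it as
  normal: the 0.20 value is itself the ROC-selected cut-off, and the
  convention "≥ cut-off is test-negative" is standard for a marker whose
  low values are the positive direction. This is a package decision, not a
  documented feature of the source analysis; the thresholds are plain
  function arguments, so sensitivity analyses are one keystroke away.

The prealbumin unit follows the published numbers verbatim (0.14–0.20
"mg/dL"). These values are about 100-fold below typical physiological
mg/dL prealbumin ranges and are plausibly mislabelled g/L; the package
deliberately does not second-guess the printed scale, because every
downstream quantity (cut-off, scores, comparisons) is scale-invariant.
Missing inputs always yield missing scores — complete-case analysis, never
imputation — because the published confidence intervals imply that only 58
of 71 patients were evaluable for the serum markers.

PG-SGA (patient-generated subjective global assessment) is treated as an
input instrument: the numeric score and the A/B/C global rating enter the
data model, and `pgsga_triage()` maps the score to the standard
intervention bands 0–1 / 2–3 / 4–8 / ≥9. Only the outer bands are fixed by
the source description; the 2–3 vs 4–8 boundary is the standard scored
PG-SGA convention.

## ROC analysis, cut-point selection, and interval methods

`roc_curve()` builds the empirical curve over all observed thresholds. The
direction is an explicit argument (`lower_is_positive` for prealbumin,
whose metastatic mean 0.14 sits below the nonmetastatic 0.20); automatic
direction detection is a reproducibility hazard and is deliberately
absent. The AUC is the trapezoidal area, identical to the rank-sum
statistic with ties counted one half; the test suite enforces that
equivalence against a brute-force pairwise oracle. `youden_cutoff()`
maximizes J = sensitivity + specificity − 1 with deterministic tie-breaks
(higher sensitivity, then lower threshold).

The interval methods are fixed choices, selected because they reproduce,
digit for digit, every confidence bound printed in the source analysis
when applied to the reconstructed integer tables (see below) — in effect a
discovered specification:

* **Wilson score intervals** for sensitivity, specificity, PPV, NPV;
* **Simel log-method intervals** for likelihood ratios,
  with SE(log LR⁺) = √((1−sen)/tp + spe/fp) and
  SE(log LR⁻) = √(sen/fn + (1−spe)/tn);
* **Hanley–McNeil** for the AUC, with q₁ = A/(2−A), q₂ = 2A²/(1+A).

Display rounding is half-up, 1 decimal for percentages and 2 for ratios,
matching the published formatting; a half-even mode exists in the
reconstruction matcher because publications rarely state their rounding
rule.

The published "regression tree" evaluating the PCPS is realized as
`stump_split()`, a single Gini-impurity-optimal split of the ordered score
levels: with a three-level ordinal predictor and a binary outcome a deeper
tree is vacuous. On cohorts with the published score-by-group structure
the optimal split is {0, 1} vs {2}, exactly the published grouping. The
reported stump metrics are apparent (resubstitution) metrics; whether the
source analysis cross-validated is unknown, which may explain why its
stump sensitivity (76.5%, implying 28 evaluable patients) differs from its
ROC-row sensitivity (77.1%, implying 58). The package reports both
reconstructions side by side without forcing a reconciliation.

## Confusion-matrix reconstruction

`reconstruct()` enumerates every 2×2 integer table (class sizes up to
`n_max`, default 71) whose rounded metrics reproduce a set of published
percentages. Four independent percentages over-determine the table: the
ROC row (77.1 / 52.2 / 71.1 / 60.0) admits the unique minimal table
(tp, fn, fp, tn) = (27, 8, 11, 12), n = 58, and that table then reproduces
all six published confidence intervals under the three interval methods —
a simultaneous check that the reconstruction and the method identification
are correct. The suite property-tests soundness (every candidate
reproduces the inputs) and completeness (a planted table is always
recovered).

## The synthetic cohort generator

`simulate_cohort()` emulates the published cohort structure — it is the
package's study-conditions definition, not a tuning knob:

* group sizes 43/28 exactly; 79% male, 54% proximal/GEJ tumours, PG-SGA
  categories A/B/C at 13/49/38% (hence 87% malnourished);
* Gaussian biomarkers per group (means/SDs from the published comparison
  table), truncated at zero by resampling; BMI truncated to (10, 60) and
  age to (18, 100);
* CRP and the scored PG-SGA drawn log-normal via
  `fit_lognormal_from_quartiles()`, which matches the published median
  exactly and the quartile ratio exactly. A two-parameter family cannot
  hit three free quantiles, so individually asymmetric printed quartiles
  are matched only up to their log-scale asymmetry — visible for the
  nonmetastatic CRP row. PG-SGA draws are rounded to integers;
* each serum biomarker (albumin, prealbumin, transferrin, CRP, TLC)
  independently masked missing at rate 0.18, completely at random. The
  published intervals imply 58 of 71 evaluable patients (58/71 ≈ 0.82);
  the missingness mechanism is unstated in the source, so MCAR is the
  neutral choice. BMI and PG-SGA are never masked: anthropometry and the
  questionnaire were completed by all patients;
* biomarkers are sampled independently within group. No published
  covariances exist to calibrate a copula, so cross-marker correlation
  (e.g. the biologically expected negative prealbumin–CRP association) is
  absent. Consequently, passing tests show that the *methods* behave
  correctly under the published marginals; they cannot certify behaviour
  under realistic joint structure, and joint-dependent quantities (e.g.
  the PCPS score distribution) match the published ones only
  approximately.

Where the source's per-sex metastasis breakdown is internally inconsistent
(rows evidently swapped), the generator uses the overall 43/28 split and
does not model a sex-by-stage interaction.

## Group-comparison statistics

`compare_means()` is the pooled-variance Student t-test (the published
mean-difference CIs are consistent with pooled degrees of freedom; Welch
is available via `pooled = FALSE`), oriented as nonmetastatic −
metastatic so that markers depressed in metastatic disease give positive
differences. `compare_distributions()` is the two-sided Mann-Whitney test.
`compare_categorical()` computes the Pearson statistic and, in exact mode,
the exact conditional p-value: all tables with the observed margins,
weighted by the multivariate hypergeometric law, summing those whose
Pearson statistic is at least the observed one — the standard meaning of
"exact chi-square" in clinical statistics software. Enumeration is over
the free cells and switches to a margins-preserving Monte Carlo
(`r2dtable`, 10⁵ draws) only when the enumeration bound exceeds 2×10⁶
tables; all tables in this analysis are enumerated exactly.
`kruskal_wallis()` applies the tie-corrected H test. No multiplicity
correction is applied anywhere, matching the source analysis design.

## Numerical choices and problem sizes

* Rounding in reconstruction matching uses half-up with a 10⁻⁹ nudge
  against binary representation artefacts.
* Youden and Gini ties break deterministically (documented above and in
  the function help).
* Degenerate inputs: single-class outcomes abort ROC/evaluation stages,
  which the pipeline reports as skipped-with-reason sections rather than
  silent omissions; empty groups make summaries `NA`.
* The generator-recovery tests use 10⁴ patients per group and compare
  Gaussian moments against closed-form zero-truncated-normal moments at
  ~4 Monte-Carlo SEs; the cut-off-recovery analysis uses 2×10⁴ per group,
  at which the empirical Youden threshold concentrates within ±0.02 of the
  analytic density crossing of the two prealbumin normals (≈0.2006
  mg/dL). These sizes keep every run in seconds while leaving comfortable
  stochastic margins.

## Worked example

```{r example, eval = FALSE}
library(pcps)

cohort <- simulate_cohort(default_synthetic_config(seed = 42))
scored <- score_cohort(cohort)

curve <- roc_curve(scored$prealbumin, scored$metastatic, "lower_is_positive")
youden_cutoff(curve)

cm <- confusion_from_predictions(scored$pcps_binary == "high",
                                 scored$metastatic)
diagnostic_report(cm)
```

The numbered scripts under `analysis/` run the same stages end to end on a
saved cohort and write their tables under `results/`.

## Known limitations

* No biomarker correlation structure, no survival endpoint, no repeated
  measures: the generator reproduces published marginals only.
* The reconstruction applies to 2×2 tables from rounded percentages; AUC
  values alone do not determine a table and are out of scope.
* AUC inference is Hanley–McNeil only (no DeLong, no bootstrap), because
  that is the method the published intervals identify.
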