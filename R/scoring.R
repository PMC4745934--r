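#' Glasgow Prognostic Score (GPS)
#'
#' Inflammation-based 0/1/2 score. A patient with CRP <= 10 mg/L and albumin
#' >= 3.5 g/dL scores 0; one abnormality scores 1; both abnormalities
#' (CRP > 10 and albumin < 3.5) score 2. Both boundary values count as
#' normal. Missing inputs give a missing score, never an imputed one.
#'
#' @param crp C-reactive protein, mg/L (vectorised; `NA` allowed).
#' @param albumin serum albumin, g/dL (vectorised; `NA` allowed).
#' @param crp_cutoff,albumin_cutoff abnormality thresholds; defaults 10 mg/L
#'   and 3.5 g/dL.
#' @return integer vector of scores in `{0, 1, 2}`, `NA` where either input
#'   is missing.
#' @export
compute_gps <- function(crp, albumin, crp_cutoff = 10, albumin_cutoff = 3.5) {
  stopifnot(length(crp) == length(albumin))
  if (any(crp <= 0, na.rm = TRUE) || any(albumin <= 0, na.rm = TRUE)) {
    stop("biomarker values must be positive")
  }
  crp_abnormal <- crp > crp_cutoff
  alb_abnormal <- albumin < albumin_cutoff
  as.integer(crp_abnormal + alb_abnormal)
}

#' Prealbumin/CRP based prognostic score (PCPS)
#'
#' Analogue of the GPS substituting prealbumin for albumin: prealbumin
#' >= 0.20 mg/dL with CRP < 10 mg/L scores 0; exactly one abnormality scores
#' 1; prealbumin < 0.20 with CRP >= 10 scores 2.
#'
#' Boundary conventions differ between the two markers and are deliberate:
#' CRP exactly at the cut-off is abnormal (the published score table puts 10
#' on the abnormal side), while prealbumin exactly at the cut-off is normal
#' (the table omits the case; a value at an ROC-selected cut-off is
#' conventionally on the negative side). Note this CRP boundary differs from
#' the GPS one (`<= 10` normal there), each following its own published
#' definition.
#'
#' @param prealbumin serum prealbumin, mg/dL (vectorised; `NA` allowed).
#' @param crp C-reactive protein, mg/L (vectorised; `NA` allowed).
#' @param prealbumin_cutoff,crp_cutoff thresholds; defaults 0.20 mg/dL and
#'   10 mg/L.
#' @return integer vector of scores in `{0, 1, 2}`, `NA` where either input
#'   is missing.
#' @export
compute_pcps <- function(prealbumin, crp, prealbumin_cutoff = 0.20,
                         crp_cutoff = 10) {
  stopifnot(length(prealbumin) == length(crp))
  if (any(prealbumin <= 0, na.rm = TRUE) || any(crp <= 0, na.rm = TRUE)) {
    stop("biomarker values must be positive")
  }
  pa_abnormal <- prealbumin < prealbumin_cutoff
  crp_abnormal <- crp >= crp_cutoff
  as.integer(pa_abnormal + crp_abnormal)
}

#' Collapse PCPS into the published two-level grouping
#'
#' Scores 0 and 1 form the `"low"` category, score 2 the `"high"` category.
#'
#' @param score integer PCPS values in `{0, 1, 2}` (`NA` allowed).
#' @return character vector `"low"`/`"high"`, `NA` propagated.
#' @export
binarize_pcps <- function(score) {
  if (any(!score %in% c(0L, 1L, 2L) & !is.na(score))) {
    stop("PCPS scores must be 0, 1 or 2")
  }
  ifelse(is.na(score), NA_character_, ifelse(score == 2L, "high", "low"))
}

#' PG-SGA nutritional triage bands
#'
#' Maps the scored patient-generated subjective global assessment to the
#' standard triage recommendation: 0-1 no intervention needed, 2-3 patient
#' and family education, 4-8 dietitian intervention, >= 9 critical need for
#' symptom management and/or nutritional support.
#'
#' @param pgsga_score non-negative integer score (vectorised; `NA` allowed).
#' @return character vector of band labels, `NA` propagated.
#' @export
pgsga_triage <- function(pgsga_score) {
  if (any(pgsga_score < 0, na.rm = TRUE)) stop("pgsga_score must be >= 0")
  bands <- c("none_needed", "patient_family_education", "dietitian_intervention",
             "critical_need")
  idx <- findInterval(pgsga_score, c(0, 2, 4, 9))
  bands[idx]
}

#' Score every patient in a cohort
#'
#' Appends `gps`, `pcps`, `pcps_binary` and `pgsga_triage` columns. Scores
#' are missing wherever an input biomarker is missing; input fields are
#' untouched, and the operation is idempotent.
#'
#' @param cohort a cohort (see [as_cohort()]).
#' @param prealbumin_cutoff,crp_cutoff_pcps,crp_cutoff_gps,albumin_cutoff
#'   score thresholds, passed through to [compute_pcps()] and
#'   [compute_gps()].
#' @return the cohort with four appended (or overwritten) score columns.
#' @export
score_cohort <- function(cohort, prealbumin_cutoff = 0.20, crp_cutoff_pcps = 10,
                         crp_cutoff_gps = 10, albumin_cutoff = 3.5) {
  cohort$gps <- compute_gps(cohort$crp, cohort$albumin,
                            crp_cutoff = crp_cutoff_gps,
                            albumin_cutoff = albumin_cutoff)
  cohort$pcps <- compute_pcps(cohort$prealbumin, cohort$crp,
                              prealbumin_cutoff = prealbumin_cutoff,
                              crp_cutoff = crp_cutoff_pcps)
  cohort$pcps_binary <- binarize_pcps(cohort$pcps)
  cohort$pgsga_triage <- pgsga_triage(cohort$pgsga_score)
  cohort
}
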