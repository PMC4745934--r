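#' Run the full prognostic-score analysis pipeline
#'
#' Orchestrates simulate/load -> score -> ROC and Youden cut-off -> binary
#' diagnostic evaluation -> group-comparison statistics, producing one
#' machine-readable report whose sections mirror the published table
#' structure of a prognostic-score study: cohort summary, group-wise
#' biomarker comparisons, prealbumin ROC with cut-off, PCPS evaluation
#' against metastasis, score-by-nutrition and score-by-metastasis
#' associations. Every section records its complete-case n — the shifting
#' denominators of complete-case analyses are the chief reproducibility
#' hazard of this kind of study — and any section that cannot be computed is
#' marked skipped with a reason rather than dropped.
#'
#' @param config a `"synthetic_config"` (or path to a YAML/JSON config);
#'   drives simulation when no cohort is given and supplies the score
#'   thresholds' defaults.
#' @param cohort optional cohort (or path to a cohort CSV); when supplied,
#'   simulation is skipped.
#' @param prealbumin_cutoff,crp_cutoff threshold defaults for the scores.
#' @return list of class `"analysis_report"`; serialize with
#'   [write_report()].
#' @export
run_pipeline <- function(config = default_synthetic_config(), cohort = NULL,
                         prealbumin_cutoff = 0.20, crp_cutoff = 10) {
  if (is.character(config)) config <- read_synthetic_config(config)
  validate_synthetic_config(config)
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  scored <- score_cohort(cohort, prealbumin_cutoff = prealbumin_cutoff,
                         crp_cutoff_pcps = crp_cutoff,
                         crp_cutoff_gps = crp_cutoff)
  section <- function(expr) {
    tryCatch(expr, error = function(e) list(skipped = TRUE,
                                            reason = conditionMessage(e)))
  }

  cohort_summary <- list(
    n = nrow(scored),
    n_metastatic = sum(scored$metastatic),
    n_nonmetastatic = sum(!scored$metastatic),
    prop_male = mean(scored$sex == "male"),
    prop_gej_proximal = mean(scored$anatomic_site == "GEJ_proximal"),
    pgsga_category = as.list(prop.table(table(factor(scored$pgsga_category,
                                                     levels = c("A", "B", "C"))))),
    prop_malnourished = mean(scored$pgsga_category %in% c("B", "C")),
    pgsga_mean = mean(scored$pgsga_score, na.rm = TRUE),
    pgsga_sd = stats::sd(scored$pgsga_score, na.rm = TRUE)
  )

  gaussian_vars <- c("bmi", "albumin", "prealbumin", "transferrin", "tlc")
  group_comparisons <- c(
    lapply(gaussian_vars, function(v) section(
      compare_means(scored[[v]], scored$metastatic, variable = v))),
    lapply(c("crp", "pgsga_score"), function(v) section(
      compare_distributions(scored[[v]], scored$metastatic, variable = v)))
  )
  names(group_comparisons) <- c(gaussian_vars, "crp", "pgsga_score")

  roc_section <- section({
    curve <- roc_curve(scored$prealbumin, scored$metastatic,
                       direction = "lower_is_positive")
    cut <- youden_cutoff(curve)
    n_cc <- sum(!is.na(scored$prealbumin))
    list(auc = curve$auc, ci_auc = curve$ci_auc, n_complete = n_cc,
         n_pos = curve$n_pos, n_neg = curve$n_neg,
         cutoff = cut$threshold, youden_j = cut$youden_j,
         sen_at_cutoff = cut$sen, spe_at_cutoff = cut$spe)
  })

  evaluation <- section({
    cm <- confusion_from_predictions(scored$pcps_binary == "high",
                                     scored$metastatic)
    stump <- stump_split(scored$pcps, scored$metastatic)
    list(pcps_high_vs_metastasis = diagnostic_report(cm),
         stump = stump)
  })

  score_by_nutrition <- section(list(
    gps = kruskal_wallis(scored$pgsga_score, scored$gps, "pgsga_by_gps"),
    pcps = kruskal_wallis(scored$pgsga_score, scored$pcps, "pgsga_by_pcps")
  ))

  score_by_metastasis <- section({
    make_table <- function(score_col) {
      tab <- table(factor(scored[[score_col]], levels = 0:2),
                   factor(ifelse(scored$metastatic, "metastatic", "nonmetastatic"),
                          levels = c("metastatic", "nonmetastatic")))
      tab <- unclass(tab)[rowSums(tab) > 0, , drop = FALSE]  # unobserved levels
      compare_categorical(tab, exact = TRUE, variable = score_col)
    }
    list(gps = make_table("gps"), pcps = make_table("pcps"))
  })

  report <- list(
    cohort_summary = cohort_summary,
    group_comparisons = group_comparisons,
    roc = roc_section,
    evaluation = evaluation,
    score_by_nutrition = score_by_nutrition,
    score_by_metastasis = score_by_metastasis,
    provenance = list(
      seed = config$seed,
      cohort_source = (attr(cohort, "provenance") %||% list())$source,
      package_version = as.character(utils::packageVersion("pcps")),
      thresholds = list(prealbumin = prealbumin_cutoff, crp = crp_cutoff)
    )
  )
  class(report) <- "analysis_report"
  report
}

#' Serialize an analysis report to JSON
#'
#' Deterministic JSON rendering of [run_pipeline()] output: running the
#' pipeline twice with the same config and seed yields byte-identical
#' files.
#'
#' @param report an `"analysis_report"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}
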