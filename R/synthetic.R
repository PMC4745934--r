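#' Fit a log-normal distribution from median and quartiles
#'
#' Right-skewed biomarkers (CRP, the scored PG-SGA) are typically published
#' as median (25th-75th percentile). A log-normal with
#' `mu = log(median)` and `sigma = log(q75/q25) / (2 * qnorm(0.75))`
#' reproduces exactly those three summaries.
#'
#' @param median,q25,q75 positive reals with `q25 < median < q75`.
#' @return list with log-scale location `mu` and scale `sigma`.
#' @examples
#' fit_lognormal_from_quartiles(37.60, 15.59, 85.16)
#' @export
fit_lognormal_from_quartiles <- function(median, q25, q75) {
  if (!(is.finite(median) && is.finite(q25) && is.finite(q75))) {
    stop("median and quartiles must be finite")
  }
  if (q25 <= 0) stop("quartiles must be positive")
  if (!(q25 < median && median < q75)) {
    stop("need q25 < median < q75, got (", q25, ", ", median, ", ", q75, ")")
  }
  list(mu = log(median), sigma = log(q75 / q25) / (2 * stats::qnorm(0.75)))
}

#' Default synthetic-cohort configuration
#'
#' Encodes the published cohort structure of a 71-patient inoperable gastric
#' adenocarcinoma study: 43 metastatic (stage 4) and 28 nonmetastatic
#' (stage 3) patients; 79% male; 54% gastroesophageal-junction/proximal
#' tumours; PG-SGA categories A/B/C at 13/49/38%; group-wise biomarker
#' means/SDs (BMI, albumin, prealbumin, transferrin, TLC), CRP and scored
#' PG-SGA medians with quartiles; and an 18% independent missingness rate on
#' the five serum biomarkers (yielding ~58 of 71 evaluable patients per
#' marker, matching the published complete-case denominators).
#'
#' @param seed integer RNG seed stored in the config; drives
#'   [simulate_cohort()].
#' @return a list of class `"synthetic_config"`.
#' @export
default_synthetic_config <- function(seed = 1L) {
  config <- list(
    metastatic = list(
      n = 43L,
      prealbumin_mean = 0.14, prealbumin_sd = 0.06,
      albumin_mean = 3.57, albumin_sd = 0.74,
      transferrin_mean = 218.48, transferrin_sd = 119.68,
      tlc_mean = 1.18, tlc_sd = 0.49,
      bmi_mean = 21.94, bmi_sd = 3.94,
      crp_median = 37.60, crp_q25 = 15.59, crp_q75 = 85.16,
      pgsga_median = 17, pgsga_q25 = 13, pgsga_q75 = 20.5
    ),
    nonmetastatic = list(
      n = 28L,
      prealbumin_mean = 0.20, prealbumin_sd = 0.10,
      albumin_mean = 3.94, albumin_sd = 0.68,
      transferrin_mean = 279.07, transferrin_sd = 135.75,
      tlc_mean = 1.27, tlc_sd = 0.54,
      bmi_mean = 22.13, bmi_sd = 4.11,
      crp_median = 15.61, crp_q25 = 5.52, crp_q75 = 30.01,
      pgsga_median = 17, pgsga_q25 = 11, pgsga_q75 = 19
    ),
    prop_male = 0.79,
    prop_gej_proximal = 0.54,
    pgsga_category_probs = c(A = 0.13, B = 0.49, C = 0.38),
    age_mean = 62.13, age_sd = 14.39,
    biomarker_missing_rate = 0.18,
    seed = as.integer(seed)
  )
  class(config) <- "synthetic_config"
  config
}

#' Load a synthetic-cohort configuration from YAML or JSON
#'
#' Fields present in the file override the defaults from
#' [default_synthetic_config()]; everything else keeps its default.
#'
#' @param path a `.yaml`/`.yml` or `.json` file mirroring the config fields.
#' @param seed optional seed overriding both the file and the default.
#' @return a validated `"synthetic_config"`.
#' @export
read_synthetic_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # YAML 1.1 parses a bare `n:` key as a boolean; restore the field name
  fix_n_key <- function(lst) {
    if (is.list(lst) && "FALSE" %in% names(lst)) {
      names(lst)[names(lst) == "FALSE"] <- "n"
    }
    lst
  }
  for (grp in intersect(c("metastatic", "nonmetastatic"), names(raw))) {
    raw[[grp]] <- fix_n_key(raw[[grp]])
  }
  config <- default_synthetic_config()
  config <- utils::modifyList(config, raw)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(names(raw$pgsga_category_probs))) {
    config$pgsga_category_probs <- unlist(raw$pgsga_category_probs)[c("A", "B", "C")]
  }
  class(config) <- "synthetic_config"
  validate_synthetic_config(config)
  config
}

validate_synthetic_config <- function(config) {
  for (grp in c("metastatic", "nonmetastatic")) {
    g <- config[[grp]]
    if (g$n < 0L) stop(grp, "$n must be >= 0")
    sds <- unlist(g[grep("_sd$", names(g))])
    if (any(sds <= 0)) stop(grp, ": all SDs must be positive")
    if (!(g$crp_q25 < g$crp_median && g$crp_median < g$crp_q75)) {
      stop(grp, ": CRP quartiles must be increasing")
    }
    if (!(g$pgsga_q25 < g$pgsga_median && g$pgsga_median < g$pgsga_q75)) {
      stop(grp, ": PG-SGA quartiles must be increasing")
    }
  }
  fracs <- c(config$prop_male, config$prop_gej_proximal, config$biomarker_missing_rate)
  if (any(fracs < 0 | fracs > 1)) stop("proportions must lie in [0, 1]")
  if (abs(sum(config$pgsga_category_probs) - 1) > 1e-8) {
    stop("pgsga_category_probs must sum to 1")
  }
  if (config$metastatic$n + config$nonmetastatic$n < 1L) {
    stop("at least one patient required")
  }
  invisible(config)
}

# Zero-truncated (optionally interval-truncated) Gaussian by resampling.
rnorm_truncated <- function(n, mean, sd, lower = 0, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
  }
  x
}

#' Simulate a synthetic cohort
#'
#' Draws `metastatic$n + nonmetastatic$n` patients. Gaussian biomarkers come
#' from the group means/SDs truncated at zero (BMI additionally truncated to
#' its plausible range, age to 18-100); CRP is log-normal via
#' [fit_lognormal_from_quartiles()]; the scored PG-SGA is log-normal from its
#' quartiles, rounded to an integer. Sex, anatomic site and PG-SGA category
#' are drawn from the configured proportions independently of group. Each
#' serum biomarker (albumin, prealbumin, transferrin, CRP, TLC) is masked
#' missing independently at `biomarker_missing_rate`. Biomarkers are sampled
#' independently within group; no correlation structure is imposed.
#' Fully reproducible given `config$seed`.
#'
#' @param config a `"synthetic_config"`, e.g. [default_synthetic_config()].
#' @return a validated cohort (see [as_cohort()]).
#' @export
simulate_cohort <- function(config = default_synthetic_config()) {
  validate_synthetic_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  sim_group <- function(params, metastatic) {
    n <- params$n
    if (n == 0L) return(NULL)
    crp_par <- fit_lognormal_from_quartiles(params$crp_median, params$crp_q25,
                                            params$crp_q75)
    pg_par <- fit_lognormal_from_quartiles(params$pgsga_median, params$pgsga_q25,
                                           params$pgsga_q75)
    data.frame(
      age = rnorm_truncated(n, config$age_mean, config$age_sd, 18, 100),
      sex = ifelse(stats::runif(n) < config$prop_male, "male", "female"),
      anatomic_site = ifelse(stats::runif(n) < config$prop_gej_proximal,
                             "GEJ_proximal", "distal"),
      stage = if (metastatic) 4L else 3L,
      metastatic = metastatic,
      bmi = rnorm_truncated(n, params$bmi_mean, params$bmi_sd, 10, 60),
      albumin = rnorm_truncated(n, params$albumin_mean, params$albumin_sd),
      prealbumin = rnorm_truncated(n, params$prealbumin_mean, params$prealbumin_sd),
      transferrin = rnorm_truncated(n, params$transferrin_mean, params$transferrin_sd),
      crp = stats::rlnorm(n, crp_par$mu, crp_par$sigma),
      tlc = rnorm_truncated(n, params$tlc_mean, params$tlc_sd),
      pgsga_score = round(stats::rlnorm(n, pg_par$mu, pg_par$sigma)),
      pgsga_category = sample(c("A", "B", "C"), n, replace = TRUE,
                              prob = config$pgsga_category_probs),
      stringsAsFactors = FALSE
    )
  }

  df <- rbind(sim_group(config$metastatic, TRUE),
              sim_group(config$nonmetastatic, FALSE))
  df$patient_id <- sprintf("P%03d", seq_len(nrow(df)))
  for (col in BIOMARKER_COLUMNS) {
    mask <- stats::runif(nrow(df)) < config$biomarker_missing_rate
    df[[col]][mask] <- NA_real_
  }
  as_cohort(df[COHORT_COLUMNS], strict = TRUE,
            provenance = list(source = "simulate_cohort", seed = config$seed,
                              generator_version = "pcps 0.1.0"))
}

#' Summarize a cohort by metastasis group
#'
#' Per biomarker and group: number of non-missing values, mean and SD, and
#' median with 25th/75th percentiles, computed over non-missing values only.
#' Groups with no non-missing values get `NA` summaries.
#'
#' @param cohort a cohort.
#' @return data frame with one row per (variable, group).
#' @export
summarize_cohort <- function(cohort) {
  vars <- c("bmi", "albumin", "prealbumin", "transferrin", "crp", "tlc",
            "pgsga_score")
  groups <- list(metastatic = cohort$metastatic, nonmetastatic = !cohort$metastatic)
  rows <- list()
  for (v in vars) {
    for (g in names(groups)) {
      x <- cohort[[v]][groups[[g]]]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = g, n = length(x),
        mean = if (length(x) >= 1L) mean(x) else NA_real_,
        sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
        median = if (length(x) >= 1L) stats::median(x) else NA_real_,
        q25 = if (length(x) >= 1L) unname(stats::quantile(x, 0.25)) else NA_real_,
        q75 = if (length(x) >= 1L) unname(stats::quantile(x, 0.75)) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
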