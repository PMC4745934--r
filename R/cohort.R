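#' @keywords internal
"_PACKAGE"

# Column layout of a cohort table. `metastatic` is stored explicitly even
# though derivable from stage: the outcome label is the analysis pivot and
# the redundancy catches data-entry errors at validation time.
COHORT_COLUMNS <- c(
  "patient_id", "age", "sex", "anatomic_site", "stage", "metastatic",
  "bmi", "albumin", "prealbumin", "transferrin", "crp", "tlc",
  "pgsga_score", "pgsga_category"
)

BIOMARKER_COLUMNS <- c("albumin", "prealbumin", "transferrin", "crp", "tlc")

NUMERIC_COLUMNS <- c("age", "bmi", BIOMARKER_COLUMNS, "pgsga_score")

#' Construct a validated cohort
#'
#' A cohort is a data frame with one row per patient and a fixed column set:
#' `patient_id`, `age` (years), `sex` (`male`/`female`), `anatomic_site`
#' (`GEJ_proximal`/`distal`), `stage` (3 = locally advanced unresectable,
#' 4 = distant metastasis), `metastatic` (logical, must equal `stage == 4`),
#' `bmi` (kg/m2), `albumin` (g/dL), `prealbumin` (mg/dL), `transferrin`
#' (mg/dL), `crp` (mg/L), `tlc` (10^9 cells/L), `pgsga_score` (non-negative
#' integer) and `pgsga_category` (`A`/`B`/`C`). Any biomarker may be `NA`
#' (missing); missing values are never imputed downstream.
#'
#' @param df data frame holding the columns above (extra columns are kept).
#' @param strict if `TRUE`, any invariant violation is an error; otherwise
#'   offending rows are dropped and counted in the `provenance` attribute.
#' @param provenance free-text metadata (source, seed, generator version)
#'   stored as an attribute.
#' @return the validated data frame, with class `"cohort"` prepended and a
#'   `provenance` attribute.
#' @export
as_cohort <- function(df, strict = TRUE, provenance = list()) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("cohort must contain at least one patient")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in NUMERIC_COLUMNS) df[[col]] <- as.numeric(df[[col]])
  df$stage <- as.integer(df$stage)
  df$metastatic <- as.logical(df$metastatic)
  df$patient_id <- as.character(df$patient_id)

  bad <- cohort_row_violations(df)
  if (any(bad != "")) {
    msgs <- paste0("row ", which(bad != ""), ": ", bad[bad != ""])
    if (strict) {
      stop("cohort validation failed:\n  ", paste(msgs, collapse = "\n  "))
    }
    df <- df[bad == "", , drop = FALSE]
    if (nrow(df) == 0L) stop("all rows failed validation")
    provenance$dropped_rows <- sum(bad != "")
    provenance$drop_reasons <- msgs
  }
  if (anyDuplicated(df$patient_id)) stop("patient_id values must be unique")
  rownames(df) <- NULL
  class(df) <- unique(c("cohort", class(df)))
  attr(df, "provenance") <- provenance
  df
}

# One message per offending row ("" = row is valid). Biomarkers may be NA;
# when present they must be positive. Mandatory fields must be non-missing.
cohort_row_violations <- function(df) {
  n <- nrow(df)
  msg <- character(n)
  flag <- function(cond, text) {
    cond[is.na(cond)] <- TRUE
    ifelse(cond & msg == "", text, msg)
  }
  msg <- flag(is.na(df$patient_id) | df$patient_id == "", "missing patient_id")
  msg <- flag(is.na(df$metastatic), "missing metastatic label")
  msg <- flag(!(df$stage %in% c(3L, 4L)), "stage must be 3 or 4")
  msg <- flag(df$metastatic != (df$stage == 4L), "metastatic label inconsistent with stage")
  msg <- flag(!(df$sex %in% c("male", "female")), "sex must be male/female")
  msg <- flag(!(df$anatomic_site %in% c("GEJ_proximal", "distal")),
              "anatomic_site must be GEJ_proximal/distal")
  msg <- flag(!(df$pgsga_category %in% c("A", "B", "C")), "pgsga_category must be A/B/C")
  ok_range <- function(x, lo, hi) is.na(x) | (x > lo & x < hi)
  msg <- flag(!ok_range(df$age, 18, 100), "age outside (18, 100)")
  msg <- flag(!ok_range(df$bmi, 10, 60), "bmi outside (10, 60)")
  for (col in BIOMARKER_COLUMNS) {
    msg <- flag(!(is.na(df[[col]]) | df[[col]] > 0), paste0(col, " must be positive"))
  }
  msg <- flag(!(is.na(df$pgsga_score) | df$pgsga_score >= 0), "pgsga_score must be >= 0")
  msg
}

#' Read a cohort from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row naming the cohort
#' columns. Empty cells encode missing biomarkers.
#'
#' @param path path to the CSV file.
#' @param strict passed to [as_cohort()]: error on invalid rows (`TRUE`) or
#'   drop them with a count in provenance (`FALSE`).
#' @return a validated cohort.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "")
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in NUMERIC_COLUMNS) {
    x <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(parsed)
    if (any(bad) && strict) {
      stop("unparseable numeric value in column '", col, "', row ",
           which(bad)[1L], ": '", x[which(bad)[1L]], "'")
    }
    raw[[col]] <- parsed
  }
  raw$metastatic <- tolower(raw$metastatic) %in% c("true", "t", "1", "yes")
  as_cohort(raw, strict = strict, provenance = list(source = path))
}

#' Write a cohort to CSV
#'
#' Numeric values are written at full double precision so that
#' `read_cohort(write_cohort(x))` reproduces `x` field-for-field, including
#' the missingness pattern (missing values become empty cells). Output is
#' deterministic: identical cohorts give byte-identical files.
#'
#' @param cohort a validated cohort.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort, strict = TRUE,
                      provenance = attr(cohort, "provenance") %||% list())
  out <- cohort[COHORT_COLUMNS]
  for (col in NUMERIC_COLUMNS) {
    x <- out[[col]]
    out[[col]] <- ifelse(is.na(x), "", sprintf("%.17g", x))
  }
  out$metastatic <- ifelse(out$metastatic, "TRUE", "FALSE")
  utils::write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
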