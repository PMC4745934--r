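#' Construct a confusion matrix
#'
#' Cell counts for a binary classifier; the positive class throughout this
#' package is metastatic disease.
#'
#' @param tp,fn,fp,tn non-negative integer counts (true/false positives and
#'   negatives).
#' @return list of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Cross-tabulate predictions against truth
#'
#' @param predicted_positive,truth equal-length logical vectors; pairs with
#'   any `NA` are dropped (complete-case analysis).
#' @return a [confusion_matrix()].
#' @export
confusion_from_predictions <- function(predicted_positive, truth) {
  stopifnot(length(predicted_positive) == length(truth))
  keep <- !is.na(predicted_positive) & !is.na(truth)
  p <- predicted_positive[keep]
  t <- truth[keep]
  if (length(p) == 0L) stop("no complete cases")
  confusion_matrix(tp = sum(p & t), fn = sum(!p & t),
                   fp = sum(p & !t), tn = sum(!p & !t))
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes, `n` trials, `conf_level` coverage (default 0.95).
#' @param n number of trials.
#' @param conf_level confidence level.
#' @return numeric `c(lower, upper)`, always within `[0, 1]` and containing
#'   `k/n`.
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  # clamp to [0,1] and guarantee the point estimate is bracketed even when
  # p-hat sits on a boundary and the quotient loses an ulp
  c(lower = max(0, min((centre - half) / denom, p)),
    upper = min(1, max((centre + half) / denom, p)))
}

# Simel log-method interval for a likelihood ratio: exp(log(lr) +/- z * se).
lr_log_ci <- function(lr, se, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (!is.finite(lr) || lr <= 0 || !is.finite(se)) return(c(lower = NA_real_, upper = NA_real_))
  exp(log(lr) + c(lower = -1, upper = 1) * z * se)
}

#' Full diagnostic evaluation of a confusion matrix
#'
#' Point estimates: sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' predictive values, accuracy, likelihood ratios `LR+ = sen/(1-spe)` and
#' `LR- = (1-sen)/spe`, and the Youden index `J = sen + spe - 1`.
#' Proportion intervals use the Wilson score method; likelihood-ratio
#' intervals use the Simel log method with
#' `SE(log LR+) = sqrt((1-sen)/tp + spe/fp)` and
#' `SE(log LR-) = sqrt(sen/fn + (1-spe)/tn)`. A perfect specificity makes
#' `LR+` infinite with an undefined interval; a zero cell inside an SE term
#' leaves that interval `NA` and sets `ci_flagged`.
#'
#' @param cm a [confusion_matrix()].
#' @param conf_level confidence level for all intervals (default 0.95).
#' @return list of class `"diagnostic_report"`.
#' @export
diagnostic_report <- function(cm, conf_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n_pos <- cm$tp + cm$fn
  n_neg <- cm$tn + cm$fp
  if (n_pos < 1L || n_neg < 1L) stop("need at least one case in each class")
  n <- n_pos + n_neg
  sen <- cm$tp / n_pos
  spe <- cm$tn / n_neg
  lr_pos <- if (spe < 1) sen / (1 - spe) else Inf
  lr_neg <- if (spe > 0) (1 - sen) / spe else Inf
  se_log_lrp <- if (cm$tp > 0 && cm$fp > 0) sqrt((1 - sen) / cm$tp + spe / cm$fp) else NA_real_
  se_log_lrn <- if (cm$fn > 0 && cm$tn > 0) sqrt(sen / cm$fn + (1 - spe) / cm$tn) else NA_real_
  report <- list(
    cm = cm, n_pos = n_pos, n_neg = n_neg, n = n,
    sen = sen, spe = spe,
    ppv = if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_,
    npv = if (cm$tn + cm$fn > 0) cm$tn / (cm$tn + cm$fn) else NA_real_,
    accuracy = (cm$tp + cm$tn) / n,
    lr_pos = lr_pos, lr_neg = lr_neg,
    youden_j = sen + spe - 1,
    ci_sen = wilson_ci(cm$tp, n_pos, conf_level),
    ci_spe = wilson_ci(cm$tn, n_neg, conf_level),
    ci_ppv = if (cm$tp + cm$fp > 0) wilson_ci(cm$tp, cm$tp + cm$fp, conf_level) else c(NA, NA),
    ci_npv = if (cm$tn + cm$fn > 0) wilson_ci(cm$tn, cm$tn + cm$fn, conf_level) else c(NA, NA),
    ci_lr_pos = lr_log_ci(lr_pos, se_log_lrp, conf_level),
    ci_lr_neg = lr_log_ci(lr_neg, se_log_lrn, conf_level),
    ci_flagged = is.na(se_log_lrp) || is.na(se_log_lrn),
    conf_level = conf_level
  )
  class(report) <- "diagnostic_report"
  report
}

#' @export
print.diagnostic_report <- function(x, ...) {
  pct <- function(p) sprintf("%.1f%%", round_half_up(100 * p, 1))
  ci_pct <- function(ci) sprintf("(%.1f-%.1f)", round_half_up(100 * ci[1], 1),
                                 round_half_up(100 * ci[2], 1))
  ratio <- function(r) sprintf("%.2f", round_half_up(r, 2))
  cat(sprintf("Diagnostic report (n = %d: %d positive, %d negative)\n",
              x$n, x$n_pos, x$n_neg))
  cat(sprintf("  sensitivity %s %s   specificity %s %s\n",
              pct(x$sen), ci_pct(x$ci_sen), pct(x$spe), ci_pct(x$ci_spe)))
  cat(sprintf("  PPV %s %s   NPV %s %s\n",
              pct(x$ppv), ci_pct(x$ci_ppv), pct(x$npv), ci_pct(x$ci_npv)))
  cat(sprintf("  accuracy %s   LR+ %s (%s-%s)   LR- %s (%s-%s)\n",
              pct(x$accuracy), ratio(x$lr_pos), ratio(x$ci_lr_pos[1]),
              ratio(x$ci_lr_pos[2]), ratio(x$lr_neg), ratio(x$ci_lr_neg[1]),
              ratio(x$ci_lr_neg[2])))
  cat(sprintf("  Youden J %.3f\n", x$youden_j))
  invisible(x)
}

#' Likelihood ratios from sensitivity and specificity
#'
#' `LR+ = sen/(1-spe)`; `LR- = (1-sen)/spe`. Useful for recomputing
#' published likelihood ratios directly from published operating
#' characteristics.
#'
#' @param sen,spe proportions in `[0, 1]`.
#' @return list with `lr_pos` and `lr_neg`.
#' @export
likelihood_ratios <- function(sen, spe) {
  stopifnot(sen >= 0, sen <= 1, spe >= 0, spe <= 1)
  list(lr_pos = if (spe < 1) sen / (1 - spe) else Inf,
       lr_neg = if (spe > 0) (1 - sen) / spe else Inf)
}

#' Empirical ROC curve
#'
#' Builds the threshold-indexed (false-positive rate, sensitivity) curve
#' over all unique observed values plus a sentinel, computes the area under
#' the curve by the trapezoidal rule (equivalent to the rank-sum statistic
#' with ties counted one half), and attaches a Hanley-McNeil confidence
#' interval. The classification direction is an explicit argument, never
#' auto-detected: `"lower_is_positive"` predicts the positive class when
#' `value < threshold` (appropriate when the positive group has the lower
#' marker mean, as for prealbumin in metastatic disease);
#' `"higher_is_positive"` predicts positive when `value > threshold`.
#'
#' @param values numeric biomarker values (complete cases only are used).
#' @param truth logical, `TRUE` for the positive class.
#' @param direction `"lower_is_positive"` or `"higher_is_positive"`.
#' @param conf_level confidence level for the AUC interval.
#' @return list of class `"roc_curve"` with `thresholds`, `sen`, `fpr`,
#'   `auc`, `ci_auc`, `n_pos`, `n_neg`, `direction`.
#' @export
roc_curve <- function(values, truth,
                      direction = c("lower_is_positive", "higher_is_positive"),
                      conf_level = 0.95) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(truth))
  keep <- !is.na(values) & !is.na(truth)
  x <- values[keep]
  y <- truth[keep]
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos < 1L || n_neg < 1L) stop("need at least one case in each class")

  # Work on a scale where smaller transformed values are called positive.
  xt <- if (direction == "lower_is_positive") x else -x
  u <- sort(unique(xt))
  idx <- match(xt, u)
  pos_at <- as.numeric(rowsum(as.numeric(y), idx)[, 1])  # ordered by level
  tot_at <- tabulate(idx, nbins = length(u))
  neg_at <- tot_at - pos_at
  # Threshold t classifies transformed value < t as positive; t = u[i] has
  # everything strictly below u[i] positive, the +Inf sentinel everything.
  sen <- c(0, cumsum(pos_at)) / n_pos
  fpr <- c(0, cumsum(neg_at)) / n_neg
  thresholds_t <- c(u, Inf)
  thresholds <- if (direction == "lower_is_positive") thresholds_t else -thresholds_t
  auc <- sum(diff(fpr) * (utils::head(sen, -1) + utils::tail(sen, -1)) / 2)
  ci_auc <- if (n_pos >= 2 && n_neg >= 2) {
    hanley_mcneil_ci(auc, n_pos, n_neg, conf_level)
  } else {
    c(lower = NA_real_, upper = NA_real_)
  }
  structure(list(thresholds = thresholds, sen = sen, fpr = fpr,
                 auc = auc,
                 ci_auc = ci_auc,
                 n_pos = n_pos, n_neg = n_neg, direction = direction,
                 conf_level = conf_level),
            class = "roc_curve")
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal-approximation interval using the Hanley-McNeil standard error with
#' `q1 = A/(2-A)` and `q2 = 2A^2/(1+A)`:
#' `SE^2 = (A(1-A) + (n_pos-1)(q1-A^2) + (n_neg-1)(q2-A^2)) / (n_pos n_neg)`.
#'
#' @param auc area under the curve, in (0, 1) for a finite-width interval.
#' @param n_pos,n_neg class sizes (each >= 2).
#' @param conf_level confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
hanley_mcneil_ci <- function(auc, n_pos, n_neg, conf_level = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 2, n_neg >= 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(lower = auc - z * se, upper = auc + z * se)
}

#' Youden-index-optimal cut-off on an ROC curve
#'
#' Returns the threshold maximizing `J = sensitivity + specificity - 1`.
#' Ties are broken toward higher sensitivity, then toward the lower
#' threshold, so the result is deterministic.
#'
#' @param curve an [roc_curve()].
#' @return list of class `"cutoff_result"` with `threshold`, `youden_j`,
#'   `sen`, `spe`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sen - curve$fpr
  best <- which(j >= max(j) - 1e-12)
  best <- best[curve$sen[best] >= max(curve$sen[best]) - 1e-12]
  best <- best[which.min(curve$thresholds[best])]
  structure(list(threshold = curve$thresholds[best],
                 youden_j = j[best],
                 sen = curve$sen[best],
                 spe = 1 - curve$fpr[best]),
            class = "cutoff_result")
}

#' Single-split classification stump for an ordinal score
#'
#' Realizes a "regression tree" over a low-cardinality ordinal predictor and
#' binary outcome as the only non-vacuous tree: a single binary split of the
#' ordered score levels. Every split `score <= s` vs `score > s` is
#' evaluated; the one minimizing total Gini impurity is returned, each side
#' predicting its majority truth class (ties predict the positive class).
#'
#' @param score ordinal numeric score per patient (`NA` pairs dropped).
#' @param truth logical outcome per patient.
#' @return list with `split_point` (largest level on the left side), `gini`,
#'   the left/right predicted classes and the resulting
#'   [confusion_matrix()].
#' @export
stump_split <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  keep <- !is.na(score) & !is.na(truth)
  s <- score[keep]
  y <- truth[keep]
  levels <- sort(unique(s))
  if (length(levels) < 2L) stop("score must have at least 2 distinct values")
  n <- length(s)
  gini <- function(y_side) {
    if (length(y_side) == 0L) return(0)
    p <- mean(y_side)
    1 - p^2 - (1 - p)^2
  }
  candidates <- utils::head(levels, -1)
  impurity <- vapply(candidates, function(cut) {
    left <- s <= cut
    (sum(left) * gini(y[left]) + sum(!left) * gini(y[!left])) / n
  }, numeric(1))
  best <- which.min(impurity)  # ties: lowest split point
  cut <- candidates[best]
  left <- s <= cut
  majority_positive <- function(y_side) mean(y_side) >= 0.5
  pred <- ifelse(left, majority_positive(y[left]), majority_positive(y[!left]))
  list(split_point = cut,
       gini = impurity[best],
       predict_left = majority_positive(y[left]),
       predict_right = majority_positive(y[!left]),
       cm = confusion_from_predictions(as.logical(pred), y))
}
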