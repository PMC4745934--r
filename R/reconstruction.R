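#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention most clinical
#' software prints with), unlike base `round()`'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny nudge guards against values like 2.5 stored as 2.4999999999999996
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Does value (e.g. 100*tp/(tp+fn)) print as `printed` at `digits` decimals?
matches_rounded <- function(value, printed, digits, rounding) {
  r <- if (rounding == "half_up") round_half_up(value, digits) else round(value, digits)
  abs(r - printed) < 10^(-digits) / 2
}

#' Reconstruct integer confusion matrices from rounded published metrics
#'
#' Exhaustively enumerates all 2x2 integer tables with `tp + fn <= n_max`
#' and `tn + fp <= n_max` whose metrics, rounded to the printed precision,
#' reproduce every supplied percentage: sensitivity and specificity always,
#' plus any of PPV, NPV and accuracy that are given. Candidates are sorted
#' by total sample size, so the first row is the smallest table consistent
#' with everything printed. With several independent percentages the minimal
#' table is usually unique, turning a published summary row back into an
#' exact integer fixture.
#'
#' @param sen_pct,spe_pct published sensitivity and specificity, in percent
#'   at `digits` decimals (required).
#' @param ppv_pct,npv_pct,accuracy_pct optional further published
#'   percentages.
#' @param n_max cap on each class size (default 71, a typical single-centre
#'   cohort cap; set it to the published cohort size).
#' @param digits decimals the percentages were printed to (default 1).
#' @param rounding `"half_up"` (default) or `"half_even"`; the publication's
#'   rounding rule is rarely stated, so both are available.
#' @return list of class `"reconstruction_result"`: `candidates` (data frame
#'   with columns tp, fn, fp, tn, n) and `is_unique_minimal`.
#' @export
reconstruct <- function(sen_pct, spe_pct, ppv_pct = NULL, npv_pct = NULL,
                        accuracy_pct = NULL, n_max = 71, digits = 1,
                        rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  pcts <- c(sen_pct, spe_pct, ppv_pct, npv_pct, accuracy_pct)
  if (any(pcts < 0 | pcts > 100)) stop("percentages must lie in [0, 100]")
  if (n_max < 2) stop("n_max must be >= 2")

  # All (k, n) with k successes out of n printing as the target percentage.
  matching_pairs <- function(target_pct) {
    grid <- expand.grid(n = 1:n_max, k = 0:n_max)
    grid <- grid[grid$k <= grid$n, ]
    grid[matches_rounded(100 * grid$k / grid$n, target_pct, digits, rounding), ]
  }
  pos <- matching_pairs(sen_pct)   # k = tp, n = tp + fn
  neg <- matching_pairs(spe_pct)   # k = tn, n = tn + fp
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    return(structure(list(candidates = data.frame(tp = integer(), fn = integer(),
                                                  fp = integer(), tn = integer(),
                                                  n = integer()),
                          is_unique_minimal = FALSE),
                     class = "reconstruction_result"))
  }
  cand <- merge(data.frame(tp = pos$k, fn = pos$n - pos$k),
                data.frame(tn = neg$k, fp = neg$n - neg$k))
  cand$n <- cand$tp + cand$fn + cand$fp + cand$tn
  keep <- rep(TRUE, nrow(cand))
  if (!is.null(ppv_pct)) {
    denom <- cand$tp + cand$fp
    keep <- keep & denom > 0 &
      matches_rounded(100 * cand$tp / pmax(denom, 1), ppv_pct, digits, rounding)
  }
  if (!is.null(npv_pct)) {
    denom <- cand$tn + cand$fn
    keep <- keep & denom > 0 &
      matches_rounded(100 * cand$tn / pmax(denom, 1), npv_pct, digits, rounding)
  }
  if (!is.null(accuracy_pct)) {
    keep <- keep & matches_rounded(100 * (cand$tp + cand$tn) / cand$n,
                                   accuracy_pct, digits, rounding)
  }
  cand <- cand[keep, c("tp", "fn", "fp", "tn", "n")]
  cand <- cand[order(cand$n, cand$tp, cand$tn), ]
  rownames(cand) <- NULL
  minimal_n <- if (nrow(cand) > 0L) cand$n[1L] else NA_integer_
  structure(list(candidates = cand,
                 is_unique_minimal = nrow(cand) > 0L && sum(cand$n == minimal_n) == 1L),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("%d candidate table(s); minimal table %s\n", nrow(x$candidates),
              if (x$is_unique_minimal) "is unique" else "is not unique"))
  print(utils::head(x$candidates, 10))
  invisible(x)
}

#' Check a confusion matrix against published confidence intervals
#'
#' Recomputes the full diagnostic report for `cm` and compares every
#' supplied interval, after display rounding, with the published bounds:
#' proportions in percent at 1 decimal, likelihood ratios at 2 decimals.
#' A `TRUE` result means the reconstruction and the interval methods
#' (Wilson for proportions, Simel log method for likelihood ratios) are
#' simultaneously consistent with the publication.
#'
#' @param cm a [confusion_matrix()].
#' @param printed named list of intervals, each `c(lower, upper)`; allowed
#'   names: `ci_sen`, `ci_spe`, `ci_ppv`, `ci_npv` (percent) and
#'   `ci_lr_pos`, `ci_lr_neg` (ratio scale).
#' @param conf_level confidence level of the published intervals.
#' @param rounding `"half_up"` or `"half_even"`.
#' @return `TRUE` iff every supplied interval is reproduced.
#' @export
verify_against_cis <- function(cm, printed, conf_level = 0.95,
                               rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  report <- diagnostic_report(cm, conf_level = conf_level)
  spec <- list(ci_sen = list(scale = 100, digits = 1),
               ci_spe = list(scale = 100, digits = 1),
               ci_ppv = list(scale = 100, digits = 1),
               ci_npv = list(scale = 100, digits = 1),
               ci_lr_pos = list(scale = 1, digits = 2),
               ci_lr_neg = list(scale = 1, digits = 2))
  unknown <- setdiff(names(printed), names(spec))
  if (length(unknown) > 0L) stop("unknown interval name(s): ",
                                 paste(unknown, collapse = ", "))
  for (name in names(printed)) {
    s <- spec[[name]]
    computed <- report[[name]] * s$scale
    ok <- all(is.finite(computed)) &&
      all(mapply(matches_rounded, computed, printed[[name]],
                 MoreArgs = list(digits = s$digits, rounding = rounding)))
    if (!ok) return(FALSE)
  }
  TRUE
}
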