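group_comparison <- function(variable, method, statistic, p_value,
                             group_summaries, mean_diff = NULL,
                             mean_diff_ci = NULL) {
  structure(list(variable = variable, method = method,
                 statistic = unname(statistic), p_value = unname(p_value),
                 mean_diff = mean_diff, mean_diff_ci = mean_diff_ci,
                 group_summaries = group_summaries),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %s, p = %.4g\n", x$variable, x$method,
              format(x$statistic, digits = 4), x$p_value))
  if (!is.null(x$mean_diff)) {
    cat(sprintf("  mean difference %.4g (95%% CI %.4g to %.4g)\n",
                x$mean_diff, x$mean_diff_ci[1], x$mean_diff_ci[2]))
  }
  invisible(x)
}

#' Pooled-variance two-sample t-test between metastasis groups
#'
#' Complete-case Student t-test with pooled variance. The mean difference is
#' oriented as nonmetastatic minus metastatic, so that a marker depressed in
#' metastatic disease (e.g. prealbumin) yields a positive difference, the
#' orientation used in published group-comparison tables.
#'
#' @param values numeric biomarker per patient.
#' @param metastatic logical group label per patient.
#' @param variable name for reporting.
#' @param pooled use the pooled-variance (Student) test; `FALSE` gives
#'   Welch.
#' @return a `"group_comparison"` with `mean_diff` and its 95% CI.
#' @export
compare_means <- function(values, metastatic, variable = "value", pooled = TRUE) {
  keep <- !is.na(values) & !is.na(metastatic)
  x <- values[keep & !metastatic]   # nonmetastatic first: diff = nonmet - met
  y <- values[keep & metastatic]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 complete cases per group")
  fit <- stats::t.test(x, y, var.equal = pooled, conf.level = 0.95)
  summaries <- list(
    metastatic = list(n = length(y), mean = mean(y), sd = stats::sd(y)),
    nonmetastatic = list(n = length(x), mean = mean(x), sd = stats::sd(x))
  )
  group_comparison(variable, if (pooled) "t_test" else "welch_t_test",
                   fit$statistic, fit$p.value, summaries,
                   mean_diff = unname(diff(rev(fit$estimate))),
                   mean_diff_ci = as.numeric(fit$conf.int))
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison between metastasis groups
#'
#' Two-sided rank-sum test on complete cases; reports group medians and
#' quartiles, the summaries appropriate for skewed markers such as CRP.
#'
#' @inheritParams compare_means
#' @return a `"group_comparison"`.
#' @export
compare_distributions <- function(values, metastatic, variable = "value") {
  keep <- !is.na(values) & !is.na(metastatic)
  x <- values[keep & !metastatic]
  y <- values[keep & metastatic]
  if (length(x) < 1L || length(y) < 1L) stop("need complete cases in both groups")
  fit <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  q <- function(v) list(n = length(v), median = stats::median(v),
                        q25 = unname(stats::quantile(v, 0.25)),
                        q75 = unname(stats::quantile(v, 0.75)))
  group_comparison(variable, "mann_whitney", fit$statistic, fit$p.value,
                   list(metastatic = q(y), nonmetastatic = q(x)))
}

# Pearson chi-square statistic of an observed table.
pearson_statistic <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# Exact conditional p-value: enumerate every table with the observed
# margins, weight by the multivariate hypergeometric probability, and sum
# the probability of tables whose Pearson statistic is at least the
# observed one. Enumeration is over the (r-1)(c-1) free cells and is
# feasible for the small contingency tables of clinical score comparisons;
# beyond `max_tables` a margins-preserving Monte Carlo (r2dtable) is used.
exact_chisq_p <- function(tab, max_tables = 2e6, mc_draws = 1e5) {
  r_margins <- rowSums(tab)
  c_margins <- colSums(tab)
  nr <- length(r_margins)
  nc <- length(c_margins)
  # enumeration visits at most prod over free rows of weak compositions
  n_tables_bound <- prod(choose(r_margins[-nr] + nc - 1, nc - 1))
  observed <- pearson_statistic(tab)
  if (n_tables_bound > max_tables) {
    sims <- stats::r2dtable(mc_draws, r_margins, c_margins)
    stats <- vapply(sims, pearson_statistic, numeric(1))
    return(mean(stats >= observed - 1e-9))
  }
  log_const <- sum(lgamma(r_margins + 1)) + sum(lgamma(c_margins + 1)) -
    lgamma(sum(tab) + 1)
  p_total <- 0
  recurse <- function(filled, row, col_left) {
    if (row > nr) {
      t_full <- matrix(unlist(filled), nr, nc, byrow = TRUE)
      if (pearson_statistic(t_full) >= observed - 1e-9) {
        p_total <<- p_total + exp(log_const - sum(lgamma(t_full + 1)))
      }
      return(invisible())
    }
    if (row == nr) {
      if (all(col_left >= 0)) recurse(c(filled, list(col_left)), nr + 1L, col_left * 0L)
      return(invisible())
    }
    # enumerate compositions of this row's margin bounded by column slack
    row_cells <- integer(nc)
    fill_cell <- function(j, remaining) {
      if (j == nc) {
        if (remaining <= col_left[nc]) {
          row_cells[nc] <<- remaining
          recurse(c(filled, list(row_cells)), row + 1L, col_left - row_cells)
        }
        return(invisible())
      }
      for (v in 0:min(remaining, col_left[j])) {
        row_cells[j] <<- v
        fill_cell(j + 1L, remaining - v)
      }
    }
    fill_cell(1L, r_margins[row])
    invisible()
  }
  recurse(list(), 1L, c_margins)
  min(p_total, 1)
}

#' Chi-square association test for a contingency table
#'
#' Pearson chi-square statistic; the p-value is either the exact conditional
#' tail probability (all tables with the observed margins whose Pearson
#' statistic is at least the observed one, weighted hypergeometrically —
#' the "exact chi-square" of standard statistical packages) or the
#' asymptotic chi-square approximation.
#'
#' @param tab non-negative integer matrix with at least 2 rows and columns.
#' @param exact compute the exact conditional p-value (default `TRUE`).
#' @param variable name for reporting.
#' @return a `"group_comparison"`.
#' @export
compare_categorical <- function(tab, exact = TRUE, variable = "table") {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin")
  statistic <- pearson_statistic(tab)
  p <- if (exact) {
    exact_chisq_p(tab)
  } else {
    stats::pchisq(statistic, df = (nrow(tab) - 1) * (ncol(tab) - 1),
                  lower.tail = FALSE)
  }
  col_pct <- sweep(tab, 2, colSums(tab), "/") * 100
  group_comparison(variable, if (exact) "chi_square_exact" else "chi_square",
                   statistic, p, list(counts = tab, column_percent = col_pct))
}

#' Kruskal-Wallis test of a numeric variable across group levels
#'
#' Standard H statistic with tie correction, for associating an ordinal or
#' continuous measure (e.g. the scored PG-SGA) with a categorical score.
#'
#' @param values numeric per patient.
#' @param groups factor-like group labels (>= 2 levels after dropping
#'   incomplete cases).
#' @param variable name for reporting.
#' @return a `"group_comparison"`.
#' @export
kruskal_wallis <- function(values, groups, variable = "value") {
  keep <- !is.na(values) & !is.na(groups)
  v <- values[keep]
  g <- factor(groups[keep])
  if (nlevels(g) < 2L) stop("need >= 2 group levels")
  fit <- stats::kruskal.test(v, g)
  med <- tapply(v, g, stats::median)
  group_comparison(variable, "kruskal_wallis", fit$statistic, fit$p.value,
                   list(medians = as.list(med),
                        n = as.list(as.integer(table(g)))))
}
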