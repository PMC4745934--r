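test_that("confusion_from_predictions counts the four cells", {
  perfect <- confusion_from_predictions(rep(c(TRUE, FALSE), c(5, 5)),
                                        rep(c(TRUE, FALSE), c(5, 5)))
  expect_equal(unclass(perfect)[c("tp", "fn", "fp", "tn")],
               list(tp = 5L, fn = 0L, fp = 0L, tn = 5L))
  always <- confusion_from_predictions(rep(TRUE, 5), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(c(always$tp, always$fn, always$fp, always$tn), c(3, 0, 2, 0))
  truth <- c(TRUE, FALSE, NA, TRUE)
  self <- confusion_from_predictions(truth, truth)  # NA pair dropped
  expect_equal(c(self$fn, self$fp), c(0, 0))
  expect_equal(self$tp + self$tn, 3)
  expect_error(confusion_from_predictions(NA, TRUE), "no complete cases")
})

test_that("diagnostic report reproduces the published ROC-table row", {
  rep4 <- diagnostic_report(confusion_matrix(27, 8, 11, 12))
  expect_equal(round_half_up(100 * rep4$sen, 1), 77.1)
  expect_equal(round_half_up(100 * rep4$spe, 1), 52.2)
  expect_equal(round_half_up(100 * rep4$ppv, 1), 71.1)
  expect_equal(round_half_up(100 * rep4$npv, 1), 60.0)
  expect_equal(round_half_up(rep4$lr_pos, 2), 1.61)
  expect_equal(round_half_up(rep4$lr_neg, 2), 0.44)
  # Wilson intervals, percent, one decimal
  expect_equal(round_half_up(100 * rep4$ci_sen, 1), c(lower = 61.0, upper = 87.9))
  expect_equal(round_half_up(100 * rep4$ci_spe, 1), c(lower = 33.0, upper = 70.8))
  expect_equal(round_half_up(100 * rep4$ci_ppv, 1), c(lower = 55.2, upper = 83.0))
  expect_equal(round_half_up(100 * rep4$ci_npv, 1), c(lower = 38.7, upper = 78.1))
  # Simel log-method intervals, two decimals
  expect_equal(round_half_up(rep4$ci_lr_pos, 2), c(lower = 1.01, upper = 2.56))
  expect_equal(round_half_up(rep4$ci_lr_neg, 2), c(lower = 0.21, upper = 0.90))
})

test_that("diagnostic report reproduces the published stump metrics", {
  rep3 <- diagnostic_report(confusion_matrix(13, 4, 4, 7))
  expect_equal(round_half_up(100 * rep3$sen, 1), 76.5)
  expect_equal(round_half_up(100 * rep3$spe, 1), 63.6)
  expect_equal(round_half_up(100 * rep3$accuracy, 1), 71.4)
})

test_that("diagnostic metrics satisfy their structural identities", {
  set.seed(401)
  for (i in 1:25) {
    cm <- confusion_matrix(sample(1:40, 1), sample(0:40, 1),
                           sample(0:40, 1), sample(1:40, 1))
    r <- diagnostic_report(cm)
    # sen*(tp+fn) and spe*(tn+fp) recover the integer cells
    expect_equal(r$sen * r$n_pos, cm$tp)
    expect_equal(r$spe * r$n_neg, cm$tn)
    # accuracy is the prevalence-weighted average of sen and spe
    expect_equal(r$accuracy, (r$sen * r$n_pos + r$spe * r$n_neg) / r$n)
    expect_equal(r$youden_j, r$sen + r$spe - 1)
    # J > 0 <=> LR+ > 1 <=> LR- < 1, when the LRs are defined
    if (is.finite(r$lr_pos) && is.finite(r$lr_neg) && r$lr_neg > 0) {
      expect_equal(r$youden_j > 0, r$lr_pos > 1)
      expect_equal(r$youden_j > 0, r$lr_neg < 1)
    }
    # every CI contains its point estimate
    expect_true(r$ci_sen[1] <= r$sen && r$sen <= r$ci_sen[2])
    expect_true(r$ci_spe[1] <= r$spe && r$spe <= r$ci_spe[2])
  }
  perfect <- diagnostic_report(confusion_matrix(7, 0, 0, 7))
  expect_equal(c(perfect$sen, perfect$spe, perfect$ppv, perfect$npv,
                 perfect$accuracy, perfect$youden_j), rep(1, 6))
  expect_true(is.infinite(perfect$lr_pos))
  expect_true(perfect$ci_flagged)
})

test_that("Wilson interval stays in [0,1], brackets p-hat, hits 0 at k=0", {
  for (n in c(1, 5, 35, 200)) {
    for (k in unique(c(0, 1, floor(n / 2), n))) {
      ci <- wilson_ci(k, n)
      expect_true(ci[1] >= 0 && ci[2] <= 1)
      expect_true(ci[1] <= k / n && k / n <= ci[2])
    }
    expect_equal(unname(wilson_ci(0, n)[1]), 0)
  }
})

test_that("ROC AUC equals the pairwise rank-sum oracle, with ties", {
  set.seed(402)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth) || all(truth)) next
    # coarse rounding forces ties across and within classes
    values <- round(rnorm(n, mean = ifelse(truth, -0.5, 0.5)), 1)
    dir <- sample(c("lower_is_positive", "higher_is_positive"), 1)
    curve <- roc_curve(values, truth, direction = dir)
    expect_equal(curve$auc, oracle_auc_pairwise(values, truth, dir),
                 tolerance = 1e-12)
  }
})

test_that("ROC endpoints, separation, and monotone-transform invariance hold", {
  truth <- rep(c(TRUE, FALSE), each = 6)
  values <- c(rnorm(6, 0, 0.1), rnorm(6, 10, 0.1))
  curve <- roc_curve(values, truth, "lower_is_positive")
  expect_equal(curve$auc, 1)
  expect_equal(c(curve$fpr[1], curve$sen[1]), c(0, 0))
  expect_equal(c(tail(curve$fpr, 1), tail(curve$sen, 1)), c(1, 1))
  expect_true(all(diff(curve$sen) >= 0) && all(diff(curve$fpr) >= 0))

  set.seed(403)
  v <- rlnorm(40)
  t2 <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
  a1 <- roc_curve(v, t2, "lower_is_positive")$auc
  a2 <- roc_curve(log(v), t2, "lower_is_positive")$auc  # strictly monotone map
  expect_equal(a1, a2, tolerance = 1e-12)

  expect_error(roc_curve(v, rep(TRUE, 40)), "each class")
})

test_that("ROC AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(404)
  values <- c(rnorm(30, 0.14, 0.06), rnorm(25, 0.20, 0.10))
  truth <- rep(c(TRUE, FALSE), c(30, 25))
  ours <- roc_curve(values, truth, "lower_is_positive")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = values,
                                        direction = ">", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Hanley-McNeil interval reproduces the published AUC interval", {
  ci <- hanley_mcneil_ci(0.68, 35, 23)
  expect_equal(round_half_up(ci, 2), c(lower = 0.54, upper = 0.82))
  # symmetry at AUC = 0.5 and variance monotonicity in n
  ci5 <- hanley_mcneil_ci(0.5, 20, 20)
  expect_equal(unname(ci5[1] + ci5[2]), 1, tolerance = 1e-12)
  widths <- sapply(c(10, 20, 40, 80), function(n) diff(hanley_mcneil_ci(0.7, n, n)))
  expect_true(all(diff(widths) < 0))
  expect_error(hanley_mcneil_ci(0.7, 1, 10), "n_pos")
})

test_that("Youden cut-off agrees with an exhaustive scan on random instances", {
  set.seed(405)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    values <- round(rnorm(n, ifelse(truth, 0, 1), 1), 1)
    curve <- roc_curve(values, truth, "lower_is_positive")
    got <- youden_cutoff(curve)
    want <- oracle_youden_scan(values, truth, "lower_is_positive")
    expect_equal(got$youden_j, want$j, tolerance = 1e-12)
    expect_equal(got$sen, want$sen, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("Youden cut-off on separated groups picks J = 1 deterministically", {
  values <- c(1, 2, 3, 10, 11, 12)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cut <- youden_cutoff(roc_curve(values, truth, "lower_is_positive"))
  expect_equal(cut$youden_j, 1)
  # tie-break: equal J and sen across (3, 10]; lowest threshold wins
  expect_equal(cut$threshold, 10)
})

test_that("Gini stump matches exhaustive enumeration and finds the published grouping", {
  set.seed(406)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    score <- sample(0:3, n, replace = TRUE)
    if (length(unique(score)) < 2) next
    truth <- runif(n) < (0.2 + 0.2 * score)
    got <- stump_split(score, truth)
    want <- oracle_stump(score, truth)
    expect_equal(got$gini, want$gini, tolerance = 1e-12)
    expect_equal(got$split_point, want$split_point)
  }

  # a PCPS-like distribution (high score enriched in metastatic disease)
  # must split the levels as {0,1} vs {2}
  set.seed(407)
  pcps <- c(sample(0:2, 430, TRUE, prob = c(0.09, 0.15, 0.76)),
            sample(0:2, 280, TRUE, prob = c(0.27, 0.37, 0.36)))
  met <- rep(c(TRUE, FALSE), c(430, 280))
  split <- stump_split(pcps, met)
  expect_equal(split$split_point, 1)

  # perfectly predictive binary score: zero impurity
  perfect <- stump_split(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(perfect$gini, 0)
  expect_equal(c(perfect$cm$fn, perfect$cm$fp), c(0, 0))

  expect_error(stump_split(rep(1, 5), rep(TRUE, 5)), "distinct")
})
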