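# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementations they check.

# AUC as the pairwise rank statistic: fraction of (positive, negative) pairs
# where the positive case is on the positive side, ties counted one half.
oracle_auc_pairwise <- function(values, truth, direction = "lower_is_positive") {
  pos <- values[truth]
  neg <- values[!truth]
  cmp <- outer(pos, neg, function(p, q) {
    if (direction == "lower_is_positive") (p < q) + 0.5 * (p == q)
    else (p > q) + 0.5 * (p == q)
  })
  mean(cmp)
}

# Exhaustive Youden scan: evaluate J at every candidate threshold directly
# from the definition of the classification rule.
oracle_youden_scan <- function(values, truth, direction = "lower_is_positive") {
  thresholds <- if (direction == "lower_is_positive") {
    c(sort(unique(values)), Inf)
  } else {
    c(-Inf, sort(unique(values)))
  }
  best <- list(j = -Inf, sen = -Inf, threshold = Inf)
  for (t in thresholds) {
    pred <- if (direction == "lower_is_positive") values < t else values > t
    sen <- sum(pred & truth) / sum(truth)
    spe <- sum(!pred & !truth) / sum(!truth)
    j <- sen + spe - 1
    better <- (j > best$j + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && sen > best$sen + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && abs(sen - best$sen) <= 1e-12 && t < best$threshold)
    if (better) best <- list(j = j, sen = sen, spe = spe, threshold = t)
  }
  best
}

# Direct Gini evaluation of every ordinal split.
oracle_stump <- function(score, truth) {
  levels <- sort(unique(score))
  n <- length(score)
  gini <- function(y) if (length(y) == 0) 0 else {
    p <- mean(y); 1 - p^2 - (1 - p)^2
  }
  res <- sapply(head(levels, -1), function(cut) {
    l <- score <= cut
    (sum(l) * gini(truth[l]) + sum(!l) * gini(truth[!l])) / n
  })
  list(split_point = head(levels, -1)[which.min(res)], gini = min(res))
}

# Kruskal-Wallis H from its definitional rank formula with tie correction.
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  groups <- factor(groups)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# A tiny fully-specified valid cohort for plumbing tests.
make_test_cohort_df <- function(n = 4) {
  data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    age = seq(45, 45 + 5 * (n - 1), by = 5),
    sex = rep(c("male", "female"), length.out = n),
    anatomic_site = rep(c("GEJ_proximal", "distal"), length.out = n),
    stage = rep(c(4L, 3L), length.out = n),
    metastatic = rep(c(TRUE, FALSE), length.out = n),
    bmi = rep(21.5, n),
    albumin = rep(3.8, n),
    prealbumin = seq(0.10, by = 0.04, length.out = n),
    transferrin = rep(250, n),
    crp = seq(5, by = 10, length.out = n),
    tlc = rep(1.2, n),
    pgsga_score = rep(12L, n),
    pgsga_category = rep(c("B", "C"), length.out = n),
    stringsAsFactors = FALSE
  )
}
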