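test_that("log-normal fit reproduces its median and quartiles in closed form", {
  # standard log-normal
  z75 <- qnorm(0.75)
  fit <- fit_lognormal_from_quartiles(1, exp(-z75), exp(z75))
  expect_equal(fit$mu, 0, tolerance = 1e-12)
  expect_equal(fit$sigma, 1, tolerance = 1e-12)

  # published CRP summaries, both groups: the fit preserves the median and
  # the interquartile ratio exactly (a two-parameter family cannot hit three
  # free quantiles; printed quartiles are slightly asymmetric on the log
  # scale, so each quartile is recovered up to that asymmetry)
  for (row in list(c(37.60, 15.59, 85.16), c(15.61, 5.52, 30.01))) {
    fit <- fit_lognormal_from_quartiles(row[1], row[2], row[3])
    expect_equal(qlnorm(0.5, fit$mu, fit$sigma), row[1], tolerance = 1e-10)
    expect_equal(qlnorm(0.75, fit$mu, fit$sigma) / qlnorm(0.25, fit$mu, fit$sigma),
                 row[3] / row[2], tolerance = 1e-10)
  }

  # frozen values from the closed form applied to the metastatic CRP row
  fit <- fit_lognormal_from_quartiles(37.60, 15.59, 85.16)
  expect_equal(fit$mu, 3.627004, tolerance = 1e-6)
  expect_equal(fit$sigma, 1.258657, tolerance = 1e-6)

  expect_error(fit_lognormal_from_quartiles(1, 2, 3), "q25 < median")
  expect_error(fit_lognormal_from_quartiles(1, -1, 3), "positive")
})

test_that("simulated cohorts match the configured cohort structure", {
  cfg <- default_synthetic_config(seed = 42)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 71)
  expect_equal(sum(co$metastatic), 43)
  expect_equal(sum(co$stage == 3L), 28)
  expect_true(all(co$pgsga_category %in% c("A", "B", "C")))
  expect_true(all(co$prealbumin > 0, na.rm = TRUE))
})

test_that("simulation is seed-deterministic, byte-identical on disk", {
  cfg <- default_synthetic_config(seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, fa)
  write_cohort(b, fb)
  expect_identical(readLines(fa), readLines(fb))

  c2 <- simulate_cohort(default_synthetic_config(seed = 10))
  expect_false(identical(a$prealbumin, c2$prealbumin))
})

test_that("a degenerate group size of zero yields a single-group cohort", {
  cfg <- default_synthetic_config(seed = 3)
  cfg$metastatic$n <- 0L
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 28)
  expect_true(all(!co$metastatic))
})

test_that("generator recovers its configured parameters at large n", {
  cfg <- default_synthetic_config(seed = 2024)
  cfg$metastatic$n <- 10000L
  cfg$nonmetastatic$n <- 10000L
  co <- simulate_cohort(cfg)
  s <- summarize_cohort(co)
  get <- function(v, g, col) s[s$variable == v & s$group == g, col]

  # Gaussian markers: compare against the zero-truncated normal moments
  # (the generative law), computed in closed form as the oracle
  trunc_moments <- function(mu, sd) {
    a <- -mu / sd                      # standardized truncation point
    lambda <- dnorm(a) / (1 - pnorm(a))
    m <- mu + sd * lambda
    v <- sd^2 * (1 + a * lambda - lambda^2)
    list(mean = m, sd = sqrt(v))
  }
  checks <- list(
    c("prealbumin", "metastatic", 0.14, 0.06),
    c("prealbumin", "nonmetastatic", 0.20, 0.10),
    c("albumin", "metastatic", 3.57, 0.74),
    c("transferrin", "nonmetastatic", 279.07, 135.75),
    c("tlc", "metastatic", 1.18, 0.49)
  )
  for (ck in checks) {
    tm <- trunc_moments(as.numeric(ck[3]), as.numeric(ck[4]))
    n_eff <- get(ck[1], ck[2], "n")
    expect_lt(abs(get(ck[1], ck[2], "mean") - tm$mean), 4 * tm$sd / sqrt(n_eff))
    expect_lt(abs(get(ck[1], ck[2], "sd") - tm$sd), 4 * tm$sd / sqrt(2 * n_eff))
    # truncation shifts these parameter sets by well under one SD
    expect_lt(abs(tm$mean - as.numeric(ck[3])), 0.1 * as.numeric(ck[4]))
  }

  # log-normal CRP: the sample median converges to the configured median,
  # the sample quartiles to the fitted distribution's quartiles; at this n
  # the relative Monte-Carlo SE of a lognormal quantile with sigma ~1.26 is
  # ~2%, so the band is set at ~4 SEs
  fit_m <- fit_lognormal_from_quartiles(37.60, 15.59, 85.16)
  expect_lt(abs(get("crp", "metastatic", "median") / 37.60 - 1), 0.08)
  expect_lt(abs(get("crp", "metastatic", "q25") /
                  qlnorm(0.25, fit_m$mu, fit_m$sigma) - 1), 0.08)
  expect_lt(abs(get("crp", "metastatic", "q75") /
                  qlnorm(0.75, fit_m$mu, fit_m$sigma) - 1), 0.08)
  expect_lt(abs(get("crp", "nonmetastatic", "median") / 15.61 - 1), 0.08)

  # missingness rate converges on the serum biomarkers
  miss <- mean(is.na(co$prealbumin))
  expect_lt(abs(miss - 0.18), 3 * sqrt(0.18 * 0.82 / nrow(co)))
})

test_that("cohort summaries handle degenerate groups", {
  df <- make_test_cohort_df(2)[1, ]  # single metastatic patient
  co <- as_cohort(df)
  s <- summarize_cohort(co)
  row <- s[s$variable == "prealbumin" & s$group == "metastatic", ]
  expect_equal(row$mean, df$prealbumin)
  expect_true(is.na(row$sd))
  empty <- s[s$variable == "crp" & s$group == "nonmetastatic", ]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean))

  df2 <- make_test_cohort_df(4)
  df2$crp <- NA_real_
  s2 <- summarize_cohort(as_cohort(df2))
  expect_true(all(is.na(s2[s2$variable == "crp", "mean"])))
})

test_that("config files override defaults and are validated", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("biomarker_missing_rate: 0.0", "seed: 5",
               "metastatic:", "  n: 10"), path)
  cfg <- read_synthetic_config(path)
  expect_equal(cfg$biomarker_missing_rate, 0)
  expect_equal(cfg$metastatic$n, 10)
  expect_equal(cfg$metastatic$prealbumin_mean, 0.14)  # untouched default
  co <- simulate_cohort(cfg)
  expect_false(anyNA(co$prealbumin))

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("biomarker_missing_rate: 1.5", bad)
  expect_error(read_synthetic_config(bad), "proportions")
})
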