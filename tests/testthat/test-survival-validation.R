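test_that("Kaplan-Meier estimates match the product-limit construction", {
  # all censored: the curve never steps down
  km0 <- km_estimate(data.frame(time = c(3, 7, 9), event = c(0, 0, 0)))
  expect_true(all(km0$estimate == 1))

  # single subject with an event at t = 5
  km1 <- km_estimate(data.frame(time = 5, event = 1))
  expect_equal(km1$estimate[km1$time == 5], 0)

  # 5 subjects: events at 1, 3, 4; censored at 2, 5
  co <- data.frame(time = 1:5, event = c(1, 0, 1, 1, 0))
  km <- km_estimate(co)
  oracle <- km_oracle(co$time, co$event)
  got <- km$estimate[match(oracle$time, km$time)]
  expect_equal(got, oracle$estimate, tolerance = 1e-12)
  expect_equal(oracle$estimate, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))

  # invariance to subject ordering
  perm <- co[c(4, 1, 5, 3, 2), ]
  expect_equal(km_estimate(perm), km)

  expect_error(km_estimate(data.frame(time = numeric(), event = numeric())),
               "non-empty")
})

test_that("log-rank test is symmetric, handles the single-event case, and matches brute force", {
  A <- data.frame(time = c(10, 20, 30), event = c(1, 0, 1))
  expect_equal(logrank_test(A, A)$chi_square, 0, tolerance = 1e-12)
  expect_equal(logrank_test(A, A)$p_value, 1, tolerance = 1e-12)

  B <- data.frame(time = c(15, 25), event = c(0, 1))
  ab <- logrank_test(A, B)
  ba <- logrank_test(B, A)
  expect_equal(ab$chi_square, ba$chi_square, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

  # one event total: closed-form single-risk-set statistic
  A1 <- data.frame(time = c(5, 9), event = c(1, 0))
  B1 <- data.frame(time = c(7, 11, 13), event = c(0, 0, 0))
  # at t = 5: n1 = 2, n2 = 3, d = 1 -> O - E = 1 - 2/5, V = (2*3)/25
  chi_closed <- (1 - 2 / 5)^2 / (6 / 25)
  expect_equal(logrank_test(A1, B1)$chi_square, chi_closed, tolerance = 1e-10)

  expect_error(logrank_test(A, data.frame(time = numeric(),
                                          event = numeric())), "non-empty")
  expect_error(logrank_test(data.frame(time = 1, event = 0),
                            data.frame(time = 2, event = 0)),
               "at least one event")
})

test_that("log-rank chi-square agrees with the brute-force oracle on random small cohorts", {
  set.seed(13)
  for (i in 1:100) {
    pair <- random_cohort_pair(n_max = 12L)
    got <- logrank_test(pair$A, pair$B)
    expect_equal(got$chi_square, pair$oracle$chi_square, tolerance = 1e-10)
    expect_equal(got$p_value, pair$oracle$p_value, tolerance = 1e-10)
  }
})

test_that("cutpoint scan tests midpoints, honors group-size floors, and adjusts p", {
  # even n with min_group = n/2: only the median split is admissible
  set.seed(14)
  co <- generate_survival(16, hazard_ratio = 3, seed = 14)
  sc <- scan_best_cutpoint(co, min_group = 8)
  expect_identical(sc$n_cutpoints_tested, 1L)
  expect_identical(unname(sc$group_sizes), c(8L, 8L))
  xs <- sort(co$expression)
  expect_equal(sc$best_cutpoint, (xs[8] + xs[9]) / 2)
  expect_gte(sc$p_adjusted, sc$p_raw)

  # separated expression clusters with distinct hazards: the cut falls in the gap
  set.seed(15)
  xlow <- runif(50, 0, 1)
  xhigh <- runif(50, 3, 4)
  co2 <- generate_survival(100, true_cutpoint = 2, hazard_ratio = 10,
                           baseline_hazard = 1 / 300,
                           censoring_horizon = 5000, seed = 15,
                           expression = c(xlow, xhigh))
  sc2 <- scan_best_cutpoint(co2, min_group = 8)
  expect_gt(sc2$best_cutpoint, 1)
  expect_lt(sc2$best_cutpoint, 3)
  expect_lt(sc2$p_adjusted, 0.001)

  expect_error(scan_best_cutpoint(co, min_group = 20), "smaller than")
})

test_that("scanned minimum p equals an exhaustive loop of log-rank tests", {
  set.seed(16)
  co <- generate_survival(30, hazard_ratio = 2, seed = 16)
  sc <- scan_best_cutpoint(co, min_group = 3)
  ux <- sort(unique(co$expression))
  cand <- (ux[-1] + ux[-length(ux)]) / 2
  ps <- c()
  for (cp in cand) {
    lo <- co[co$expression <= cp, ]
    hi <- co[co$expression > cp, ]
    if (nrow(lo) < 3 || nrow(hi) < 3) next
    ps <- c(ps, logrank_test(lo, hi)$p_value)
  }
  expect_equal(sc$p_raw, min(ps), tolerance = 1e-12)
  expect_identical(sc$n_cutpoints_tested, length(ps))
  expect_true(all(sc$p_raw <= sc$scan$p_value))
})

test_that("the scan recovers a strong true threshold and stays calibrated under the null", {
  # recovery: HR = 4, n = 200; the best cutpoint should fall near the truth
  hits <- 0L
  for (s in 1:50) {
    co <- generate_survival(200, true_cutpoint = 1, hazard_ratio = 4,
                            baseline_hazard = 1 / 400,
                            censoring_horizon = 3000, seed = 3000 + s)
    sc <- scan_best_cutpoint(co, min_group = 8)
    band <- stats::quantile(co$expression, c(0.4, 0.6))
    if (sc$best_cutpoint >= band[1] && sc$best_cutpoint <= band[2])
      hits <- hits + 1L
  }
  expect_gte(hits, 45L)  # >= 90% of seeds

  # null: HR = 1; Bonferroni-adjusted minimum p rejects conservatively
  rejects <- 0L
  n_seeds <- 300L
  for (s in seq_len(n_seeds)) {
    co <- generate_survival(40, true_cutpoint = 1, hazard_ratio = 1,
                            baseline_hazard = 1 / 400,
                            censoring_horizon = 3000, seed = 9000 + s)
    sc <- scan_best_cutpoint(co, min_group = 8)
    if (sc$p_adjusted < 0.05) rejects <- rejects + 1L
  }
  # at most nominal level plus 3-sigma binomial slack
  expect_lte(rejects / n_seeds, 0.05 + 3 * sqrt(0.05 * 0.95 / n_seeds))
})

test_that("survival cohorts round-trip through delimited text", {
  co <- generate_survival(20, seed = 30)
  tf <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(subject_id = co$subject_id,
                                  time_days = co$time, event = co$event,
                                  expression = co$expression), tf)
  back <- read_survival_cohort(tf)
  expect_equal(back$time, co$time)
  expect_identical(as.integer(back$event), co$event)
})

test_that("scan results expose tidy, glance, and Kaplan-Meier plots", {
  co <- generate_survival(40, hazard_ratio = 3, seed = 31)
  sc <- scan_best_cutpoint(co, min_group = 8)
  expect_s3_class(autoplot(sc), "ggplot")
  td <- tidy(sc)
  expect_true(all(c("cutpoint", "chi_square", "p_value") %in% names(td)))
  gl <- glance(sc)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$p_raw, sc$p_raw)
  expect_output(print(sc), "cutpoint_scan")
})
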