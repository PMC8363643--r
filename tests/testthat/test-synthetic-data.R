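test_that("expression generation is deterministic and strictly positive", {
  a <- generate_expression(k_genes = 40, n_per_class = c(4, 5),
                           m_informative = 3, effect_delta = 1.5, seed = 99)
  b <- generate_expression(k_genes = 40, n_per_class = c(4, 5),
                           m_informative = 3, effect_delta = 1.5, seed = 99)
  expect_identical(a, b)
  expect_true(all(a$expression > 0))
  expect_identical(dim(a$expression), c(40L, 9L))
  expect_length(a$truth, 3L)
  expect_true(all(a$truth %in% rownames(a$expression)))
  # serialized form is byte-identical too
  fa <- tempfile(); fb <- tempfile()
  write_expression_matrix(a$expression, fa)
  write_expression_matrix(b$expression, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_error(generate_expression(10, c(3, 3), m_informative = 11),
               "m_informative")
})

test_that("a zero effect yields exchangeable classes at the nominal test level", {
  sim <- generate_expression(k_genes = 500, n_per_class = c(10, 10),
                             m_informative = 0, effect_delta = 0, seed = 123)
  lx <- log(sim$expression)
  cls <- sim$labels$class_index
  p <- apply(lx, 1, function(row) stats::t.test(row[cls == 0],
                                                row[cls == 1])$p.value)
  rate <- mean(p < 0.05)
  # binomial tolerance: 0.05 +/- 3 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("planted genes dominate the observed class-mean differences", {
  hits <- 0L
  for (s in 1:100) {
    sim <- generate_expression(k_genes = 100, n_per_class = c(10, 10),
                               m_informative = 5, effect_delta = 3, seed = s)
    lx <- log(sim$expression)
    cls <- sim$labels$class_index
    d <- abs(rowMeans(lx[, cls == 1]) - rowMeans(lx[, cls == 0]))
    top5 <- names(sort(d, decreasing = TRUE))[1:5]
    if (setequal(top5, sim$truth)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("study-emulation presets reproduce the cohort geometries", {
  t1 <- generate_expression_preset("task1", seed = 1)
  expect_identical(ncol(t1$expression), 12L)
  expect_identical(as.integer(table(t1$labels$class)), c(6L, 6L))
  expect_identical(nrow(t1$expression), 11273L)
  t2 <- generate_expression_preset("task2", seed = 1)
  expect_identical(ncol(t2$expression), 13L)
  expect_identical(as.integer(table(t2$labels$class)), c(6L, 7L))
})

test_that("recovery power grows with effect size and sample size", {
  recovered <- function(delta, n) {
    hits <- 0L
    for (s in 1:30) {
      sim <- generate_expression(k_genes = 80, n_per_class = c(n, n),
                                 m_informative = 4, effect_delta = delta,
                                 seed = 1000 + s)
      lx <- log(sim$expression)
      cls <- sim$labels$class_index
      d <- abs(rowMeans(lx[, cls == 1, drop = FALSE]) -
                 rowMeans(lx[, cls == 0, drop = FALSE]))
      hits <- hits + sum(sim$truth %in% names(sort(d, TRUE))[1:4])
    }
    hits
  }
  expect_lte(recovered(0.5, 5), recovered(2, 5))
  expect_lte(recovered(1, 4), recovered(1, 10))
})

test_that("survival generation respects the threshold hazard model", {
  co <- generate_survival(n_subjects = 300, true_cutpoint = 2,
                          hazard_ratio = 6, baseline_hazard = 1 / 400,
                          censoring_horizon = 3000, seed = 21)
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% c(0L, 1L)))
  hi <- co$expression > 2
  # high-expression subjects die much faster under HR = 6
  expect_lt(stats::median(co$time[hi]), stats::median(co$time[!hi]))

  # a vanishing censoring horizon censors everyone
  co0 <- generate_survival(50, censoring_horizon = 1e-9, seed = 3)
  expect_identical(sum(co0$event), 0L)

  # hazard_ratio = 1: groups around the cutpoint are exchangeable
  con <- generate_survival(n_subjects = 2000, true_cutpoint = 1,
                           hazard_ratio = 1, baseline_hazard = 1 / 400,
                           censoring_horizon = 3000, seed = 22)
  grp_hi <- con[con$expression > 1, ]
  grp_lo <- con[con$expression <= 1, ]
  lr <- logrank_test(grp_lo, grp_hi)
  expect_gt(lr$p_value, 0.01)
  m_lo <- stats::median(grp_lo$time[grp_lo$event == 1])
  m_hi <- stats::median(grp_hi$time[grp_hi$event == 1])
  expect_lt(abs(m_lo - m_hi) / max(m_lo, m_hi), 0.2)
})
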