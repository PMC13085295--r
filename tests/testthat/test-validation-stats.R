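test_that("recovery percentages match the printed worked example", {
  expect_equal(round(recovery_percent(14.98, 15.00), 2), 99.87)
  expect_equal(recovery_percent(7.3, 7.3), 100)
  expect_equal(recovery_percent(0, 10), 0)
  expect_error(recovery_percent(5, 0), "nominal")
})

test_that("recovery summaries reproduce the printed PLS-BUP column", {
  s <- summarize_recoveries(table3_pls_bup_recovery)
  expect_equal(s$mean_percent, 100.33, tolerance = 1e-4)
  expect_equal(s$rsd_percent, 0.83, tolerance = 1e-2)
  expect_equal(s$n_used, 8L)
  # printed ANN-DMA column as a second spot check
  s2 <- summarize_recoveries(table3_ann_dma_recovery)
  expect_equal(s2$mean_percent, 99.79, tolerance = 1e-2)
  expect_equal(s2$rsd_percent, 0.59, tolerance = 1e-2)
  expect_equal(summarize_recoveries(rep(100, 4))$rsd_percent, 0)
})

test_that("the Dixon Q rule flags the printed MCR-ALS DEX outlier", {
  q <- dixon_q_test(table3_mcr_dex_recovery)
  expect_equal(q$q_statistic, (114.44 - 104.44) / (114.44 - 98.87),
               tolerance = 1e-12)
  expect_equal(round(q$q_statistic, 3), 0.642)
  expect_equal(q$q_critical, 0.468)
  expect_equal(q$rejected_value, 114.44)
  # the summary drops it before computing mean/RSD
  s <- summarize_recoveries(table3_mcr_dex_recovery, apply_q = TRUE)
  expect_equal(s$rejected_indices, 1L)
  expect_equal(s$n_used, 7L)
})

test_that("Q statistic agrees with a brute-force gap/range oracle", {
  expect_equal(dixon_q_test(c(1, 2, 3))$q_statistic, 0.5)
  expect_null(dixon_q_test(c(1, 2, 3))$rejected_value)
  expect_error(dixon_q_test(c(1, 2)), "3..10")
  expect_error(dixon_q_test(seq_len(11)), "3..10")
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    v <- round(rnorm(n, 100, 3), 2)
    s <- sort(v)
    q_bf <- max(s[2] - s[1], s[n] - s[n - 1]) / (s[n] - s[1])
    expect_equal(dixon_q_test(v)$q_statistic, q_bf, tolerance = 1e-12)
    # order invariance
    expect_equal(dixon_q_test(rev(v))$q_statistic,
                 dixon_q_test(v)$q_statistic)
  }
  # identical values: q defined as 0, nothing rejected
  expect_null(dixon_q_test(rep(5, 4))$rejected_value)
})

test_that("regression diagnostics match the normal-equation oracle", {
  x <- c(1, 2, 3, 4, 5)
  d0 <- regression_diagnostics(x, x)
  expect_equal(d0$slope, 1); expect_equal(d0$intercept, 0, tolerance = 1e-12)
  expect_equal(d0$r, 1); expect_equal(d0$rmsec, 0)
  d1 <- regression_diagnostics(2 * x + 1, x)
  expect_equal(d1$slope, 2); expect_equal(d1$intercept, 1, tolerance = 1e-12)
  expect_equal(d1$r, 1)
  set.seed(42)
  nom <- runif(10, 2, 25); prd <- nom + rnorm(10, 0, 0.3)
  d2 <- regression_diagnostics(prd, nom)
  X <- cbind(1, nom)
  b <- solve(t(X) %*% X, t(X) %*% prd)
  expect_lt(abs(d2$intercept - b[1]), 1e-10)
  expect_lt(abs(d2$slope - b[2]), 1e-10)
  expect_error(regression_diagnostics(prd, rep(3, 10)), "variance")
})

test_that("the EJCR contains the ideal point for unbiased predictions only", {
  set.seed(43)
  nom <- c(15, 5, 25, 25, 25, 20, 20, 20)
  e1 <- ejcr(nom + rnorm(8, 0, 1e-9), nom)
  expect_true(e1$contains_ideal)
  expect_lt(abs(e1$intercept - 0), 1e-6)
  expect_lt(abs(e1$slope - 1), 1e-6)
  # 10% proportional bias at tiny noise is far outside the region
  e2 <- ejcr(1.1 * nom + rnorm(8, 0, 0.01), nom)
  expect_false(e2$contains_ideal)
  # boundary points satisfy the defining quadratic form
  XtX <- crossprod(cbind(1, nom))
  rhs <- 2 * e2$s2 * e2$f_crit
  qf_vals <- apply(e2$ellipse_boundary, 1, function(b) {
    d <- b - c(e2$intercept, e2$slope)
    t(d) %*% XtX %*% d
  })
  expect_equal(unname(qf_vals), rep(rhs, 360), tolerance = 1e-8)
  expect_error(ejcr(c(1, 2), c(1, 2)), "3 points")
})

test_that("one-sample t against 100% follows the direct formula", {
  sym <- c(101, 101, 101, 99, 99, 99, 101, 99)
  r <- one_sample_t_vs_reference(sym)
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 7L)
  expect_false(r$significant)
  set.seed(44)
  v <- rnorm(8, 100.5, 1)
  r2 <- one_sample_t_vs_reference(v)
  expect_equal(r2$statistic, (mean(v) - 100) / (sd(v) / sqrt(8)))
  expect_error(one_sample_t_vs_reference(rep(100, 5)), "zero")
})

test_that("two-sample comparison uses pooled t and larger-over-smaller F", {
  a <- c(99.5, 100.2, 100.8, 99.9)
  same <- compare_with_official(a, a)
  expect_equal(same$t$statistic, 0)
  expect_equal(same$F$statistic, 1)
  # n1 = 8 vs n2 = 3: t critical 2.262 at df 9
  set.seed(45)
  m8 <- rnorm(8, 100, 1); o3 <- rnorm(3, 100, 1.4)
  cmp <- compare_with_official(m8, o3)
  expect_equal(cmp$t$df, 9L)
  expect_equal(round(cmp$t$critical, 3), 2.262)
  sp2 <- (7 * var(m8) + 2 * var(o3)) / 9
  t_bf <- (mean(m8) - mean(o3)) / sqrt(sp2 * (1 / 8 + 1 / 3))
  expect_equal(cmp$t$statistic, t_bf)
  expect_equal(cmp$F$statistic, max(var(m8), var(o3)) / min(var(m8), var(o3)))
  expect_error(compare_with_official(rep(1, 3), rep(1, 3)), "zero pooled")
})

test_that("critical values reproduce the tabulated t and F entries", {
  expect_equal(round(critical_value("t_two_sided", 0.05, 7), 3), 2.365)
  expect_equal(round(critical_value("t_two_sided", 0.01, 7), 3), 3.499)
  expect_equal(round(critical_value("t_two_sided", 0.05, 9), 3), 2.262)
  expect_equal(round(critical_value("F_upper", 0.05, c(2, 7)), 3), 4.737)
  expect_equal(round(critical_value("F_upper", 0.05, c(2, 6)), 3), 5.143)
  expect_equal(round(critical_value("F_upper", 0.05, c(2, 5)), 3), 5.786)
  # normal limit at huge df
  expect_equal(critical_value("t_two_sided", 0.05, 1e6), 1.960,
               tolerance = 1e-3)
  expect_error(critical_value("t_two_sided", 0.05, 0), "df")
  expect_error(critical_value("F_upper", 0.05, 7), "pair|df = c")
})

test_that("molar masses and the titration equivalence match the pharmacopeia", {
  expect_equal(molar_mass("C"), 12.011)
  expect_equal(round(molar_mass("H2O"), 3), 18.015)
  # dextromethorphan base: 1.0 mL of 0.1 M NaOH = 35.23 mg
  expect_equal(round(titration_equivalent("C18H26BrNO", 0.1, 1.0), 2), 35.23)
  expect_error(molar_mass("C2Xx3"), "unknown element")
})
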