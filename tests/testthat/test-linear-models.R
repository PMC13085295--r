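test_that("PCR at full rank reproduces the OLS oracle", {
  set.seed(11)
  X <- matrix(rnorm(10 * 4), 10, 4)
  Y <- matrix(rnorm(10 * 2), 10, 2)
  m <- fit_pcr(X, Y, n_lv = 4)
  expect_lt(max(abs(predict(m, X) - ols_oracle_predict(X, Y))), 1e-8)
})

test_that("PCR recovers a noiseless linear map exactly at full rank", {
  set.seed(12)
  X <- matrix(rnorm(12 * 5), 12, 5)
  B <- matrix(rnorm(5 * 3), 5, 3)
  Y <- X %*% B
  m <- fit_pcr(X, Y, n_lv = 5)
  expect_lt(max(abs(predict(m, X) - Y)), 1e-8)
  expect_error(fit_pcr(X, Y, n_lv = 7), "rank")
})

test_that("PLS at full rank reproduces the OLS oracle and spans XtY first", {
  set.seed(13)
  X <- matrix(rnorm(12 * 5), 12, 5)
  Y <- matrix(rnorm(12 * 3), 12, 3)
  m <- fit_pls(X, Y, n_lv = 5)
  expect_lt(max(abs(predict(m, X) - ols_oracle_predict(X, Y))), 1e-6)
  # orthonormal single-response toy: first weight vector proportional to X'y
  Q <- qr.Q(qr(matrix(rnorm(20 * 4), 20, 4)))
  y <- matrix(rnorm(20), 20, 1)
  mp <- fit_pls(Q, y, n_lv = 1, center = FALSE)
  xty <- numeric(4)
  for (j in 1:4) for (i in 1:20) xty[j] <- xty[j] + Q[i, j] * y[i]
  w1 <- mp$W[, 1]
  expect_lt(max(abs(w1 - xty / sqrt(sum(xty^2)))), 1e-10)
  expect_error(fit_pls(matrix(1, 5, 3), matrix(rnorm(10), 5, 2), 1),
               "zero-variance")
})

test_that("PCR and PLS match OLS at full rank across random instances", {
  set.seed(14)
  for (trial in 1:50) {
    n <- sample(8:15, 1); p <- sample(3:6, 1); q <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * q), n, q)
    ols <- ols_oracle_predict(X, Y)
    expect_lt(max(abs(predict(fit_pcr(X, Y, p), X) - ols)), 1e-6)
    expect_lt(max(abs(predict(fit_pls(X, Y, p), X) - ols)), 1e-6)
  }
})

test_that("training RMSEC is non-increasing in the latent-variable count", {
  st <- sim_study(noise_spec(sd_frac = 0.005, seed = 7L))
  for (fitter in list(fit_pcr, fit_pls)) {
    rmsec <- sapply(1:8, function(k) {
      m <- fitter(st$Xcal, st$Ycal, k)
      mean(rmse(predict(m, st$Xcal), st$Ycal, "calibration"))
    })
    expect_true(all(diff(rmsec) <= 1e-10))
  }
})

test_that("the study defaults (PCR 6 LV, PLS 5 LV) build with finite RMSEC", {
  st <- sim_study(noise_spec(sd_frac = 0.005, seed = 3L))
  m6 <- fit_pcr(st$Xcal, st$Ycal, 6)
  m5 <- fit_pls(st$Xcal, st$Ycal, 5)
  expect_true(all(is.finite(rmse(predict(m6, st$Xcal), st$Ycal, "calibration"))))
  expect_true(all(is.finite(rmse(predict(m5, st$Xcal), st$Ycal, "calibration"))))
})

test_that("prediction honours centering, permutation, and grid checks", {
  st <- sim_study()
  m <- fit_pcr(st$Xcal, st$Ycal, 4)
  # the calibration mean spectrum predicts the calibration mean concentrations
  mean_spec <- matrix(colMeans(st$Xcal), 1)
  expect_equal(as.vector(predict(m, mean_spec)),
               unname(colMeans(st$Ycal)), tolerance = 1e-10)
  # permuting samples permutes predictions identically
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  expect_equal(unname(predict(m, st$Xval[perm, ])),
               unname(predict(m, st$Xval)[perm, ]))
  expect_error(predict(m, st$Xval[, 1:50]), "match")
  # noiseless validation recovery at 4 LVs is exact
  for (fitter in list(fit_pcr, fit_pls)) {
    mm <- fitter(st$Xcal, st$Ycal, 4)
    expect_lt(max(abs(predict(mm, st$Xval) - st$Yval)), 1e-6)
  }
})

test_that("leave-one-out CV finds the true rank on noiseless data", {
  st <- sim_study()
  sel <- loocv_select_lv(st$Xcal, st$Ycal, max_lv = 6, fit = "PCR")
  expect_equal(sel$chosen_lv, 4L)
  expect_lt(sel$rmsecv[sel$candidate_lvs == 4], 1e-6)
  # brute-force LOOCV loop oracle at 4 LVs
  sse <- 0
  for (i in seq_len(nrow(st$Xcal))) {
    m <- fit_pcr(st$Xcal[-i, ], st$Ycal[-i, ], 4)
    sse <- sse + sum((predict(m, st$Xcal[i, , drop = FALSE]) - st$Ycal[i, ])^2)
  }
  expect_equal(sel$rmsecv[sel$candidate_lvs == 4],
               sqrt(sse / (nrow(st$Xcal) * 4)), tolerance = 1e-12)
  expect_error(loocv_select_lv(st$Xcal, st$Ycal, max_lv = 16), "exceeds")
})

test_that("0-LV RMSECV equals the closed-form leave-one-out mean error", {
  set.seed(15)
  X <- matrix(rnorm(9 * 4), 9, 4)
  Y <- matrix(rnorm(9 * 2), 9, 2)
  sel <- loocv_select_lv(X, Y, max_lv = 2, lvs = 0:2)
  n <- nrow(Y)
  # leaving out i, the mean predictor errs by (n/(n-1)) (y_i - ybar)
  err2 <- sum((n / (n - 1))^2 * sweep(Y, 2, colMeans(Y))^2)
  expect_equal(sel$rmsecv[sel$candidate_lvs == 0], sqrt(err2 / (n * ncol(Y))),
               tolerance = 1e-12)
})

test_that("LOOCV choice is stable under sample duplication on noiseless data", {
  st <- sim_study()
  sel1 <- loocv_select_lv(st$Xcal, st$Ycal, max_lv = 5, fit = "PCR")
  Xd <- rbind(st$Xcal, st$Xcal); Yd <- rbind(st$Ycal, st$Ycal)
  sel2 <- loocv_select_lv(Xd, Yd, max_lv = 5, fit = "PCR")
  expect_equal(sel2$chosen_lv, sel1$chosen_lv)
})

test_that("rmse matches hand arithmetic including the printed worked example", {
  expect_equal(unname(rmse(matrix(1:4), matrix(1:4))), 0, ignore_attr = TRUE)
  expect_equal(unname(rmse(matrix(0.3 + 1), matrix(1))), 0.3,
               ignore_attr = TRUE)
  r <- rmse(matrix(table2_pls_bup_pred), matrix(table2_val_bup_nominal))
  expect_equal(unname(r), 0.15, tolerance = 1e-12, ignore_attr = TRUE)
  # consistent with the printed full-precision 0.1506 given 2-dp inputs
  expect_lt(abs(unname(r) - 0.1506), 0.002)
  expect_error(rmse(matrix(1:2), matrix(1:3)), "shape")
})
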