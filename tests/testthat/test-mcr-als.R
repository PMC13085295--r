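test_that("pure-standard initialization returns the supplied profiles", {
  st <- sim_study()
  S0 <- initialize_profiles(st$Xcal, 4, "pure_standards", st$pure_w)
  expect_equal(unname(S0), unname(st$pure_w$absorptivity))
  expect_error(initialize_profiles(st$Xcal, 4, "pure_standards"), "requires")
})

test_that("purest-row selection finds maximally dissimilar rows", {
  # 4 orthogonal spectra plus mixtures; exhaustive subset oracle
  set.seed(21)
  base <- diag(4) * c(5, 4, 3, 2) # orthogonal rows, row 1 largest norm
  mix <- matrix(runif(6 * 4, 0.2, 1), 6, 4) %*% diag(4)
  D <- rbind(base, mix)[sample(10), ]
  S0 <- initialize_profiles(D, 4, "purest_rows")
  picked <- t(S0)
  gram_det <- function(rows) {
    Rn <- sweep(rows, 1, sqrt(rowSums(rows^2)), "/")
    det(tcrossprod(Rn))
  }
  best <- max(apply(utils::combn(10, 4), 2, function(s) gram_det(D[s, ])))
  expect_equal(gram_det(picked), best, tolerance = 1e-9)
  # k = 1 picks the largest-norm row
  S1 <- initialize_profiles(D, 1, "purest_rows")
  expect_equal(as.vector(S1), D[which.max(rowSums(D^2)), ])
  # rank-deficient data still warns; k beyond the sample count is rejected
  expect_warning(initialize_profiles(rbind(diag(2), diag(2), c(1, 1)), 3,
                                     "purest_rows"), "rank")
  expect_error(suppressWarnings(initialize_profiles(diag(3), 4, "purest_rows")),
               "samples")
})

test_that("horizontal unimodality corrects secondary peaks and is idempotent", {
  expect_equal(apply_unimodality(c(0, 1, 3, 2, 1)), c(0, 1, 3, 2, 1))
  expect_equal(apply_unimodality(c(0, 2, 1, 3, 0)), c(0, 2, 2, 3, 0))
  expect_equal(apply_unimodality(rep(2, 5)), rep(2, 5))
  v <- c(0.1, 0.5, 0.2, 0.9, 0.4, 0.6, 0.1)
  once <- apply_unimodality(v, tol = 1)
  expect_equal(apply_unimodality(once, tol = 1), once)
  # strict correction yields a single mode: monotone up to the max, then down
  expect_equal(which.max(once), which.max(v))
  m <- which.max(once)
  expect_true(all(diff(once[1:m]) >= 0))
  expect_true(all(diff(once[m:length(once)]) <= 0))
})

test_that("the correlation constraint maps profiles onto concentration units", {
  ref <- c(2, 4, 6, 8, 10)
  # already calibrated column passes through unchanged
  cc <- apply_correlation_constraint(c(ref, 5), seq_len(5), ref)
  expect_equal(cc$slope, 1); expect_equal(cc$intercept, 0, tolerance = 1e-12)
  expect_equal(cc$column, c(ref, 5))
  # exact affine distortion is inverted: 2t + 3 maps back to t
  col <- c(2 * ref + 3, 2 * 7 + 3)
  cc2 <- apply_correlation_constraint(col, seq_len(5), ref)
  expect_equal(cc2$column[1:5], ref, tolerance = 1e-12)
  expect_equal(cc2$column[6], 7, tolerance = 1e-12)
  expect_error(apply_correlation_constraint(c(1, 1, 1, 5), 1:3, c(1, 2, 3)),
               "zero-variance")
})

test_that("lack of fit follows the shared-denominator definition", {
  D <- matrix(1, 2, 2)
  C <- matrix(c(1, 1), 2, 1)
  S <- matrix(c(1, 1), 2, 1) # C S' = all ones
  expect_equal(lack_of_fit(D, C, S), list(lof_percent = 0, r2_percent = 100))
  # hand arithmetic: one residual of 1 out of four unit entries
  S2 <- matrix(c(1, 0), 2, 1)
  C2 <- matrix(c(1, 1), 2, 1)
  # C2 S2' = [[1,0],[1,0]]; E has two entries of 1 -> lof 100 sqrt(2/4)
  fom <- lack_of_fit(D, C2, S2)
  expect_equal(fom$lof_percent, 100 * sqrt(2 / 4))
  expect_equal(fom$r2_percent, 100 * (1 - 2 / 4))
  # halving the residual (same D) halves lof exactly
  set.seed(24)
  D3 <- matrix(runif(9), 3, 3)
  P <- matrix(runif(9), 3, 3)
  E3 <- D3 - P
  halfP <- D3 - E3 / 2
  f_full <- lack_of_fit(D3, diag(3), t(P))
  f_half <- lack_of_fit(D3, diag(3), t(halfP))
  expect_equal(f_half$lof_percent, f_full$lof_percent / 2, tolerance = 1e-12)
  expect_error(lack_of_fit(matrix(0, 2, 2), C, S), "all-zero")
})

test_that("ALS resolves noiseless mixtures exactly with ground-truth spectra", {
  st <- sim_study()
  S0 <- initialize_profiles(st$Xcal, 4, "pure_standards", st$pure_w)
  res <- run_mcr_als(st$Xcal, S0, mcr_constraints(correlation = st$Ycal))
  expect_true(res$converged)
  expect_lt(res$lof_percent, 0.1)
  expect_gt(res$r2_percent, 99.99)
  # recovered spectral shapes match the generating profiles
  cs <- diag(crossprod(
    sweep(res$S, 2, sqrt(colSums(res$S^2)), "/"),
    sweep(st$pure_w$absorptivity, 2,
          sqrt(colSums(st$pure_w$absorptivity^2)), "/")))
  expect_true(all(cs >= 0.999))
  # reconstruction identity is exact by construction
  expect_identical(st$Xcal - res$C %*% t(res$S), res$E)
  expect_true(min(res$C) >= -1e-12 && min(res$S) >= -1e-12)
})

test_that("zero-residual input converges at iteration 2 with lof 0", {
  set.seed(22)
  C <- matrix(runif(6 * 2), 6, 2)
  S <- matrix(runif(8 * 2), 8, 2)
  res <- run_mcr_als(C %*% t(S), S, mcr_constraints())
  expect_true(res$converged)
  expect_equal(res$n_iterations, 2L)
  expect_equal(res$lof_percent, 0, tolerance = 1e-10)
  expect_equal(res$r2_percent, 100, tolerance = 1e-10)
})

test_that("rank-1 data is recovered up to scale, fixed by the correlation step", {
  set.seed(23)
  conc <- c(1, 2, 3, 4, 5)
  s <- exp(-((1:40) - 20)^2 / 50)
  D <- outer(conc, s)
  res <- run_mcr_als(D, matrix(s + 0.05 * runif(40), ncol = 1),
                     mcr_constraints(correlation = matrix(conc[1:4]),
                                     calibration_rows = 1:4))
  expect_equal(as.vector(res$C), conc, tolerance = 1e-6)
  expect_gt(abs(stats::cor(as.vector(res$S), s)), 0.99999)
})

test_that("lof is non-increasing under projection constraints", {
  st <- sim_study(noise_spec(sd_frac = 0.005, seed = 9L))
  S0 <- initialize_profiles(st$Xcal, 4, "pure_standards", st$pure_w)
  res <- run_mcr_als(st$Xcal, S0, mcr_constraints(), max_iter = 20,
                     conv_threshold_percent = 1e-8)
  expect_true(all(diff(res$lof_history) <= 1e-9))
  expect_true(min(res$C) >= -1e-12 && min(res$S) >= -1e-12)
  expect_error(run_mcr_als(st$Xcal * NA, S0, mcr_constraints()), "NaN")
})

test_that("one-by-one quantification recovers all validation mixtures", {
  st <- sim_study()
  S0 <- initialize_profiles(st$Xcal, 4, "pure_standards", st$pure_w)
  q <- quantify_test_samples(st$Xcal, st$Xval, st$Ycal, S0)
  expect_lt(max(abs(q$predicted - st$Yval)), 1e-5) # 32 values
  # a duplicated calibration row predicts its own reference
  q2 <- quantify_test_samples(st$Xcal, st$Xcal[3, , drop = FALSE],
                              st$Ycal, S0)
  expect_lt(max(abs(q2$predicted - st$Ycal[3, ])), 1e-5)
  # order permutation leaves per-sample results unchanged
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  qp <- quantify_test_samples(st$Xcal, st$Xval[perm, ], st$Ycal, S0)
  expect_equal(qp$predicted, q$predicted[perm, ])
  expect_error(quantify_test_samples(st$Xcal, st$Xval[, 1:50], st$Ycal, S0),
               "grids")
})
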