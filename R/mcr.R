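#' MCR-ALS constraint set
#'
#' Constraints steer the alternating-least-squares factorization
#' `D = C %*% t(S) + E` toward chemically meaningful profiles and reduce
#' rotational/intensity ambiguity. Non-negativity is solved as constrained
#' least squares (per-row/column NNLS), not by clipping. The correlation
#' constraint adds an inner calibration step: at every iteration the
#' resolved concentration column is regressed onto the known reference
#' concentrations of the calibration rows, and the fitted line is applied
#' to the whole column, putting `C` in real concentration units.
#'
#' @param nonneg_C,nonneg_S Enforce non-negative concentration / spectral
#'   profiles.
#' @param unimodal_C,unimodal_S Enforce unimodality (horizontal correction)
#'   on concentration / spectral profiles.
#' @param unimodal_tol Violation tolerance of the horizontal correction
#'   (1.05 allows 5% violations before correcting).
#' @param correlation Optional reference concentration matrix (calibration
#'   rows x components, ug/mL) for the inner calibration.
#' @param calibration_rows Row indices of `D` the reference rows correspond
#'   to; defaults to the first `nrow(correlation)` rows.
#' @return An `mcr_constraints` object.
#' @export
mcr_constraints <- function(nonneg_C = TRUE, nonneg_S = TRUE,
                            unimodal_C = FALSE, unimodal_S = FALSE,
                            unimodal_tol = 1.05,
                            correlation = NULL, calibration_rows = NULL) {
  if (!any(nonneg_C, nonneg_S, unimodal_C, unimodal_S, !is.null(correlation)))
    stop("mcr_constraints: at least one constraint must be active")
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (is.null(calibration_rows))
      calibration_rows <- seq_len(nrow(correlation))
    if (length(calibration_rows) != nrow(correlation))
      stop("mcr_constraints: calibration_rows / reference length mismatch")
  }
  structure(list(nonneg_C = nonneg_C, nonneg_S = nonneg_S,
                 unimodal_C = unimodal_C, unimodal_S = unimodal_S,
                 unimodal_tol = unimodal_tol,
                 correlation = correlation,
                 calibration_rows = calibration_rows),
            class = "mcr_constraints")
}

#' Initial spectral profile estimates for MCR-ALS
#'
#' `pure_standards` uses measured (here: generated) pure-component spectra
#' on the data grid. `purest_rows` picks the k most mutually dissimilar data
#' rows by greedily maximizing the determinant of the Gram matrix of the
#' normalized selected rows, starting from the row of largest norm.
#'
#' @param D A [spectra_matrix()] or numeric matrix.
#' @param k Number of components.
#' @param method `"pure_standards"` or `"purest_rows"`.
#' @param pure A `pure_spectra_set` (required for `pure_standards`); it is
#'   windowed to the data grid if needed.
#' @return Matrix n_points x k of initial spectral profiles.
#' @export
initialize_profiles <- function(D, k, method = c("pure_standards", "purest_rows"),
                                pure = NULL) {
  method <- match.arg(method)
  grid <- if (inherits(D, "spectra_matrix")) D$grid else NULL
  Dm <- if (inherits(D, "spectra_matrix")) D$absorbance else as.matrix(D)
  stopifnot(k >= 1)
  r <- qr(Dm)$rank
  if (k > r)
    warning("initialize_profiles: k = ", k, " exceeds the numerical rank (",
            r, ") of D; rotational ambiguity expected")
  if (method == "pure_standards") {
    if (is.null(pure))
      stop("initialize_profiles: pure_standards requires a pure_spectra_set")
    if (!is.null(grid) && pure$grid$n_points != grid$n_points)
      pure <- window_pure_spectra(pure, grid$lo_nm, grid$hi_nm)
    S0 <- pure$absorptivity[, seq_len(k), drop = FALSE]
    if (nrow(S0) != ncol(Dm))
      stop("initialize_profiles: pure spectra are not on the data grid")
    return(S0)
  }
  # purest_rows: greedy D-optimal style row selection
  if (k > nrow(Dm))
    stop("initialize_profiles: purest_rows needs k <= number of samples")
  norms <- sqrt(rowSums(Dm^2))
  Rn <- sweep(Dm, 1L, pmax(norms, .Machine$double.eps), "/")
  sel <- which.max(norms)
  while (length(sel) < k) {
    cand <- setdiff(seq_len(nrow(Dm)), sel)
    dets <- vapply(cand, function(i) {
      G <- tcrossprod(Rn[c(sel, i), , drop = FALSE])
      det(G)
    }, numeric(1))
    sel <- c(sel, cand[which.max(dets)])
  }
  t(Dm[sel, , drop = FALSE])
}

#' Horizontal unimodality correction
#'
#' Forces a profile to have a single mode: scanning from the ends toward the
#' global maximum, any value that breaks monotonicity by more than the
#' tolerance factor is replaced by the neighbouring bound (a flat,
#' "horizontal" correction). The global maximum position is preserved and
#' the operation is idempotent.
#'
#' @param profile Numeric vector of finite values.
#' @param mode Only `"horizontal"` is implemented.
#' @param tol Violation tolerance (1 = strict; 1.05 allows 5% bumps).
#' @return Corrected numeric vector.
#' @export
#' @examples
#' apply_unimodality(c(0, 2, 1, 3, 0)) # 0 2 2 3 0
apply_unimodality <- function(profile, mode = "horizontal", tol = 1.05) {
  stopifnot(mode == "horizontal", all(is.finite(profile)), tol >= 1)
  v <- profile
  m <- which.max(v)
  if (m > 2) for (i in 2:(m - 1)) if (v[i] * tol < v[i - 1]) v[i] <- v[i - 1]
  n <- length(v)
  if (m < n) for (i in (m + 1):n) if (v[i] > v[i - 1] * tol) v[i] <- v[i - 1]
  v
}

#' Correlation (inner calibration) constraint
#'
#' Regresses the known reference concentrations of the calibration rows on
#' the resolved concentration column, then applies the fitted line to the
#' entire column. Calibration entries become the back-transformed fitted
#' references, and test entries are rescaled through the same line, so the
#' column ends up in real concentration units.
#'
#' @param C_column Resolved concentration column (arbitrary units).
#' @param calibration_mask Logical (or index) vector marking calibration rows.
#' @param reference Known concentrations (ug/mL) of the masked rows.
#' @return List: `column` (corrected), `slope`, `intercept` of the inner
#'   regression `reference ~ C_column[mask]`.
#' @export
apply_correlation_constraint <- function(C_column, calibration_mask, reference) {
  idx <- if (is.logical(calibration_mask)) which(calibration_mask)
         else as.integer(calibration_mask)
  if (length(idx) < 2) stop("apply_correlation_constraint: need >= 2 calibration rows")
  if (length(reference) != length(idx))
    stop("apply_correlation_constraint: reference length mismatch")
  x <- C_column[idx]
  if (var(x) < .Machine$double.eps)
    stop("apply_correlation_constraint: zero-variance resolved column")
  sl <- sum((x - mean(x)) * (reference - mean(reference))) / sum((x - mean(x))^2)
  ic <- mean(reference) - sl * mean(x)
  list(column = sl * C_column + ic, slope = sl, intercept = ic)
}

#' Lack of fit and explained variance of a bilinear factorization
#'
#' `lof = 100 * sqrt(sum(E^2) / sum(D^2))` and
#' `r2 = 100 * (1 - sum(E^2) / sum(D^2))` with `E = D - C %*% t(S)`, sums
#' over all matrix entries.
#'
#' @param D Data matrix (or [spectra_matrix()]).
#' @param C Concentration profiles (samples x k).
#' @param S Spectral profiles (wavelengths x k).
#' @return List `lof_percent`, `r2_percent`.
#' @export
lack_of_fit <- function(D, C, S) {
  Dm <- if (inherits(D, "spectra_matrix")) D$absorbance else as.matrix(D)
  E <- Dm - C %*% t(S)
  ssd <- sum(Dm^2)
  if (ssd == 0) stop("lack_of_fit: all-zero data matrix")
  sse <- sum(E^2)
  list(lof_percent = 100 * sqrt(sse / ssd), r2_percent = 100 * (1 - sse / ssd))
}

solve_ls <- function(A, B) {
  # least-squares solve min ||A X - B||, ridge fallback on singularity
  G <- crossprod(A)
  out <- tryCatch(solve(G, crossprod(A, B)), error = function(e) NULL)
  if (is.null(out)) {
    warning("mcr_als: singular least-squares step; applying ridge jitter 1e-10")
    out <- solve(G + diag(1e-10, ncol(A)), crossprod(A, B))
  }
  out
}

#' Run MCR-ALS
#'
#' Alternates (i) the concentration step `C <- argmin ||D - C t(S)||` with
#' C-constraints (non-negativity via NNLS, unimodality, correlation inner
#' calibration) and (ii) the spectral step with S-constraints, until the
#' relative change of the lack of fit between consecutive iterations falls
#' below `conv_threshold_percent`/100 or `max_iter` is reached.
#'
#' @param D A [spectra_matrix()] or matrix (samples x wavelengths).
#' @param init_S Initial spectral profiles (wavelengths x k), e.g. from
#'   [initialize_profiles()].
#' @param constraints An [mcr_constraints()] object.
#' @param conv_threshold_percent Convergence threshold on the relative lof
#'   change, in percent (default 0.1).
#' @param max_iter Iteration cap (default 50).
#' @return An `mcr_result`: `C`, `S`, `E` (with `D = C t(S) + E` exact by
#'   construction), `lof_percent`, `r2_percent`, `n_iterations`, `converged`,
#'   `lof_history`, and `inner_calibration` (per-component slope/intercept)
#'   when the correlation constraint is active.
#' @export
run_mcr_als <- function(D, init_S, constraints = mcr_constraints(),
                        conv_threshold_percent = 0.1, max_iter = 50L) {
  Dm <- if (inherits(D, "spectra_matrix")) D$absorbance else as.matrix(D)
  if (any(is.na(Dm))) stop("run_mcr_als: NaN/NA in data matrix")
  if (conv_threshold_percent <= 0) stop("run_mcr_als: threshold must be > 0")
  S <- as.matrix(init_S)
  if (nrow(S) != ncol(Dm)) stop("run_mcr_als: init_S rows must match wavelengths")
  k <- ncol(S)
  cn <- colnames(S)
  lof_prev <- Inf
  lof_history <- numeric(0)
  converged <- FALSE
  inner <- NULL
  C <- matrix(0, nrow(Dm), k)
  for (iter in seq_len(max_iter)) {
    # --- C step ---
    if (constraints$nonneg_C) {
      for (i in seq_len(nrow(Dm)))
        C[i, ] <- pracma::lsqnonneg(S, Dm[i, ])$x
    } else {
      C <- t(solve_ls(S, t(Dm)))
    }
    if (constraints$unimodal_C)
      for (j in seq_len(k))
        C[, j] <- apply_unimodality(C[, j], tol = constraints$unimodal_tol)
    if (!is.null(constraints$correlation)) {
      inner <- matrix(NA_real_, k, 2, dimnames = list(cn, c("slope", "intercept")))
      for (j in seq_len(k)) {
        cc <- apply_correlation_constraint(C[, j], constraints$calibration_rows,
                                           constraints$correlation[, j])
        C[, j] <- cc$column
        inner[j, ] <- c(cc$slope, cc$intercept)
      }
      if (constraints$nonneg_C) C[C < 0] <- 0
    }
    # --- S step ---
    if (constraints$nonneg_S) {
      for (jw in seq_len(ncol(Dm)))
        S[jw, ] <- pracma::lsqnonneg(C, Dm[, jw])$x
    } else {
      S <- t(solve_ls(C, Dm))
    }
    if (constraints$unimodal_S)
      for (j in seq_len(k))
        S[, j] <- apply_unimodality(S[, j], tol = constraints$unimodal_tol)
    fom <- lack_of_fit(Dm, C, S)
    lof_history <- c(lof_history, fom$lof_percent)
    # lof below 1e-10 percent is numerical noise: treat as fully converged
    rel <- if (!is.finite(lof_prev)) Inf
           else if (lof_prev < 1e-10 && fom$lof_percent < 1e-10) 0
           else abs(lof_prev - fom$lof_percent) / max(lof_prev, 1e-14)
    if (rel < conv_threshold_percent / 100) { converged <- TRUE; break }
    lof_prev <- fom$lof_percent
  }
  fom <- lack_of_fit(Dm, C, S)
  rownames(S) <- colnames(Dm)
  colnames(C) <- cn; colnames(S) <- cn
  rownames(C) <- rownames(Dm)
  structure(list(C = C, S = S, E = Dm - C %*% t(S),
                 lof_percent = fom$lof_percent, r2_percent = fom$r2_percent,
                 n_iterations = length(lof_history), converged = converged,
                 lof_history = lof_history, inner_calibration = inner),
            class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf("mcr_result: %d components, %d iteration(s)%s, lof %.4f%%, R2 %.4f%%\n",
              ncol(x$C), x$n_iterations,
              if (x$converged) " (converged)" else " (iteration cap)",
              x$lof_percent, x$r2_percent))
  invisible(x)
}

#' Quantify test samples by one-by-one augmented MCR-ALS
#'
#' For each test spectrum, the calibration matrix is augmented with that
#' single row, MCR-ALS is run with the correlation constraint masked to the
#' calibration rows, and the test row of the resolved `C` (already in
#' concentration units through the inner calibration) is read off. Results
#' are independent of the order the test rows are processed in.
#'
#' @param calibration_D Calibration spectra ([spectra_matrix()] or matrix).
#' @param test_D Test spectra on the same grid.
#' @param reference Calibration concentration matrix (rows x components).
#' @param init_S Initial spectral profiles (wavelengths x k).
#' @param constraints Base [mcr_constraints()]; its correlation slot is
#'   overwritten with `reference` on the calibration rows.
#' @param conv_threshold_percent,max_iter Passed to [run_mcr_als()].
#' @return List: `predicted` (test samples x k matrix, ug/mL), `runs`
#'   (per-sample `mcr_result`s).
#' @export
quantify_test_samples <- function(calibration_D, test_D, reference, init_S,
                                  constraints = mcr_constraints(),
                                  conv_threshold_percent = 0.1, max_iter = 50L) {
  Dc <- if (inherits(calibration_D, "spectra_matrix")) calibration_D$absorbance
        else as.matrix(calibration_D)
  Dt <- if (inherits(test_D, "spectra_matrix")) test_D$absorbance
        else as.matrix(test_D)
  if (ncol(Dc) != ncol(Dt)) stop("quantify_test_samples: grids do not match")
  reference <- as.matrix(reference)
  stopifnot(nrow(reference) == nrow(Dc))
  k <- ncol(init_S)
  pred <- matrix(NA_real_, nrow(Dt), k,
                 dimnames = list(rownames(Dt), colnames(init_S)))
  runs <- vector("list", nrow(Dt))
  cons <- mcr_constraints(nonneg_C = constraints$nonneg_C,
                          nonneg_S = constraints$nonneg_S,
                          unimodal_C = constraints$unimodal_C,
                          unimodal_S = constraints$unimodal_S,
                          unimodal_tol = constraints$unimodal_tol,
                          correlation = reference,
                          calibration_rows = seq_len(nrow(Dc)))
  for (i in seq_len(nrow(Dt))) {
    Daug <- rbind(Dc, Dt[i, , drop = FALSE])
    res <- run_mcr_als(Daug, init_S, cons, conv_threshold_percent, max_iter)
    pred[i, ] <- res$C[nrow(Daug), ]
    runs[[i]] <- res
  }
  list(predicted = pred, runs = runs)
}
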