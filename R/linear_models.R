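#' Multivariate calibration models: PCR and PLS
#'
#' Both models regress the (mean-centered) concentration block `Y` on a small
#' number of latent variables extracted from the (mean-centered) absorbance
#' block `X`. PCR uses the leading principal components of `X` alone; PLS
#' extracts components that maximize covariance with `Y` (NIPALS PLS2 with
#' X- and Y-deflation), typically needing fewer latent variables. Shipped
#' defaults follow the study configuration: 6 latent variables for PCR,
#' 5 for PLS, chosen by leave-one-out cross-validation.
#'
#' @name linear-models
NULL

as_xy_matrices <- function(X, Y) {
  X <- if (inherits(X, "spectra_matrix")) X$absorbance else as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  list(X = X, Y = Y)
}

new_calibration_model <- function(kind, n_lv, B, x_means, y_means, extra = list()) {
  structure(c(list(kind = kind, n_lv = n_lv, coefficients = B,
                   x_means = x_means, y_means = y_means), extra),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model: %s, %d latent variable(s), %d wavelengths -> %d components\n",
              x$kind, x$n_lv, nrow(x$coefficients), ncol(x$coefficients)))
  invisible(x)
}

#' Fit a principal component regression model
#'
#' Regresses the concentrations on the scores of the first `n_lv` principal
#' components of the centered spectra (components ordered by decreasing
#' singular value), then maps the coefficients back to wavelength space.
#'
#' @param X Spectra: a [spectra_matrix()] or numeric matrix (samples x
#'   wavelengths).
#' @param Y Concentration matrix (samples x components, ug/mL).
#' @param n_lv Number of latent variables; must not exceed the numerical
#'   rank of the centered `X`.
#' @param center Mean-center `X` and `Y` before fitting (default TRUE; the
#'   stored means are reapplied at prediction).
#' @return A `calibration_model` of kind `"PCR"`.
#' @export
fit_pcr <- function(X, Y, n_lv, center = TRUE) {
  d <- as_xy_matrices(X, Y)
  xm <- if (center) colMeans(d$X) else rep(0, ncol(d$X))
  ym <- if (center) colMeans(d$Y) else rep(0, ncol(d$Y))
  Xc <- sweep(d$X, 2L, xm); Yc <- sweep(d$Y, 2L, ym)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  if (n_lv < 1 || n_lv > r)
    stop("fit_pcr: n_lv = ", n_lv, " exceeds the numerical rank (", r,
         ") of the centered spectra")
  Vk <- sv$v[, seq_len(n_lv), drop = FALSE]
  # scores T = U_k d_k; regression of Yc on T is diag(1/d_k) U_k' Yc
  Blat <- sweep(crossprod(sv$u[, seq_len(n_lv), drop = FALSE], Yc),
                1L, sv$d[seq_len(n_lv)], "/")
  B <- Vk %*% Blat
  colnames(B) <- colnames(d$Y)
  new_calibration_model("PCR", as.integer(n_lv), B, xm, ym,
                        list(singular_values = sv$d))
}

#' Fit a PLS2 model by NIPALS
#'
#' Iterative NIPALS construction with deflation of both blocks per extracted
#' latent variable; the inner loop runs to tolerance `1e-10` with a cap of
#' 500 iterations.
#'
#' @inheritParams fit_pcr
#' @return A `calibration_model` of kind `"PLS"` (with weights `W`, loadings
#'   `P`, `Q` retained).
#' @export
fit_pls <- function(X, Y, n_lv, center = TRUE) {
  d <- as_xy_matrices(X, Y)
  xm <- if (center) colMeans(d$X) else rep(0, ncol(d$X))
  ym <- if (center) colMeans(d$Y) else rep(0, ncol(d$Y))
  Xc <- sweep(d$X, 2L, xm); Yc <- sweep(d$Y, 2L, ym)
  if (all(abs(Xc) < 1e-14)) stop("fit_pls: zero-variance spectra block")
  r <- qr(Xc)$rank
  if (n_lv < 1 || n_lv > r)
    stop("fit_pls: n_lv = ", n_lv, " exceeds the numerical rank (", r,
         ") of the centered spectra")
  p <- ncol(Xc); q <- ncol(Yc)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); Q <- matrix(0, q, n_lv)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(n_lv)) {
    u <- Yd[, which.max(apply(Yd, 2L, var)), drop = TRUE]
    t_old <- rep(Inf, nrow(Xd))
    for (it in seq_len(500L)) {
      w <- crossprod(Xd, u)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-12)
        stop("fit_pls: X-Y covariance exhausted before component ", a,
             " could be extracted")
      w <- w / wn
      tt <- Xd %*% w
      qv <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% qv / sum(qv^2)
      if (sqrt(sum((tt - t_old)^2)) < 1e-10 * sqrt(sum(tt^2))) break
      if (it == 500L)
        stop("fit_pls: NIPALS inner loop failed to converge for component ", a)
      t_old <- tt
    }
    pv <- crossprod(Xd, tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv
    Xd <- Xd - tcrossprod(tt, pv)
    Yd <- Yd - tcrossprod(tt, qv)
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  colnames(B) <- colnames(d$Y)
  new_calibration_model("PLS", as.integer(n_lv), B, xm, ym,
                        list(W = W, P = P, Q = Q))
}

#' Predict concentrations from spectra
#'
#' Applies the stored spectral centering, the regression coefficients, and
#' adds back the concentration means. Predictions are not clipped.
#'
#' @param object A `calibration_model`.
#' @param spectra A [spectra_matrix()] or matrix with the model's training
#'   wavelength width.
#' @param ... Unused.
#' @return Numeric matrix (samples x components, ug/mL).
#' @export
predict.calibration_model <- function(object, spectra, ...) {
  X <- if (inherits(spectra, "spectra_matrix")) spectra$absorbance
       else as.matrix(spectra)
  if (ncol(X) != length(object$x_means))
    stop("predict: spectra width (", ncol(X), ") does not match the model (",
         length(object$x_means), ")")
  Xc <- sweep(X, 2L, object$x_means)
  Yhat <- if (object$kind == "ANN") {
    ann_forward(object$net, Xc)
  } else {
    Xc %*% object$coefficients
  }
  out <- sweep(Yhat, 2L, object$y_means, FUN = "+")
  rownames(out) <- rownames(X)
  colnames(out) <- names(object$y_means)
  out
}

#' Leave-one-out cross-validated latent-variable selection
#'
#' For each candidate latent-variable count, each calibration sample is left
#' out once, the model is refit (including re-centering) on the remainder,
#' and the prediction error on the left-out sample is pooled over all
#' components: `RMSECV = sqrt(SSE / (n * q))`. The chosen count minimizes
#' RMSECV; ties within 1e-12 go to the smallest count (parsimony).
#' A candidate of 0 denotes the mean-only predictor.
#'
#' @inheritParams fit_pcr
#' @param max_lv Largest candidate (must be `<= n - 2` so every fold retains
#'   enough samples).
#' @param fit `"PCR"` or `"PLS"`.
#' @param lvs Candidate vector, default `1:max_lv`.
#' @return A list of class `lv_selection`: `candidate_lvs`, `rmsecv`,
#'   `chosen_lv`.
#' @export
loocv_select_lv <- function(X, Y, max_lv, fit = c("PLS", "PCR"),
                            lvs = seq_len(max_lv)) {
  fit <- match.arg(fit)
  d <- as_xy_matrices(X, Y)
  n <- nrow(d$X); q <- ncol(d$Y)
  if (max(lvs) > n - 2L)
    stop("loocv_select_lv: max candidate (", max(lvs),
         ") exceeds n - 2 = ", n - 2L)
  fitter <- if (fit == "PCR") fit_pcr else fit_pls
  sse <- numeric(length(lvs))
  for (li in seq_along(lvs)) {
    k <- lvs[li]
    for (i in seq_len(n)) {
      Xtr <- d$X[-i, , drop = FALSE]; Ytr <- d$Y[-i, , drop = FALSE]
      pred <- if (k == 0L) {
        matrix(colMeans(Ytr), 1L, q)
      } else {
        # a fold whose rank cannot support k latent variables disqualifies
        # that candidate rather than aborting the scan
        m <- tryCatch(fitter(Xtr, Ytr, n_lv = k), error = function(e) NULL)
        if (is.null(m)) { sse[li] <- Inf; break }
        predict(m, d$X[i, , drop = FALSE])
      }
      sse[li] <- sse[li] + sum((pred - d$Y[i, ])^2)
    }
  }
  rmsecv <- sqrt(sse / (n * q))
  chosen <- lvs[which(rmsecv <= min(rmsecv) + 1e-12)[1]]
  structure(list(candidate_lvs = lvs, rmsecv = rmsecv, chosen_lv = chosen),
            class = "lv_selection")
}

#' Root mean square error of calibration / prediction
#'
#' Per-component `sqrt(sum((pred - nominal)^2) / n)`. Called RMSEC when the
#' scope is the calibration set and RMSEP on the validation set.
#'
#' @param pred,nominal Matrices (or vectors) of identical shape, ug/mL.
#' @param scope `"calibration"` or `"prediction"` (label only).
#' @return Named numeric vector, one value per component, with attribute
#'   `scope`.
#' @export
rmse <- function(pred, nominal, scope = c("prediction", "calibration")) {
  scope <- match.arg(scope)
  pred <- as.matrix(pred); nominal <- as.matrix(nominal)
  if (!all(dim(pred) == dim(nominal))) stop("rmse: shape mismatch")
  if (nrow(pred) == 0) stop("rmse: no samples")
  out <- sqrt(colSums((pred - nominal)^2) / nrow(pred))
  names(out) <- colnames(nominal)
  attr(out, "scope") <- scope
  out
}
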