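#' Initialize a linear feed-forward network
#'
#' Architecture 107 -> 10 -> 4 by default: one input neuron per spectral
#' point of the working window, ten hidden neurons, one output neuron per
#' component. Both layers use the linear (purelin) transfer function, so the
#' network is a rank-constrained affine map; it is nevertheless trained by
#' full Levenberg-Marquardt backpropagation to reproduce the study
#' procedure. Weights are uniform in [-0.5, 0.5] scaled by 1/sqrt(fan-in),
#' deterministic in the seed.
#'
#' @param seed Integer seed.
#' @param n_input,n_hidden,n_output Layer sizes.
#' @return An `ann_model`: `W1` (hidden x input), `b1`, `W2`
#'   (output x hidden), `b2`, `transfer`, `seed`.
#' @export
init_network <- function(seed = 1L, n_input = 107L, n_hidden = 10L,
                         n_output = 4L) {
  with_seed(seed, {
    W1 <- matrix(runif(n_hidden * n_input, -0.5, 0.5) / sqrt(n_input),
                 n_hidden, n_input)
    b1 <- runif(n_hidden, -0.5, 0.5) / sqrt(n_input)
    W2 <- matrix(runif(n_output * n_hidden, -0.5, 0.5) / sqrt(n_hidden),
                 n_output, n_hidden)
    b2 <- runif(n_output, -0.5, 0.5) / sqrt(n_hidden)
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   transfer = c("linear", "linear"), seed = as.integer(seed)),
              class = "ann_model")
  })
}

# forward pass; X is samples x n_input, returns samples x n_output
ann_forward <- function(net, X) {
  H <- X %*% t(net$W1)
  H <- sweep(H, 2L, net$b1, FUN = "+")
  Y <- H %*% t(net$W2)
  sweep(Y, 2L, net$b2, FUN = "+")
}

net_to_par <- function(net) c(net$W1, net$b1, net$W2, net$b2)

par_to_net <- function(par, net) {
  nh <- nrow(net$W1); ni <- ncol(net$W1); no <- nrow(net$W2)
  i <- 0L
  net$W1 <- matrix(par[i + seq_len(nh * ni)], nh, ni); i <- i + nh * ni
  net$b1 <- par[i + seq_len(nh)]; i <- i + nh
  net$W2 <- matrix(par[i + seq_len(no * nh)], no, nh); i <- i + no * nh
  net$b2 <- par[i + seq_len(no)]
  net
}

# Jacobian of residuals vec(Yhat - Y) wrt parameters; rows grouped per
# sample (n_output rows each), parameter order matching net_to_par.
ann_jacobian <- function(net, X) {
  n <- nrow(X); ni <- ncol(X); nh <- nrow(net$W1); no <- nrow(net$W2)
  H <- sweep(X %*% t(net$W1), 2L, net$b1, FUN = "+")
  npar <- nh * ni + nh + no * nh + no
  J <- matrix(0, n * no, npar)
  I_no <- diag(no)
  for (s in seq_len(n)) {
    rows <- (s - 1L) * no + seq_len(no)
    # dW1: dy_k/dW1[i,j] = W2[k,i] x[j]  (vec(W1) column-major: i fast, j slow)
    J[rows, seq_len(nh * ni)] <- kronecker(matrix(X[s, ], 1L), net$W2)
    J[rows, nh * ni + seq_len(nh)] <- net$W2
    J[rows, nh * ni + nh + seq_len(no * nh)] <-
      kronecker(matrix(H[s, ], 1L), I_no)
    J[rows, nh * ni + nh + no * nh + seq_len(no)] <- I_no
  }
  J
}

mse_of <- function(net, X, Y) {
  if (nrow(X) == 0) return(NA_real_)
  mean((ann_forward(net, X) - Y)^2)
}

#' Train the network by Levenberg-Marquardt with early stopping
#'
#' Classic LM on the full Jacobian of the linear-linear network: a step
#' `delta = -(J'J + mu I)^-1 J' r` is accepted when it reduces the training
#' MSE (then `mu` is divided by 10), otherwise rejected and `mu` multiplied
#' by 10. Samples are split by seeded shuffle into train/validation/test
#' partitions; training stops after `patience` consecutive epochs without a
#' new best validation MSE, on `mu` overflow, at the epoch cap, or when the
#' MSE goal is met. The returned model is the best-validation snapshot.
#'
#' @param net An [init_network()] model.
#' @param X,Y Centered spectra (samples x n_input) and centered
#'   concentrations (samples x n_output); at least 5 rows.
#' @param split Train/validation/test fractions summing to 1
#'   (default `c(0.70, 0.15, 0.15)`).
#' @param patience Consecutive validation failures tolerated (default 6).
#' @param max_epochs Epoch cap (default 1000).
#' @param mse_goal Training-MSE goal (default 0 = run to the other criteria).
#' @param split_seed Seed of the partition shuffle (defaults to the
#'   network's seed).
#' @param mu0,mu_max Initial and maximal LM damping.
#' @return List `model` (best snapshot) and `history` (`ann_history`):
#'   per-epoch train/validation/test MSE, `mu` trajectory, `best_epoch`,
#'   `stop_reason`.
#' @export
train_lm <- function(net, X, Y, split = c(0.70, 0.15, 0.15), patience = 6L,
                     max_epochs = 1000L, mse_goal = 0,
                     split_seed = net$seed, mu0 = 1e-3, mu_max = 1e10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), abs(sum(split) - 1) < 1e-9)
  n <- nrow(X)
  if (n < 5) stop("train_lm: need at least 5 samples")
  if (all(apply(X, 2L, function(col) max(col) - min(col)) < 1e-14))
    stop("train_lm: degenerate data (all rows identical)")
  ord <- with_seed(split_seed, sample.int(n))
  n_tr <- max(1L, round(split[1] * n))
  n_va <- round(split[2] * n)
  n_va <- min(n_va, n - n_tr)
  idx_tr <- ord[seq_len(n_tr)]
  idx_va <- if (n_va > 0) ord[n_tr + seq_len(n_va)] else integer(0)
  idx_te <- if (n_tr + n_va < n) ord[(n_tr + n_va + 1L):n] else integer(0)
  Xtr <- X[idx_tr, , drop = FALSE]; Ytr <- Y[idx_tr, , drop = FALSE]
  Xva <- X[idx_va, , drop = FALSE]; Yva <- Y[idx_va, , drop = FALSE]
  Xte <- X[idx_te, , drop = FALSE]; Yte <- Y[idx_te, , drop = FALSE]

  mu <- mu0
  hist_tr <- hist_va <- hist_te <- hist_mu <- numeric(0)
  best_val <- Inf; best_net <- net; best_epoch <- 0L
  fails <- 0L
  stop_reason <- "max_epochs"
  npar <- length(net_to_par(net))
  for (epoch in seq_len(max_epochs)) {
    mse_tr <- mse_of(net, Xtr, Ytr)
    mse_va <- mse_of(net, Xva, Yva)
    mse_te <- mse_of(net, Xte, Yte)
    hist_tr <- c(hist_tr, mse_tr); hist_va <- c(hist_va, mse_va)
    hist_te <- c(hist_te, mse_te); hist_mu <- c(hist_mu, mu)
    val_now <- if (length(idx_va) > 0) mse_va else mse_tr
    if (val_now < best_val - 0) {
      best_val <- val_now; best_net <- net; best_epoch <- epoch; fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= patience) { stop_reason <- "validation_patience"; break }
    }
    if (mse_tr <= mse_goal) { stop_reason <- "goal"; break }
    # one LM step (retry with larger mu until improvement or overflow)
    r <- as.vector(t(ann_forward(net, Xtr) - Ytr)) # outputs fastest, per sample
    J <- ann_jacobian(net, Xtr)
    sse <- sum(r^2)
    improved <- FALSE
    while (mu <= mu_max) {
      delta <- if (nrow(J) < npar) {
        # Woodbury form: (J'J + mu I)^-1 J' r = J'(JJ' + mu I)^-1 r
        -crossprod(J, solve(tcrossprod(J) + diag(mu, nrow(J)), r))
      } else {
        -solve(crossprod(J) + diag(mu, npar), crossprod(J, r))
      }
      cand <- par_to_net(net_to_par(net) + as.vector(delta), net)
      sse_new <- sum((ann_forward(cand, Xtr) - Ytr)^2)
      if (sse_new < sse) {
        net <- cand; mu <- max(mu / 10, 1e-20); improved <- TRUE; break
      }
      mu <- mu * 10
    }
    if (!improved) { stop_reason <- "mu_max"; break }
  }
  # record the post-loop state if we broke before logging it
  history <- structure(
    list(mse_train = hist_tr, mse_validation = hist_va, mse_test = hist_te,
         mu = hist_mu, best_epoch = best_epoch, stop_reason = stop_reason,
         split_index = list(train = idx_tr, validation = idx_va,
                            test = idx_te)),
    class = "ann_history")
  list(model = best_net, history = history)
}

#' Predict concentrations with a trained network
#'
#' Computes `W2 (W1 x + b1) + b2` per sample and adds back the stored
#' concentration means (if supplied).
#'
#' @param net A trained `ann_model`.
#' @param spectra_centered Matrix, samples x n_input (centered spectra).
#' @param y_means Optional concentration means to add back.
#' @return Matrix samples x n_output.
#' @export
ann_predict <- function(net, spectra_centered, y_means = NULL) {
  X <- as.matrix(spectra_centered)
  if (ncol(X) != ncol(net$W1))
    stop("ann_predict: input width (", ncol(X), ") does not match the network (",
         ncol(net$W1), ")")
  out <- ann_forward(net, X)
  if (!is.null(y_means)) out <- sweep(out, 2L, y_means, FUN = "+")
  out
}

#' Collapse the linear-linear network to its affine map
#'
#' A purelin-purelin network is exactly the affine map `A x + c` with
#' `A = W2 W1` (rank at most the hidden width) and `c = W2 b1 + b2`.
#'
#' @param net An `ann_model` with linear transfers.
#' @return List `A` (n_output x n_input), `c` (n_output).
#' @export
collapse_to_affine <- function(net) {
  if (!all(net$transfer == "linear"))
    stop("collapse_to_affine: requires linear transfer in both layers")
  list(A = net$W2 %*% net$W1, c = as.vector(net$W2 %*% net$b1 + net$b2))
}

#' Fit an ANN calibration model (centering + LM training)
#'
#' Convenience wrapper mirroring [fit_pcr()]/[fit_pls()]: mean-centers both
#' blocks, initializes a 10-hidden-neuron linear network sized to the data,
#' trains it by [train_lm()], and wraps the best snapshot as a
#' `calibration_model` usable with [predict.calibration_model()].
#'
#' @inheritParams fit_pcr
#' @param seed Seed for weight initialization and the partition shuffle.
#' @param ... Passed to [train_lm()].
#' @return A `calibration_model` of kind `"ANN"` (fields `net`, `history`).
#' @export
fit_ann <- function(X, Y, seed = 1L, n_hidden = 10L, ...) {
  d <- as_xy_matrices(X, Y)
  xm <- colMeans(d$X); ym <- colMeans(d$Y)
  Xc <- sweep(d$X, 2L, xm); Yc <- sweep(d$Y, 2L, ym)
  net <- init_network(seed, n_input = ncol(Xc), n_hidden = n_hidden,
                      n_output = ncol(Yc))
  tr <- train_lm(net, Xc, Yc, ...)
  affine <- collapse_to_affine(tr$model)
  m <- new_calibration_model("ANN", n_hidden, t(affine$A), xm, ym,
                             list(net = tr$model, history = tr$history))
  names(m$y_means) <- colnames(d$Y)
  m
}
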