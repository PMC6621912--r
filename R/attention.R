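#' Attention-readout parameter block
#'
#' Three weight matrices over the concatenated trace state
#' `x_deep = [X_1, ..., X_L]` (length `L * N`): the deep-attention network
#' `w_deep` (`L x L*N`) scoring layer importance, the spatial-attention
#' network `w_spatial` (`N x L*N`) gating individual neurons, and the
#' readout `w_out` (`O x N`) mapping the attended state to class scores.
#'
#' @param n_layers number of reservoirs `L`.
#' @param n_hidden reservoir width `N` (all layers equal).
#' @param n_classes number of output classes `O`.
#' @param init_sd sd of the Gaussian weight initialization.
#' @param seed RNG seed.
#' @return an object of class `attention_params`.
#' @export
attention_params <- function(n_layers, n_hidden, n_classes,
                             init_sd = 0.01, seed = 1L) {
  stopifnot(n_layers >= 1, n_hidden >= 1, n_classes >= 2)
  d <- n_layers * n_hidden
  with_seed(derive_seed(seed, "attention-init"), {
    structure(list(
      w_deep = matrix(rnorm(n_layers * d, 0, init_sd), n_layers, d),
      w_spatial = matrix(rnorm(n_hidden * d, 0, init_sd), n_hidden, d),
      w_out = matrix(rnorm(n_classes * n_hidden, 0, init_sd),
                     n_classes, n_hidden),
      n_layers = n_layers, n_hidden = n_hidden, n_classes = n_classes
    ), class = "attention_params")
  })
}

check_xdeep <- function(params, x_deep) {
  if (length(x_deep) != params$n_layers * params$n_hidden) {
    stop("x_deep length does not match n_layers * n_hidden", call. = FALSE)
  }
  invisible(x_deep)
}

#' Deep-attention layer coefficients
#'
#' `A_deep = softmax(w_deep %*% x_deep)`: one coefficient per reservoir,
#' positive and summing to 1, scoring each layer's importance for the
#' current state.
#'
#' @param params an [attention_params()].
#' @param x_deep concatenated trace state (length `L * N`).
#' @return numeric vector of `L` coefficients.
#' @export
deep_attention <- function(params, x_deep) {
  check_xdeep(params, x_deep)
  softmax(as.numeric(params$w_deep %*% x_deep))
}

#' Collapse layer states under deep-attention coefficients
#'
#' `X_S = sum_l A_l * X_l`: the attention-weighted sum of the per-layer
#' trace blocks, one vector of length `N`.
#'
#' @param x_deep concatenated trace state.
#' @param a_deep normalized layer coefficients.
#' @param n_hidden reservoir width `N`.
#' @return numeric vector of length `N`.
#' @export
collapse_layers <- function(x_deep, a_deep, n_hidden) {
  stopifnot(length(x_deep) == length(a_deep) * n_hidden)
  blocks <- matrix(x_deep, n_hidden, length(a_deep))
  as.numeric(blocks %*% a_deep)
}

#' Spatial-attention gates
#'
#' `A_spatial[n] = logistic(w_spatial[n, ] %*% x_deep)`: an independent gate
#' in (0, 1) per neuron of the collapsed representation (no normalization
#' across neurons).
#'
#' @param params an [attention_params()].
#' @param x_deep concatenated trace state.
#' @return numeric vector of `N` gates in (0, 1).
#' @export
spatial_attention <- function(params, x_deep) {
  check_xdeep(params, x_deep)
  logistic(as.numeric(params$w_spatial %*% x_deep))
}

#' Full attention-modulated readout
#'
#' Runs the complete chain: deep attention collapses the layers to `X_S`,
#' spatial attention gates it to `X_F = X_S * A_spatial`, and the readout
#' gives per-class scores `y = logistic(w_out %*% X_F)`. The predicted
#' label is `argmax y` (ties to the lowest class index).
#'
#' @param params an [attention_params()].
#' @param x_deep concatenated trace state.
#' @return list with `a_deep`, `x_s`, `a_spatial`, `x_f`, `y`, `label`.
#' @export
readout <- function(params, x_deep) {
  a_deep <- deep_attention(params, x_deep)
  x_s <- collapse_layers(x_deep, a_deep, params$n_hidden)
  a_spatial <- spatial_attention(params, x_deep)
  x_f <- x_s * a_spatial
  y <- logistic(as.numeric(params$w_out %*% x_f))
  list(a_deep = a_deep, x_s = x_s, a_spatial = a_spatial, x_f = x_f,
       y = y, label = which.max(y))
}

# Loss and analytic gradients of softmax-cross-entropy over the readout
# scores, for a batch of snapshots. Returns list(loss, grads, pred).
attention_loss_grad <- function(params, snapshots, labels) {
  X <- as.matrix(snapshots)
  n <- nrow(X)
  L <- params$n_layers
  N <- params$n_hidden
  O <- params$n_classes
  Zd <- X %*% t(params$w_deep)                       # n x L
  Zd <- Zd - apply(Zd, 1, max)
  A <- exp(Zd) / rowSums(exp(Zd))
  XS <- matrix(0, n, N)
  for (l in seq_len(L)) {
    XS <- XS + A[, l] * X[, ((l - 1) * N + 1):(l * N), drop = FALSE]
  }
  Zs <- X %*% t(params$w_spatial)                    # n x N
  G <- logistic(Zs)
  XF <- XS * G
  Zo <- XF %*% t(params$w_out)                       # n x O
  Y <- logistic(Zo)
  Ym <- Y - apply(Y, 1, max)
  P <- exp(Ym) / rowSums(exp(Ym))
  T_ <- matrix(0, n, O)
  T_[cbind(seq_len(n), labels)] <- 1
  loss <- -mean(log(pmax(P[cbind(seq_len(n), labels)], 1e-300)))

  dY <- (P - T_) / n
  dZo <- dY * Y * (1 - Y)
  g_out <- t(dZo) %*% XF
  dXF <- dZo %*% params$w_out
  dXS <- dXF * G
  dG <- dXF * XS
  dZs <- dG * G * (1 - G)
  g_spatial <- t(dZs) %*% X
  dA <- matrix(0, n, L)
  for (l in seq_len(L)) {
    dA[, l] <- rowSums(dXS * X[, ((l - 1) * N + 1):(l * N), drop = FALSE])
  }
  dZd <- A * (dA - rowSums(dA * A))
  g_deep <- t(dZd) %*% X
  list(loss = loss,
       grads = list(w_deep = g_deep, w_spatial = g_spatial, w_out = g_out),
       pred = max.col(P, ties.method = "first"))
}

#' Train the attention readout by full-batch gradient descent
#'
#' Minimizes softmax cross-entropy over the readout scores through the
#' attention chain only — snapshots are fixed constants, so no gradient
#' flows into the spiking network and no backpropagation through time is
#' required. Deterministic given the seed (used for initialization).
#'
#' @param snapshots matrix of `X_deep` snapshots (sequences x `L*N`).
#' @param labels integer class labels in `1..n_classes`.
#' @param n_layers,n_hidden state geometry (see [attention_params()]).
#' @param n_classes number of classes (default `max(labels)`).
#' @param lr learning rate.
#' @param epochs full-batch gradient steps.
#' @param seed initialization seed.
#' @param params optional warm-start [attention_params()].
#' @param standardize center/scale snapshot columns before training (the
#'   transform is stored in the returned params and applied automatically
#'   at prediction time).
#' @param l2 optional ridge penalty on all weight blocks (0 = plain
#'   gradient descent on the cross-entropy).
#' @return list with trained `params`, `loss` curve, and final training
#'   `accuracy`.
#' @export
train_readout <- function(snapshots, labels, n_layers, n_hidden,
                          n_classes = max(labels), lr = 0.1, epochs = 200,
                          seed = 1L, params = NULL, standardize = FALSE,
                          l2 = 0) {
  snapshots <- as.matrix(snapshots)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("degenerate single-class training data", call. = FALSE)
  }
  if (is.null(params)) {
    params <- attention_params(n_layers, n_hidden, n_classes, seed = seed)
  }
  if (standardize) {
    ctr <- colMeans(snapshots)
    scl <- apply(snapshots, 2, stats::sd)
    scl[scl < 1e-12] <- 1
    params$center <- ctr
    params$scale <- scl
  }
  snapshots <- std_apply(params, snapshots)
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    lg <- attention_loss_grad(params, snapshots, labels)
    losses[e] <- lg$loss
    params$w_deep <- params$w_deep - lr * (lg$grads$w_deep + l2 * params$w_deep)
    params$w_spatial <- params$w_spatial -
      lr * (lg$grads$w_spatial + l2 * params$w_spatial)
    params$w_out <- params$w_out - lr * (lg$grads$w_out + l2 * params$w_out)
  }
  final <- attention_loss_grad(params, snapshots, labels)
  list(params = params, loss = losses,
       accuracy = mean(final$pred == labels))
}

std_apply <- function(params, X) {
  if (is.null(params$center)) return(X)
  sweep(sweep(X, 2, params$center), 2, params$scale, "/")
}

#' Predict labels for snapshots with a trained readout
#'
#' @param params a trained [attention_params()].
#' @param snapshots matrix of `X_deep` snapshots.
#' @return integer vector of predicted labels.
#' @export
predict_readout <- function(params, snapshots) {
  snapshots <- std_apply(params, as.matrix(snapshots))
  apply(snapshots, 1, function(x) readout(params, x)$label)
}

#' Evaluate a trained readout: accuracy and confusion matrix
#'
#' @param params a trained [attention_params()].
#' @param snapshots matrix of `X_deep` snapshots.
#' @param labels true integer labels.
#' @return list with `accuracy` and `confusion` (true x predicted table).
#' @export
evaluate_readout <- function(params, snapshots, labels) {
  pred <- predict_readout(params, snapshots)
  list(accuracy = mean(pred == labels),
       confusion = table(true = factor(labels, levels = seq_len(params$n_classes)),
                         predicted = factor(pred, levels = seq_len(params$n_classes))))
}
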