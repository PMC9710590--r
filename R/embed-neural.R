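#' Neural gene embedding (E2): bottleneck autoencoder with a ReLU layer
#'
#' Architecture (one-hot gene input of size N): linear layer without bias to
#' the K-dimensional embedding, then a linear layer with bias followed by
#' ReLU to a hidden layer of `hidden` units, then a final linear layer
#' *without* bias to the M reconstruction outputs, trained with MSE loss
#' against the rows of `W`. Because the path from the embedding to the output
#' carries no terminal bias, negating an embedding vector negates the linear
#' part of the reconstruction exactly — the sign symmetry that makes signed
#' scoring meaningful. The embedding is read off as the first-layer weights
#' (rows of the N x K matrix).
#'
#' Training is full-batch gradient descent with adaptive-moment (Adam)
#' updates, with early stopping when the loss plateaus over a 50-epoch
#' window. All of optimizer, rate, and epochs are configurable; results are
#' reproducible given `seed`.
#'
#' @param W Sparse weight matrix from [build_weight_matrix()].
#' @param K Embedding dimension.
#' @param hidden Hidden-layer width (default 1000).
#' @param epochs Maximum training epochs.
#' @param seed Integer seed for weight initialization.
#' @param learning_rate Initial Adam step size.
#' @param plateau_window Early-stop window (epochs); stop when the best loss
#'   fails to improve by `plateau_tol` (relative) over this window.
#' @param plateau_tol Relative improvement threshold for early stopping.
#' @param activation Hidden-layer activation: `"relu"` (default) or
#'   `"identity"` (purely linear network, used for diagnostics: its optimum
#'   coincides with the spectral rank-K solution).
#' @return An `embedding_matrix` (method `"E2"`) with attributes
#'   `loss_history` (numeric vector) and `network` (the trained weights).
#' @export
train_neural_embedding <- function(W, K, hidden = 1000L, epochs = 500L,
                                   seed = 1L, learning_rate = 1e-3,
                                   plateau_window = 50L,
                                   plateau_tol = 1e-6,
                                   activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  relu_on <- activation == "relu"
  Wd <- as.matrix(W)
  N <- nrow(Wd); M <- ncol(Wd)
  K <- as.integer(K); H <- as.integer(hidden)
  stopifnot(K >= 1L, H >= 1L)
  par <- with_seed(sub_seed(seed, 21L), list(
    A = matrix(stats::rnorm(N * K, sd = sqrt(1 / N)), N, K),
    B = matrix(stats::rnorm(K * H, sd = sqrt(1 / K)), K, H),
    bias = rep(0, H),
    C = matrix(stats::rnorm(H * M, sd = sqrt(1 / H)), H, M)
  ))
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_hist <- numeric(0)
  best <- Inf; best_epoch <- 0L
  for (t in seq_len(epochs)) {
    Z <- par$A
    pre <- sweep(Z %*% par$B, 2, par$bias, `+`)
    Hact <- if (relu_on) pmax(pre, 0) else pre
    out <- Hact %*% par$C
    resid <- out - Wd
    loss <- mean(resid^2)
    loss_hist <- c(loss_hist, loss)
    if (loss < best * (1 - plateau_tol)) {
      best <- loss; best_epoch <- t
    } else if (t - best_epoch >= plateau_window) {
      break
    }
    g_out <- 2 * resid / (N * M)
    grad <- list(
      A = NULL, B = NULL, bias = NULL,
      C = crossprod(Hact, g_out)
    )
    g_h <- g_out %*% t(par$C)
    g_pre <- if (relu_on) g_h * (pre > 0) else g_h
    grad$B <- crossprod(Z, g_pre)
    grad$bias <- colSums(g_pre)
    grad$A <- g_pre %*% t(par$B)
    for (nm in names(par)) {
      mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * grad[[nm]]
      vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * grad[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1^t)
      vhat <- vel[[nm]] / (1 - b2^t)
      par[[nm]] <- par[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  if (length(loss_hist) > 1 && loss_hist[length(loss_hist)] >= loss_hist[1]) {
    warn(sprintf(
      "Training loss did not decrease (first %.4g, last %.4g over %d epochs).",
      loss_hist[1], loss_hist[length(loss_hist)], length(loss_hist)))
  }
  U <- par$A
  rownames(U) <- rownames(Wd)
  emb <- new_embedding(U, method = "E2")
  attr(emb, "loss_history") <- loss_hist
  attr(emb, "network") <- par
  attr(emb, "activation") <- activation
  emb
}

#' Reconstruction outputs of a trained E2 network
#'
#' Maps embedding-space vectors through the trained reconstruction path.
#' With `relu = FALSE`, the hidden nonlinearity is disabled and the map is
#' affine: `f(x) - f(0)` is then exactly linear (and antisymmetric) in `x`.
#'
#' @param emb An E2 `embedding_matrix` from [train_neural_embedding()].
#' @param X Matrix of embedding vectors (rows), K columns.
#' @param relu Apply the ReLU nonlinearity (default TRUE).
#' @return Matrix of reconstruction outputs (rows align with `X`).
#' @export
neural_reconstruct <- function(emb, X, relu = TRUE) {
  net <- attr(emb, "network")
  if (is.null(net)) abort("Embedding carries no trained network.")
  pre <- sweep(X %*% net$B, 2, net$bias, `+`)
  act <- if (relu) pmax(pre, 0) else pre
  act %*% net$C
}
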