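#' Signed, row-normalized bi-adjacency matrix W
#'
#' `W[i, j] = s_ij / sqrt(N_i)` where `s_ij` is the signed edge (0 if absent)
#' and `N_i` the number of targets of regulator `i`. The `1/sqrt(N_i)`
#' normalization makes every row a unit vector, so the gene-gene similarity
#' `S = W W^T` has unit diagonal regardless of how many targets each
#' regulator has.
#'
#' @param graph A [causal_graph()].
#' @return A sparse `dgCMatrix` (regulators x targets) with unit row norms.
#' @export
build_weight_matrix <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  if (any(graph$n_targets < 1L)) {
    abort("Every regulator must have at least one edge.")
  }
  i <- match(graph$edges$source, graph$regulators)
  j <- match(graph$edges$target, graph$targets)
  w <- graph$edges$sign / sqrt(graph$n_targets[i])
  Matrix::sparseMatrix(
    i = i, j = j, x = w,
    dims = c(length(graph$regulators), length(graph$targets)),
    dimnames = list(graph$regulators, graph$targets)
  )
}

#' Signed gene-gene similarity matrix S = W W^T
#'
#' Entries lie in `[-1, 1]`: +1 for identical downstream sign patterns, -1
#' for exactly opposite patterns, 0 for disjoint target sets.
#'
#' @param W Sparse weight matrix from [build_weight_matrix()].
#' @return A dense symmetric base matrix with unit diagonal.
#' @export
similarity_matrix <- function(W) {
  S <- as.matrix(Matrix::tcrossprod(W))
  dimnames(S) <- list(rownames(W), rownames(W))
  S
}

#' Spectral gene embedding (E1) by truncated SVD
#'
#' Computes the best rank-`K` approximation `W ~ U Sigma V^T`; the rows of
#' `U` are the gene embedding vectors. Columns of `U` are eigenvectors of
#' `S = W W^T` for its top `K` eigenvalues (`sigma^2`). A deterministic sign
#' convention orients every column of `U` so its largest-magnitude entry is
#' positive; all downstream scores are invariant to this choice.
#'
#' @param W Sparse weight matrix from [build_weight_matrix()].
#' @param K Embedding dimension, at most `min(N, M)`.
#' @return An object of class `embedding_matrix` with elements `U` (N x K,
#'   rownames = regulator ids), `sigma` (length K, nonincreasing), `V`
#'   (M x K), `K`, `method = "E1"`.
#' @export
spectral_embed <- function(W, K) {
  K <- as.integer(K)
  if (K < 1L || K > min(dim(W))) {
    abort("`K` must be between 1 and min(N, M).")
  }
  sv <- svd(as.matrix(W), nu = K, nv = K)
  sigma <- sv$d[seq_len(K)]
  tol <- max(dim(W)) * max(sv$d) * .Machine$double.eps
  if (any(sigma <= tol)) {
    warn(sprintf("K exceeds rank(W): %d trailing singular value(s) are ~0.",
                 sum(sigma <= tol)))
  }
  U <- sv$u
  V <- sv$v
  # Deterministic column-sign convention.
  for (k in seq_len(K)) {
    m <- which.max(abs(U[, k]))
    if (U[m, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  rownames(U) <- rownames(W)
  rownames(V) <- colnames(W)
  new_embedding(U, sigma = sigma, V = V, method = "E1",
                extra = list(total_energy = sum(sv$d^2)))
}

new_embedding <- function(U, sigma = NULL, V = NULL, method, extra = list()) {
  out <- c(list(U = U, sigma = sigma, V = V, K = ncol(U), method = method),
           extra)
  structure(out, class = "embedding_matrix")
}

#' @exportS3Method base::print
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %s: %d entities x K=%d\n", x$method,
              nrow(x$U), x$K))
  invisible(x)
}

#' Tidy an embedding into a long tibble
#'
#' @param x An `embedding_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `dimension`, `value`.
#' @export
tidy.embedding_matrix <- function(x, ...) {
  U <- x$U
  tibble(
    id = rep(rownames(U), times = ncol(U)),
    dimension = rep(seq_len(ncol(U)), each = nrow(U)),
    value = as.vector(U)
  )
}

#' One-row summary of an embedding
#'
#' @param x An `embedding_matrix`.
#' @param ... Unused.
#' @return A tibble with entity count, dimension, method and (for E1) the
#'   fraction of spectral energy captured.
#' @export
glance.embedding_matrix <- function(x, ...) {
  tibble(
    n = nrow(x$U), K = x$K, method = x$method,
    sigma_max = if (is.null(x$sigma)) NA_real_ else x$sigma[1],
    energy = if (is.null(x$sigma) || is.null(x$total_energy)) NA_real_
             else sum(x$sigma^2) / x$total_energy
  )
}

#' Write embedding vectors as TSV (id + K value columns)
#'
#' @param emb An `embedding_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  df <- as.data.frame(emb$U)
  names(df) <- paste0("k", seq_len(ncol(df)))
  df <- cbind(tibble(id = rownames(emb$U)), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read embedding vectors from TSV
#'
#' @param path Path written by [write_embedding()].
#' @param method Method label to attach.
#' @return An `embedding_matrix` (no singular values).
#' @export
read_embedding <- function(path, method = "E1") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = "c", .default = "d"), progress = FALSE)
  U <- as.matrix(df[, -1, drop = FALSE])
  rownames(U) <- df$id
  colnames(U) <- NULL
  new_embedding(U, method = method)
}
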