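#' Function and disease embeddings by per-function linear regression
#'
#' Each function `j` gets a vector `p_j` in gene-embedding space minimizing
#' the squared error `sum_i (x_i . p_j - Y_ij)^2`, i.e. the normal-equations
#' solution `p_j = (U^T U)^{-1} U^T y_j`. When the gene embedding is
#' orthonormal (spectral E1) this reduces to `p_j = U^T y_j`; the shortcut is
#' used automatically and agrees with the general solve. Vectors are then
#' normalized to unit length (`p_j / ||p_j||`) so that score distributions
#' under isotropic noise are comparable across functions. Functions with no
#' associated genes get a zero raw vector, are flagged, and are excluded from
#' the normalized matrix.
#'
#' @param emb An `embedding_matrix` whose rows align with the genes of `Y`.
#' @param Y An [association_matrix()] (genes x functions). Genes absent from
#'   the embedding are ignored; the embedding's row order is authoritative.
#' @return A `function_embeddings` object: `P` (J x K raw), `P_norm`
#'   (J' x K, unit rows, degenerate functions removed), `functions`,
#'   `flagged` (ids with zero raw vector), `K`.
#' @export
fit_function_embeddings <- function(emb, Y) {
  stopifnot(inherits(emb, "embedding_matrix"), inherits(Y, "assoc_matrix"))
  U <- emb$U
  common <- intersect(rownames(U), Y$genes)
  if (length(common) == 0L) abort("No genes shared between embedding and Y.")
  U <- U[common, , drop = FALSE]
  Ymat <- Y$Y[common, , drop = FALSE]
  G <- crossprod(U)
  UtY <- as.matrix(crossprod(U, Ymat))
  if (is_orthonormal(G)) {
    P <- t(UtY)
  } else {
    cond <- tryCatch(solve(G, UtY), error = function(e) NULL)
    if (is.null(cond) || rcond(G) < 1e-12) {
      abort("U^T U is numerically singular; lower the embedding dimension K.")
    }
    P <- t(cond)
  }
  rownames(P) <- Y$functions
  norms <- sqrt(rowSums(P^2))
  flagged <- Y$functions[norms == 0]
  keep <- norms > 0
  P_norm <- P[keep, , drop = FALSE] / norms[keep]
  structure(
    list(P = P, P_norm = P_norm, functions = Y$functions, flagged = flagged,
         K = ncol(U)),
    class = "function_embeddings"
  )
}

is_orthonormal <- function(G, tol = 1e-8) {
  max(abs(G - diag(nrow(G)))) < tol
}

#' @exportS3Method base::print
print.function_embeddings <- function(x, ...) {
  cat(sprintf("<function_embeddings> %d functions (%d degenerate) x K=%d\n",
              length(x$functions), length(x$flagged), x$K))
  invisible(x)
}

#' Signed gene-function scores s_ij and z-scores
#'
#' The score of gene `i` for function `j` is the scalar product
#' `s_ij = p~_j . x_i` of the normalized function vector with the gene
#' embedding vector; positive scores predict activation, negative scores
#' inhibition, and the score is exactly antisymmetric under negation of
#' either vector. z-scores standardize against an isotropic random-function
#' null: a random unit vector `p~` gives `s` with standard deviation
#' `||x_i|| / sqrt(K)`, hence `z_ij = s_ij sqrt(K) / ||x_i||`. Alternatively
#' `zmethod = "empirical"` standardizes each function column by its own mean
#' and SD.
#'
#' @param emb Gene `embedding_matrix`.
#' @param fe [fit_function_embeddings()] result.
#' @param zmethod `"analytic"` (default) or `"empirical"`.
#' @return A `score_matrix` object: `scores` and `zscores` (genes x
#'   functions), `genes`, `functions`.
#' @export
score_genes <- function(emb, fe, zmethod = c("analytic", "empirical")) {
  stopifnot(inherits(emb, "embedding_matrix"),
            inherits(fe, "function_embeddings"))
  zmethod <- match.arg(zmethod)
  S <- emb$U %*% t(fe$P_norm)
  Z <- score_zscores(S, emb, zmethod)
  structure(
    list(scores = S, zscores = Z, genes = rownames(emb$U),
         functions = rownames(fe$P_norm), K = emb$K),
    class = "score_matrix"
  )
}

#' Standardize raw gene-function scores to z-scores
#'
#' @param S Numeric matrix of raw scores (genes x functions).
#' @param emb The gene embedding used to produce `S`.
#' @param zmethod See [score_genes()].
#' @return Matrix of z-scores, a strictly increasing transform of the scores
#'   within each gene row (analytic) or function column (empirical).
#' @export
score_zscores <- function(S, emb, zmethod = c("analytic", "empirical")) {
  zmethod <- match.arg(zmethod)
  if (zmethod == "analytic") {
    xnorm <- sqrt(rowSums(emb$U^2))
    sdv <- xnorm / sqrt(emb$K)
    sdv[sdv == 0] <- Inf  # zero embedding vector: all z = 0
    Z <- S / sdv
  } else {
    mu <- colMeans(S)
    sdv <- apply(S, 2, stats::sd)
    sdv[sdv == 0] <- Inf
    Z <- sweep(sweep(S, 2, mu), 2, sdv, `/`)
  }
  dimnames(Z) <- dimnames(S)
  Z
}

#' @exportS3Method base::print
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d genes x %d functions (K=%d)\n",
              length(x$genes), length(x$functions), x$K))
  invisible(x)
}

#' Tidy gene-function scores into a long tibble
#'
#' @param x A `score_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `function_id`, `score`, `zscore`.
#' @export
tidy.score_matrix <- function(x, ...) {
  tibble(
    gene = rep(x$genes, times = length(x$functions)),
    function_id = rep(x$functions, each = length(x$genes)),
    score = as.vector(x$scores),
    zscore = as.vector(x$zscores)
  )
}

#' Cosine similarity between two embedded functions
#'
#' Function vectors are unit-normalized, so this is simply their scalar
#' product; negative values mean anti-similarity (activation of one
#' resembles inhibition of the other).
#'
#' @param fe A `function_embeddings` object.
#' @param a,b Function ids.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(fe, a, b) {
  P <- fe$P_norm
  if (!a %in% rownames(P) || !b %in% rownames(P)) {
    abort("Both functions must have (non-degenerate) embedding vectors.")
  }
  sum(P[a, ] * P[b, ])
}

#' Significance threshold for cosine similarity
#'
#' For two random unit vectors in `K` dimensions the cosine similarity has
#' standard deviation `sigma_c = K^{-1/2}` (from `1 = K sigma_c^2`, all
#' components of a unit vector being equivalent). The threshold at two
#' standard deviations is `2 K^{-1/2}` — about 0.09 at `K = 500`.
#'
#' @param K Embedding dimension.
#' @return The numeric threshold `2 / sqrt(K)`.
#' @export
similarity_threshold <- function(K) {
  stopifnot_scalar_number(K, "K")
  2 / sqrt(K)
}

#' Project selected function vectors onto their top two principal components
#'
#' Used to visualize latent linear relationships between "process of context"
#' function pairs: if embeddings encode `f_{X,Y} ~ v_X + w_Y`, segments
#' joining functions that share a context are near-parallel in this plane.
#' PCA mean-centers but does not rescale (vectors are already normalized).
#'
#' @param fe A `function_embeddings` object.
#' @param pairs Tibble/data frame with columns `a`, `b` of function ids; each
#'   row is a pair sharing a context.
#' @return A tibble with columns `function_id`, `pc1`, `pc2`; the fitted
#'   `prcomp` object is attached as attribute `"pca"`.
#' @export
project_process_pairs <- function(fe, pairs) {
  ids <- unique(c(pairs$a, pairs$b))
  missing <- setdiff(ids, rownames(fe$P_norm))
  if (length(missing) > 0L) {
    abort(sprintf("Functions without embeddings: %s.",
                  paste(utils::head(missing, 3), collapse = ", ")))
  }
  X <- fe$P_norm[ids, , drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  out <- tibble(function_id = ids, pc1 = pc$x[, 1], pc2 = pc$x[, 2])
  attr(out, "pca") <- pc
  out
}

segment_angles <- function(coords, pairs) {
  ia <- match(pairs$a, coords$function_id)
  ib <- match(pairs$b, coords$function_id)
  dx <- coords$pc1[ib] - coords$pc1[ia]
  dy <- coords$pc2[ib] - coords$pc2[ia]
  keep <- (dx != 0) | (dy != 0)
  list(theta = atan2(dy[keep], dx[keep]) %% pi, kept = keep)
}

# Circular spread of undirected segment angles: angles live modulo pi, so
# work on doubled angles; sd = sqrt(-2 log R) / 2 with R the mean resultant
# length. 0 iff all segments are exactly parallel.
angle_sd <- function(theta) {
  R <- sqrt(mean(cos(2 * theta))^2 + mean(sin(2 * theta))^2)
  R <- min(R, 1)
  sqrt(max(-2 * log(R), 0)) / 2
}

#' Permutation test for parallelism of context-pair segments
#'
#' Computes the spread (circular standard deviation, angles taken modulo pi)
#' of the angles that the segments `a -> b` form with the horizontal axis,
#' and compares it against segments with randomly permuted `b` endpoints.
#' Small p-values indicate the segments are more parallel than chance, the
#' signature of an additive latent structure ("X of Y" = process + context).
#'
#' @param coords Output of [project_process_pairs()].
#' @param pairs The pair table used for the projection.
#' @param n_permutations Number of endpoint permutations (>= 1000 advised).
#' @param seed Integer seed.
#' @return A list with `angle_sd` (observed), `p_value`
#'   `= (1 + #\{perm <= obs\}) / (1 + n)`, `n_pairs`, `n_permutations`.
#' @export
angle_parallelism_test <- function(coords, pairs, n_permutations = 1000L,
                                   seed = 1L) {
  if (nrow(pairs) < 3L) abort("Need at least 3 pairs.")
  obs <- segment_angles(coords, pairs)
  if (any(!obs$kept)) {
    warn(sprintf("Dropped %d pair(s) with coincident endpoints.",
                 sum(!obs$kept)))
  }
  pairs <- pairs[obs$kept, , drop = FALSE]
  observed <- angle_sd(obs$theta)
  perm_sd <- with_seed(sub_seed(seed, 11L), {
    vapply(seq_len(n_permutations), function(r) {
      shuffled <- pairs
      shuffled$b <- pairs$b[sample.int(nrow(pairs))]
      angle_sd(segment_angles(coords, shuffled)$theta)
    }, numeric(1))
  })
  list(
    angle_sd = observed,
    p_value = (1 + sum(perm_sd <= observed)) / (1 + n_permutations),
    n_pairs = nrow(pairs),
    n_permutations = as.integer(n_permutations)
  )
}

#' Disease map: PCA to 20 dimensions, then a 2-D t-SNE layout
#'
#' The PCA stage is exact and deterministic; the t-SNE stage is a stochastic
#' layout controlled by `seed` and intended for visualization only.
#'
#' @param fe A `function_embeddings` object.
#' @param disease_ids Function ids to map (typically diseases).
#' @param n_components PCA dimension (default 20, capped by the data).
#' @param perplexity t-SNE perplexity.
#' @param seed Integer seed for the layout.
#' @param max_iter t-SNE iterations.
#' @return A list: `pca` (tibble, one row per disease, `pc1..pc20`), `map`
#'   (tibble `function_id`, `x`, `y`).
#' @export
disease_map_coordinates <- function(fe, disease_ids, n_components = 20L,
                                    perplexity = 10, seed = 1L,
                                    max_iter = 300L) {
  ids <- intersect(disease_ids, rownames(fe$P_norm))
  if (length(ids) < 3L) abort("Need at least 3 embedded diseases.")
  X <- fe$P_norm[ids, , drop = FALSE]
  ncomp <- min(n_components, ncol(X), length(ids) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  red <- pc$x[, seq_len(ncomp), drop = FALSE]
  pca_tbl <- as_tibble(as.data.frame(red))
  names(pca_tbl) <- paste0("pc", seq_len(ncomp))
  pca_tbl <- dplyr::bind_cols(tibble(function_id = ids), pca_tbl)
  layout <- tsne_layout(red, perplexity = perplexity, seed = seed,
                        max_iter = max_iter)
  list(
    pca = pca_tbl,
    map = tibble(function_id = ids, x = layout[, 1], y = layout[, 2])
  )
}

# Compact exact-gradient t-SNE (adequate for a few hundred points).
tsne_layout <- function(X, perplexity = 10, seed = 1L, max_iter = 300L) {
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        p <- p / sp
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- with_seed(sub_seed(seed, 12L), matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  P_run <- P * 4  # early exaggeration
  for (iter in seq_len(max_iter)) {
    if (iter == 51L) P_run <- P
    if (iter == 21L) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (P_run - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    G <- momentum * G - 200 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
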