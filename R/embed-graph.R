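#' Signed coregulation similarity graph H
#'
#' Two regulators are connected when their downstream sign patterns agree
#' (or disagree) more than chance: over the `N_ik` targets both regulate,
#' the per-target sign products `s_ij s_kj` are summed and standardized,
#' `z_ik = sum_j s_ij s_kj / sqrt(N_ik)` (unit variance under a
#' random-sign null). An edge is stored when `|z_ik| >= z_cutoff`; its sign
#' is `sign(z_ik)`. Pairs with no shared targets have no edge.
#'
#' @param graph A [causal_graph()].
#' @param z_cutoff Positive cutoff on `|z|` (default 1.5).
#' @return A `similarity_graph`: list with `nodes` (all regulator ids),
#'   `edges` (tibble `i`, `k`, `sign`, `z`; i < k lexicographically) and
#'   `z_cutoff`.
#' @export
coregulation_graph <- function(graph, z_cutoff = 1.5) {
  stopifnot(inherits(graph, "causal_graph"))
  if (z_cutoff <= 0) abort("`z_cutoff` must be positive.")
  Smat <- Matrix::sparseMatrix(
    i = match(graph$edges$source, graph$regulators),
    j = match(graph$edges$target, graph$targets),
    x = as.numeric(graph$edges$sign),
    dims = c(length(graph$regulators), length(graph$targets))
  )
  num <- as.matrix(Matrix::tcrossprod(Smat))
  Nik <- as.matrix(Matrix::tcrossprod(abs(Smat)))
  z <- matrix(0, nrow(num), ncol(num))
  nz <- Nik > 0
  z[nz] <- num[nz] / sqrt(Nik[nz])
  diag(z) <- 0
  idx <- which(upper.tri(z) & abs(z) >= z_cutoff, arr.ind = TRUE)
  edges <- tibble(
    i = graph$regulators[idx[, 1]],
    k = graph$regulators[idx[, 2]],
    sign = ifelse(z[idx] > 0, 1L, -1L),
    z = z[idx]
  )
  if (nrow(edges) == 0L) warn("Similarity graph is empty at this cutoff.")
  structure(list(nodes = graph$regulators, edges = edges,
                 z_cutoff = z_cutoff),
            class = "similarity_graph")
}

#' @exportS3Method base::print
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d nodes, %d signed edges (|z| >= %.3g)\n",
              length(x$nodes), nrow(x$edges), x$z_cutoff))
  invisible(x)
}

#' Encode a signed graph as an unsigned graph by node replication
#'
#' Every node `i` of `H` is doubled into replicas `i_u` and `i_v`. A
#' positive edge `(i, k)` becomes the parallel pair `(i_u, k_u)`,
#' `(i_v, k_v)`; a negative edge the crosswise pair `(i_u, k_v)`,
#' `(i_v, k_u)`. The encoding is lossless: collapsing replicas recovers the
#' topology and signs of `H` exactly.
#'
#' @param H A [coregulation_graph()].
#' @return A `replicated_graph`: list with `nodes` (character,
#'   `<id>_u`/`<id>_v`), `edges` (tibble `from`, `to`) and `base_nodes`.
#' @export
replicate_unsigned <- function(H) {
  stopifnot(inherits(H, "similarity_graph"))
  nodes <- c(paste0(H$nodes, "_u"), paste0(H$nodes, "_v"))
  pos <- H$edges[H$edges$sign > 0, , drop = FALSE]
  neg <- H$edges[H$edges$sign < 0, , drop = FALSE]
  wire <- function(df, sfx_from, sfx_to) {
    if (nrow(df) == 0L) return(tibble(from = character(), to = character()))
    tibble(from = paste0(df$i, sfx_from), to = paste0(df$k, sfx_to))
  }
  edges <- dplyr::bind_rows(
    wire(pos, "_u", "_u"), wire(pos, "_v", "_v"),
    wire(neg, "_u", "_v"), wire(neg, "_v", "_u")
  )
  structure(list(nodes = nodes, edges = edges, base_nodes = H$nodes),
            class = "replicated_graph")
}

#' Collapse a replicated graph back to its signed form
#'
#' Inverse of [replicate_unsigned()]; used to verify losslessness.
#'
#' @param Hp A `replicated_graph`.
#' @return Tibble with columns `i`, `k`, `sign`.
#' @export
collapse_replicated <- function(Hp) {
  stopifnot(inherits(Hp, "replicated_graph"))
  base_of <- function(x) sub("_[uv]$", "", x)
  rep_of <- function(x) sub("^.*_([uv])$", "\\1", x)
  ed <- tibble(
    i = base_of(Hp$edges$from), k = base_of(Hp$edges$to),
    sign = ifelse(rep_of(Hp$edges$from) == rep_of(Hp$edges$to), 1L, -1L)
  )
  dplyr::distinct(dplyr::arrange(ed, .data$i, .data$k))
}

#' Sample node2vec random walks on a replicated graph
#'
#' Second-order biased walks with return parameter `p` and in-out parameter
#' `q`; at `p = q = 1` this reduces to a uniform first-order random walk.
#' Isolated nodes produce length-1 walks. Edges are unweighted.
#'
#' @param Hp A [replicate_unsigned()] graph.
#' @param walk_length Nodes per walk (default 30).
#' @param walks_per_node Walks started at every node (default 100).
#' @param p,q node2vec bias parameters (defaults 1).
#' @param seed Integer seed.
#' @return A `walk_corpus`: list with `walks` (integer matrix, 0-padded)
#'   and `node_names`.
#' @export
walk_corpus <- function(Hp, walk_length = 30L, walks_per_node = 100L,
                        p = 1, q = 1, seed = 1L) {
  stopifnot(inherits(Hp, "replicated_graph"))
  n <- length(Hp$nodes)
  idx_from <- match(Hp$edges$from, Hp$nodes)
  idx_to <- match(Hp$edges$to, Hp$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (e in seq_along(idx_from)) {
    adj[[idx_from[e]]] <- c(adj[[idx_from[e]]], idx_to[e])
    adj[[idx_to[e]]] <- c(adj[[idx_to[e]]], idx_from[e])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  walks <- cpp_node2vec_walks(adj, as.integer(walk_length),
                              as.integer(walks_per_node), p, q,
                              as.integer(sub_seed(seed, 31L)))
  structure(list(walks = walks, node_names = Hp$nodes),
            class = "walk_corpus")
}

#' Skip-gram embedding of a walk corpus
#'
#' word2vec-style skip-gram with negative sampling over the replica-node
#' walks. Embeddings are computed for all `2N` replica nodes; the `u`
#' replicas are returned as the gene embedding and the `v` replicas are kept
#' for diagnostics. Genes whose replicas never occur in the corpus (isolated
#' in `H`) are excluded with a message.
#'
#' @param corpus A [walk_corpus()].
#' @param K Embedding dimension.
#' @param window Skip-gram window (default 10).
#' @param negative Negative samples per positive (default 5).
#' @param epochs Passes over the corpus (default 5).
#' @param learning_rate Initial learning rate.
#' @param seed Integer seed.
#' @return An `embedding_matrix` (method `"E3"`, rows = gene ids with the
#'   `_u` suffix stripped) with attribute `v_matrix` (the `v`-replica rows).
#' @export
skipgram_embed <- function(corpus, K, window = 10L, negative = 5L,
                           epochs = 5L, learning_rate = 0.025, seed = 1L) {
  stopifnot(inherits(corpus, "walk_corpus"))
  n <- length(corpus$node_names)
  emb <- cpp_skipgram_train(corpus$walks, n, as.integer(K),
                            as.integer(window), as.integer(negative),
                            as.integer(epochs), learning_rate,
                            as.integer(sub_seed(seed, 32L)))
  rownames(emb) <- corpus$node_names
  # a node only trains if it co-occurs with context: walks of length >= 2
  connected <- corpus$walks[, 2] > 0
  seen <- tabulate(corpus$walks[connected, , drop = FALSE][
    corpus$walks[connected, , drop = FALSE] > 0], nbins = n) > 0
  u_nodes <- grep("_u$", corpus$node_names, value = TRUE)
  base <- sub("_u$", "", u_nodes)
  ok <- seen[match(u_nodes, corpus$node_names)] &
    seen[match(paste0(base, "_v"), corpus$node_names)]
  if (any(!ok)) {
    inform(sprintf("Excluded %d gene(s) with no similarity-graph walks.",
                   sum(!ok)))
  }
  U <- emb[u_nodes[ok], , drop = FALSE]
  rownames(U) <- base[ok]
  V <- emb[paste0(base[ok], "_v"), , drop = FALSE]
  rownames(V) <- base[ok]
  out <- new_embedding(U, method = "E3")
  attr(out, "v_matrix") <- V
  out
}

#' End-to-end graph-based embedding (E3) from a causal graph
#'
#' Convenience wrapper: coregulation graph, node replication, random walks,
#' skip-gram.
#'
#' @param graph A [causal_graph()].
#' @param K Embedding dimension.
#' @param z_cutoff Similarity cutoff (default 1.5).
#' @param ... Passed to [walk_corpus()] and [skipgram_embed()].
#' @param seed Integer seed.
#' @return An E3 `embedding_matrix`.
#' @export
graph_embed <- function(graph, K, z_cutoff = 1.5, seed = 1L, ...) {
  dots <- list(...)
  H <- coregulation_graph(graph, z_cutoff)
  Hp <- replicate_unsigned(H)
  wc_args <- dots[intersect(names(dots),
                            c("walk_length", "walks_per_node", "p", "q"))]
  corpus <- do.call(walk_corpus, c(list(Hp = Hp, seed = seed), wc_args))
  sg_args <- dots[intersect(names(dots),
                            c("window", "negative", "epochs",
                              "learning_rate"))]
  do.call(skipgram_embed,
          c(list(corpus = corpus, K = K, seed = seed), sg_args))
}
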