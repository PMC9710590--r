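#' Top-scoring genes for a disease
#'
#' Genes ranked by the absolute z-score of their gene-function score against
#' the disease vector; each gene carries the sign of its score (activating
#' vs inhibiting the disease). Ties are broken lexicographically by gene id.
#'
#' @param disease Function id of the disease.
#' @param scores A [score_genes()] result.
#' @param n_genes Number of genes to keep (default 15).
#' @return Tibble with columns `gene`, `score`, `zscore`, `sign`, ordered by
#'   decreasing `|zscore|`.
#' @export
top_disease_genes <- function(disease, scores, n_genes = 15L) {
  stopifnot(inherits(scores, "score_matrix"))
  if (!disease %in% scores$functions) {
    abort(sprintf("Disease '%s' has no score column.", disease))
  }
  z <- scores$zscores[, disease]
  s <- scores$scores[, disease]
  ord <- order(-abs(z), scores$genes)
  top <- utils::head(ord, n_genes)
  tibble(
    gene = scores$genes[top],
    score = unname(s[top]),
    zscore = unname(z[top]),
    sign = unname(ifelse(s[top] >= 0, 1L, -1L))
  )
}

#' Top-scoring functions for a disease
#'
#' Candidate functions are ranked by absolute cosine similarity to the
#' disease vector. To favor specific terms, a candidate is dropped when it
#' is an ontology ancestor of a higher-ranked retained candidate; redundancy
#' is further reduced by keeping only the top-ranked function within each
#' context bundle (functions sharing `metadata$context`). The disease itself
#' and its ontology ancestors are excluded.
#'
#' @param disease Function id of the disease.
#' @param fe A `function_embeddings` object.
#' @param metadata Function metadata tibble ([read_function_metadata()]);
#'   may be `NULL` (no context bundling).
#' @param ont An [ontology()]; may be `NULL` (no parent pruning).
#' @param n_functions Number of functions to keep (default 20).
#' @return Tibble with columns `function_id`, `cosine`, `sign`, `context`.
#' @export
top_disease_functions <- function(disease, fe, metadata = NULL, ont = NULL,
                                  n_functions = 20L) {
  stopifnot(inherits(fe, "function_embeddings"))
  P <- fe$P_norm
  if (!disease %in% rownames(P)) {
    abort(sprintf("Disease '%s' has no embedding vector.", disease))
  }
  cs <- as.vector(P %*% P[disease, ])
  names(cs) <- rownames(P)
  excluded <- c(disease,
                if (!is.null(ont)) ontology_ancestors(ont, disease))
  cand <- setdiff(rownames(P), excluded)
  cand <- cand[order(-abs(cs[cand]), cand)]
  ctx <- if (!is.null(metadata)) {
    stats::setNames(metadata$context, metadata$id)
  } else NULL
  kept <- character()
  kept_ctx <- character()
  for (f in cand) {
    if (length(kept) >= n_functions) break
    # specificity: never admit an ancestor of something already kept
    if (!is.null(ont) && any(kept %in% ontology_descendants(ont, f))) next
    fc <- if (!is.null(ctx)) ctx[[f]] %||% NA_character_ else NA_character_
    if (!is.na(fc) && fc %in% kept_ctx) next  # context bundle rule
    kept <- c(kept, f)
    if (!is.na(fc)) kept_ctx <- c(kept_ctx, fc)
  }
  tibble(
    function_id = kept,
    cosine = unname(cs[kept]),
    sign = ifelse(cs[kept] >= 0, 1L, -1L),
    context = if (!is.null(ctx)) unname(ctx[kept]) else NA_character_
  )
}

#' Build a disease-centric bipartite gene-function network
#'
#' Connects top-scoring genes and functions by an edge when the absolute
#' gene-function z-score exceeds `z_cut` *and* the score's sign is
#' consistent with the product of the adjacent node signs (an activating
#' gene and an inhibited function can only be joined by a negative score,
#' etc.). Edges supported by a curated association (`Y != 0`) are marked
#' `known`, the rest `inferred`; genes with a curated association to the
#' disease itself carry `known_association = TRUE`.
#'
#' @param disease Disease function id.
#' @param genes Output of [top_disease_genes()].
#' @param functions Output of [top_disease_functions()].
#' @param scores A [score_genes()] result.
#' @param Y The [association_matrix()] used for training.
#' @param z_cut Absolute z-score threshold for edges (default 3).
#' @return A `disease_network` object with tibbles `gene_nodes`,
#'   `function_nodes` and `edges`.
#' @export
build_network <- function(disease, genes, functions, scores, Y, z_cut = 3) {
  stopifnot(inherits(scores, "score_matrix"), inherits(Y, "assoc_matrix"))
  gsign <- stats::setNames(genes$sign, genes$gene)
  fsign <- stats::setNames(functions$sign, functions$function_id)
  combos <- tidyr::expand_grid(gene = genes$gene,
                               function_id = functions$function_id)
  ij <- cbind(match(combos$gene, scores$genes),
              match(combos$function_id, scores$functions))
  combos$z <- scores$zscores[ij]
  combos$score <- scores$scores[ij]
  consistent <- sign(combos$z) ==
    gsign[combos$gene] * fsign[combos$function_id]
  edges <- combos[abs(combos$z) > z_cut & consistent, , drop = FALSE]
  yij <- cbind(match(edges$gene, Y$genes),
               match(edges$function_id, Y$functions))
  known <- !is.na(yij[, 1]) & !is.na(yij[, 2])
  known[known] <- Y$Y[yij[known, , drop = FALSE]] != 0
  edges$provenance <- ifelse(known, "known", "inferred")
  dis_col <- match(disease, Y$functions)
  gene_known <- if (!is.na(dis_col)) {
    gi <- match(genes$gene, Y$genes)
    !is.na(gi) & Y$Y[cbind(gi, dis_col)] != 0
  } else rep(FALSE, nrow(genes))
  structure(
    list(
      disease = disease,
      gene_nodes = dplyr::mutate(genes, known_association = gene_known),
      function_nodes = functions,
      edges = edges,
      z_cut = z_cut
    ),
    class = "disease_network"
  )
}

#' @exportS3Method base::print
print.disease_network <- function(x, ...) {
  cat(sprintf(
    "<disease_network> %s: %d genes, %d functions, %d edges (|z| > %.3g)\n",
    x$disease, nrow(x$gene_nodes), nrow(x$function_nodes), nrow(x$edges),
    x$z_cut))
  invisible(x)
}

#' Export a disease network as GraphML and/or JSON
#'
#' @param net A [build_network()] result.
#' @param graphml Optional GraphML output path.
#' @param json Optional JSON output path.
#' @return The network, invisibly.
#' @export
write_disease_network <- function(net, graphml = NULL, json = NULL) {
  if (!is.null(graphml)) {
    verts <- data.frame(
      name = c(net$gene_nodes$gene, net$function_nodes$function_id),
      type = c(rep("gene", nrow(net$gene_nodes)),
               rep("function", nrow(net$function_nodes))),
      sign = c(net$gene_nodes$sign, net$function_nodes$sign),
      known = c(net$gene_nodes$known_association,
                rep(NA, nrow(net$function_nodes)))
    )
    ed <- data.frame(from = net$edges$gene, to = net$edges$function_id,
                     z = net$edges$z, provenance = net$edges$provenance)
    ig <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                        vertices = verts)
    igraph::write_graph(ig, graphml, format = "graphml")
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(disease = net$disease, z_cut = net$z_cut,
           gene_nodes = net$gene_nodes,
           function_nodes = net$function_nodes, edges = net$edges),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(net)
}

#' Plot a disease network as a two-column bipartite diagram
#'
#' @param object A `disease_network`.
#' @param ... Unused.
#' @return A ggplot object (genes left, functions right, node color = sign,
#'   edge linetype = provenance).
#' @export
autoplot.disease_network <- function(object, ...) {
  gn <- object$gene_nodes
  fn <- object$function_nodes
  nodes <- dplyr::bind_rows(
    tibble(id = gn$gene, x = 0,
           y = seq_len(nrow(gn)) / max(1, nrow(gn)),
           sign = gn$sign, type = "gene"),
    tibble(id = fn$function_id, x = 1,
           y = seq_len(nrow(fn)) / max(1, nrow(fn)),
           sign = fn$sign, type = "function")
  )
  ed <- object$edges |>
    dplyr::left_join(nodes[nodes$type == "gene", c("id", "x", "y")],
                     by = c(gene = "id")) |>
    dplyr::left_join(nodes[nodes$type == "function", c("id", "x", "y")],
                     by = c(function_id = "id"), suffix = c("", "_end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_end,
                   yend = .data$y_end, linetype = .data$provenance),
      alpha = 0.5) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   color = factor(.data$sign), shape = .data$type),
      size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x + ifelse(.data$x == 0, -0.05, 0.05),
                   y = .data$y, label = .data$id,
                   hjust = ifelse(.data$x == 0, 1, 0)),
      size = 2.5) +
    ggplot2::scale_color_manual(values = c(`-1` = "#3B6FB6",
                                           `1` = "#E0862C"),
                                name = "sign") +
    ggplot2::xlim(-0.6, 1.6) +
    ggplot2::theme_void() +
    ggplot2::labs(title = object$disease)
}
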