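#' Construct a signed causal expression graph
#'
#' A causal graph is a signed bipartite graph connecting `N` regulators
#' (genes, and optionally drugs) to the `M` target genes whose expression they
#' causally increase (`sign = +1`) or decrease (`sign = -1`). The absence of an
#' edge encodes "no known effect" (sign 0). Regulators and targets may overlap
#' as gene identifiers but occupy distinct index spaces.
#'
#' Duplicate `(source, target)` rows with identical signs are collapsed;
#' duplicates with conflicting signs are dropped entirely (with a warning),
#' because stored signs are meant to be consensus calls and no per-finding
#' counts are available to break the tie.
#'
#' @param edges Data frame with columns `source`, `target`, `sign` (signs
#'   must be -1 or +1).
#' @param min_targets Minimum number of downstream targets a regulator must
#'   have to be retained (regulators always need at least one edge).
#' @param kinds Optional named character vector mapping regulator ids to
#'   `"gene"` or `"drug"`; defaults to `"gene"` for every regulator.
#'
#' @return An object of class `causal_graph`: a list with `edges` (tibble,
#'   lexicographically ordered), `regulators`, `targets`, `kinds`, and
#'   `n_targets` (the per-regulator edge count \eqn{N_i}).
#' @export
causal_graph <- function(edges, min_targets = 0L, kinds = NULL) {
  edges <- as_tibble(edges)
  req <- c("source", "target", "sign")
  if (!all(req %in% names(edges))) {
    abort("`edges` needs columns source, target, sign.")
  }
  if (nrow(edges) == 0L) abort("Edge table is empty.")
  bad <- which(!edges$sign %in% c(-1, 1))
  if (length(bad) > 0L) {
    abort(sprintf("Invalid sign at edge row %d: %s (must be -1 or +1).",
                  bad[1], as.character(edges$sign[bad[1]])))
  }
  edges <- dplyr::distinct(edges, .data$source, .data$target, .data$sign)

  # Conflicting duplicate signs: drop the pair altogether.
  dup <- dplyr::count(edges, .data$source, .data$target)
  conflicted <- dup[dup$n > 1L, c("source", "target")]
  if (nrow(conflicted) > 0L) {
    warn(sprintf(
      "Dropped %d edge(s) with conflicting duplicate signs (no consensus).",
      nrow(conflicted)))
    edges <- dplyr::anti_join(edges, conflicted, by = c("source", "target"))
  }
  if (nrow(edges) == 0L) abort("No edges remain after conflict resolution.")

  min_targets <- max(1L, as.integer(min_targets))
  n_by_reg <- table(edges$source)
  keep <- names(n_by_reg)[n_by_reg >= min_targets]
  edges <- edges[edges$source %in% keep, , drop = FALSE]
  if (nrow(edges) == 0L) {
    abort("No regulators satisfy the min_targets filter.")
  }

  regulators <- lex_sort(edges$source)
  targets <- lex_sort(edges$target)
  edges <- dplyr::arrange(edges, .data$source, .data$target)
  if (is.null(kinds)) {
    kinds <- stats::setNames(rep("gene", length(regulators)), regulators)
  } else {
    kinds <- kinds[regulators]
    kinds[is.na(kinds)] <- "gene"
    names(kinds) <- regulators
  }
  nt <- table(factor(edges$source, levels = regulators))
  structure(
    list(
      edges = edges,
      regulators = regulators,
      targets = targets,
      kinds = kinds,
      n_targets = stats::setNames(as.integer(nt), regulators)
    ),
    class = "causal_graph"
  )
}

#' @exportS3Method base::print
print.causal_graph <- function(x, ...) {
  cat(sprintf(
    "<causal_graph> %d regulators (%d drugs) -> %d targets, %d signed edges\n",
    length(x$regulators), sum(x$kinds == "drug"), length(x$targets),
    nrow(x$edges)))
  invisible(x)
}

#' Read signed expression edges from a TSV file
#'
#' Expects a tab-separated file with a header row and columns
#' `source`, `target`, `sign`.
#'
#' @inheritParams causal_graph
#' @param path Path to the TSV file.
#' @return A [causal_graph()].
#' @export
read_expression_edges <- function(path, min_targets = 0L) {
  edges <- read_signed_tsv(path, c("source", "target", "sign"))
  causal_graph(edges, min_targets = min_targets)
}

read_signed_tsv <- function(path, cols) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    abort(sprintf("File '%s' has no data rows.", path),
          class = "causalembed_parse_error")
  }
  if (!all(cols %in% names(raw))) {
    abort(sprintf("File '%s' must have columns: %s.", path,
                  paste(cols, collapse = ", ")))
  }
  sgn <- suppressWarnings(as.numeric(raw$sign))
  bad <- which(is.na(sgn) | !sgn %in% c(-1, 1))
  if (length(bad) > 0L) {
    abort(sprintf("File '%s': invalid sign '%s' at data line %d.",
                  path, raw$sign[bad[1]], bad[1]),
          class = "causalembed_parse_error")
  }
  raw$sign <- as.integer(sgn)
  raw
}

#' Write a causal graph as TSV (and optionally GraphML)
#'
#' @param graph A [causal_graph()].
#' @param path Output TSV path.
#' @param graphml Optional path for a GraphML export (signed edges carried as
#'   an edge attribute, entity kind as a vertex attribute).
#' @return `path`, invisibly.
#' @export
write_expression_edges <- function(graph, path, graphml = NULL) {
  readr::write_tsv(graph$edges, path, progress = FALSE)
  if (!is.null(graphml)) {
    ig <- as_igraph(graph)
    igraph::write_graph(ig, graphml, format = "graphml")
  }
  invisible(path)
}

#' Convert a causal graph to an igraph object
#'
#' Regulator and target index spaces are kept distinct by prefixing node names
#' (`r:` and `t:`).
#'
#' @param graph A [causal_graph()].
#' @return A directed [igraph::graph] with a `sign` edge attribute.
#' @export
as_igraph <- function(graph) {
  verts <- data.frame(
    name = c(paste0("r:", graph$regulators), paste0("t:", graph$targets)),
    kind = c(unname(graph$kinds[graph$regulators]),
             rep("target", length(graph$targets)))
  )
  ed <- data.frame(
    from = paste0("r:", graph$edges$source),
    to = paste0("t:", graph$edges$target),
    sign = graph$edges$sign
  )
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = verts)
}

#' Construct a signed gene-function association matrix
#'
#' Stores the curated causal effect \eqn{Y_{ij} \in \{-1, 0, +1\}} of gene
#' `i` on function or disease `j` as a sparse matrix (genes in rows).
#'
#' @param assoc Data frame with columns `gene`, `function_id` (or `function`),
#'   `sign`.
#' @param genes Character vector fixing the gene universe (row order); rows
#'   referring to genes outside it are dropped with a message.
#' @param functions Optional character vector fixing the function universe;
#'   defaults to the functions present, lexicographically ordered.
#' @return An `assoc_matrix` object: list with sparse matrix `Y` (genes x
#'   functions), `genes` and `functions`.
#' @export
association_matrix <- function(assoc, genes, functions = NULL) {
  assoc <- as_tibble(assoc)
  if ("function" %in% names(assoc) && !"function_id" %in% names(assoc)) {
    names(assoc)[names(assoc) == "function"] <- "function_id"
  }
  genes <- lex_sort(genes)
  if (nrow(assoc) > 0L) {
    if (!all(assoc$sign %in% c(-1, 1))) {
      abort("Association signs must be -1 or +1.")
    }
    unknown <- !assoc$gene %in% genes
    if (any(unknown)) {
      inform(sprintf("Dropped %d association(s) for genes outside the graph.",
                     sum(unknown)))
      assoc <- assoc[!unknown, , drop = FALSE]
    }
  }
  functions <- functions %||%
    (if (nrow(assoc) > 0L) lex_sort(assoc$function_id) else character())
  Y <- Matrix::sparseMatrix(
    i = match(assoc$gene, genes),
    j = match(assoc$function_id, functions),
    x = as.numeric(assoc$sign),
    dims = c(length(genes), length(functions)),
    dimnames = list(genes, functions)
  )
  structure(list(Y = Y, genes = genes, functions = functions),
            class = "assoc_matrix")
}

#' @exportS3Method base::print
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d genes x %d functions, %d signed entries\n",
              length(x$genes), length(x$functions), Matrix::nnzero(x$Y)))
  invisible(x)
}

#' Read gene-function associations from a TSV file
#'
#' Expects columns `gene`, `function` (or `function_id`), `sign`. An empty
#' file yields a matrix with zero function columns.
#'
#' @param path Path to the TSV file.
#' @inheritParams association_matrix
#' @return An [association_matrix()].
#' @export
read_function_associations <- function(path, genes) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if ("function" %in% names(raw)) {
    names(raw)[names(raw) == "function"] <- "function_id"
  }
  if (nrow(raw) == 0L) {
    return(association_matrix(
      tibble(gene = character(), function_id = character(), sign = integer()),
      genes = genes))
  }
  if (!all(c("gene", "function_id", "sign") %in% names(raw))) {
    abort(sprintf("File '%s' must have columns gene, function, sign.", path))
  }
  sgn <- suppressWarnings(as.numeric(raw$sign))
  bad <- which(is.na(sgn) | !sgn %in% c(-1, 1))
  if (length(bad) > 0L) {
    abort(sprintf("File '%s': invalid sign '%s' at data line %d.",
                  path, raw$sign[bad[1]], bad[1]),
          class = "causalembed_parse_error")
  }
  raw$sign <- as.integer(sgn)
  association_matrix(raw, genes = genes)
}

#' Write an association matrix as TSV
#'
#' @param Y An [association_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_function_associations <- function(Y, path) {
  sm <- Matrix::summary(Y$Y)
  out <- tibble(
    gene = Y$genes[sm$i],
    `function` = Y$functions[sm$j],
    sign = as.integer(sm$x)
  )
  out <- dplyr::arrange(out, .data$gene, .data$`function`)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Function ontology (parent/child hierarchy)
#'
#' Functions and diseases live in a hierarchy in which parents inherit causal
#' gene associations (and their signs) from their descendants, except for very
#' general terms that a user may exclude.
#'
#' @param parent_edges Data frame with columns `child`, `parent`.
#' @return An `ontology` object (tibble of edges, validated acyclic).
#' @export
ontology <- function(parent_edges) {
  pe <- as_tibble(parent_edges)
  if (!all(c("child", "parent") %in% names(pe))) {
    abort("`parent_edges` needs columns child, parent.")
  }
  pe <- dplyr::distinct(pe, .data$child, .data$parent)
  if (nrow(pe) > 0L) {
    g <- igraph::graph_from_data_frame(pe[, c("child", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) abort("Ontology contains a cycle.")
  }
  structure(list(parent_edges = pe), class = "ontology")
}

#' Read a function ontology from a two-column TSV (child, parent)
#'
#' @param path Path to the TSV file.
#' @return An [ontology()].
#' @export
read_ontology <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  ontology(raw)
}

#' Read function metadata (id, name, process, context, category, is_disease)
#'
#' @param path Path to the TSV file.
#' @return A tibble, one row per function term. `process` and `context` must
#'   be both present or both absent for each term.
#' @export
read_function_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"id" %in% names(raw)) abort("Metadata needs an `id` column.")
  for (col in c("name", "process", "context", "category")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  raw$is_disease <- if ("is_disease" %in% names(raw)) {
    tolower(raw$is_disease) %in% c("true", "1", "yes")
  } else FALSE
  bad <- xor(is.na(raw$process), is.na(raw$context))
  if (any(bad)) {
    abort(sprintf(
      "Term '%s': process and context must be both present or both absent.",
      raw$id[which(bad)[1]]))
  }
  raw[, c("id", "name", "process", "context", "category", "is_disease")]
}

#' Leaf terms of an ontology
#'
#' A leaf has no children among the ontology edges. Terms absent from the
#' ontology entirely are considered leaves.
#'
#' @param ont An [ontology()].
#' @param ids Candidate term ids.
#' @return Logical vector parallel to `ids`.
#' @export
is_leaf <- function(ont, ids) {
  !ids %in% ont$parent_edges$parent
}

ontology_descendants <- function(ont, term) {
  pe <- ont$parent_edges
  if (nrow(pe) == 0L) return(character())
  out <- character()
  frontier <- term
  repeat {
    kids <- pe$child[pe$parent %in% frontier]
    kids <- setdiff(kids, c(out, term))
    if (length(kids) == 0L) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

ontology_ancestors <- function(ont, term) {
  pe <- ont$parent_edges
  if (nrow(pe) == 0L) return(character())
  out <- character()
  frontier <- term
  repeat {
    up <- pe$parent[pe$child %in% frontier]
    up <- setdiff(up, c(out, term))
    if (length(up) == 0L) break
    out <- c(out, up)
    frontier <- up
  }
  out
}

#' Propagate gene associations up a function hierarchy
#'
#' Every parent term (outside `excluded_roots`) inherits the signed gene
#' associations of all of its descendants, combined with its own direct
#' entries. When descendants disagree about the sign for the same gene, the
#' parent entry is set to 0 (conservative: no consensus). Leaves are left
#' unchanged. The operation is idempotent.
#'
#' @param Y An [association_matrix()].
#' @param ont An [ontology()] over (a superset of) `Y$functions`.
#' @param excluded_roots Character vector of very general terms that should
#'   not inherit (default none).
#' @return A new [association_matrix()].
#' @export
propagate_ontology <- function(Y, ont, excluded_roots = character()) {
  stopifnot(inherits(Y, "assoc_matrix"), inherits(ont, "ontology"))
  parents <- setdiff(unique(ont$parent_edges$parent), excluded_roots)
  parents <- intersect(parents, Y$functions)
  if (length(parents) == 0L) return(Y)
  Ynew <- as(Y$Y, "TsparseMatrix")
  add_i <- integer(); add_j <- integer(); add_x <- numeric()
  drop_cols <- integer()
  for (p in parents) {
    fam <- intersect(c(p, ontology_descendants(ont, p)), Y$functions)
    sub <- Y$Y[, fam, drop = FALSE]
    pos <- Matrix::rowSums(sub > 0) > 0
    neg <- Matrix::rowSums(sub < 0) > 0
    val <- ifelse(pos & neg, 0, ifelse(pos, 1, ifelse(neg, -1, 0)))
    jj <- match(p, Y$functions)
    drop_cols <- c(drop_cols, jj)
    nz <- which(val != 0)
    add_i <- c(add_i, nz)
    add_j <- c(add_j, rep(jj, length(nz)))
    add_x <- c(add_x, val[nz])
  }
  keep <- !(Ynew@j + 1L) %in% drop_cols
  Yout <- Matrix::sparseMatrix(
    i = c(Ynew@i[keep] + 1L, add_i),
    j = c(Ynew@j[keep] + 1L, add_j),
    x = c(Ynew@x[keep], add_x),
    dims = dim(Y$Y), dimnames = dimnames(Y$Y)
  )
  structure(list(Y = Yout, genes = Y$genes, functions = Y$functions),
            class = "assoc_matrix")
}
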