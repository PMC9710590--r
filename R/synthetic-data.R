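#' Latent model for synthetic signed causal data
#'
#' The generator plants a low-dimensional latent structure: every regulator
#' gene, target gene and function/disease receives an i.i.d. standard-normal
#' latent vector in `d` dimensions. Signed expression edges and gene-function
#' associations are then derived from latent dot products, so that low-rank
#' factorization methods can provably recover the planted signal. A global
#' offset on the dot products calibrates the positive:negative sign ratio to
#' roughly 2:1, the imbalance typical of curated activation/inhibition
#' content.
#'
#' @param n_genes Number of regulator genes (N).
#' @param n_targets Number of expression-regulated target genes (M).
#' @param n_functions Number of functions/diseases (J).
#' @param d Planted latent dimension.
#' @param density Expected fraction of nonzero signed expression edges.
#' @param noise_rate Probability of flipping an emitted sign; must be in
#'   `[0, 0.5)`.
#' @param sign_ratio Target positive:negative sign ratio (default 2).
#' @param seed Integer seed; all generator output is a pure function of it.
#' @return A `latent_model` object.
#' @export
latent_model <- function(n_genes = 200L, n_targets = 1000L,
                         n_functions = 100L, d = 10L, density = 0.05,
                         noise_rate = 0, sign_ratio = 2, seed = 1L) {
  if (noise_rate < 0 || noise_rate >= 0.5) {
    abort("`noise_rate` must be in [0, 0.5).")
  }
  if (density <= 0 || density > 1) abort("`density` must be in (0, 1].")
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  target_ids <- sprintf("t%05d", seq_len(n_targets))
  function_ids <- sprintf("f%05d", seq_len(n_functions))
  vecs <- with_seed(sub_seed(seed, 1L), {
    list(
      gene = matrix(stats::rnorm(n_genes * d), n_genes, d,
                    dimnames = list(gene_ids, NULL)),
      target = matrix(stats::rnorm(n_targets * d), n_targets, d,
                      dimnames = list(target_ids, NULL)),
      fun = matrix(stats::rnorm(n_functions * d), n_functions, d,
                   dimnames = list(function_ids, NULL))
    )
  })
  structure(
    list(
      n_genes = as.integer(n_genes), n_targets = as.integer(n_targets),
      n_functions = as.integer(n_functions), d = as.integer(d),
      density = density, noise_rate = noise_rate, sign_ratio = sign_ratio,
      seed = as.integer(seed),
      gene_vectors = vecs$gene, target_vectors = vecs$target,
      function_vectors = vecs$fun
    ),
    class = "latent_model"
  )
}

#' @exportS3Method base::print
print.latent_model <- function(x, ...) {
  cat(sprintf(
    "<latent_model> N=%d genes, M=%d targets, J=%d functions, d=%d, density=%.3g, noise=%.3g, seed=%d\n",
    x$n_genes, x$n_targets, x$n_functions, x$d, x$density, x$noise_rate,
    x$seed))
  invisible(x)
}

# Offset b such that a fraction `frac` of the latent dot products is
# positive: the exact root of P(D + b > 0) = frac over the realized products
# (the value bisection on the empirical CDF converges to).
calibrate_sign_offset <- function(dots, frac) {
  -stats::quantile(dots, probs = 1 - frac, names = FALSE, type = 1)
}

#' Generate a signed bipartite expression graph with planted structure
#'
#' For every (regulator, target) pair an edge is emitted with probability
#' `density`; its sign is `sign(g_i . t_j + b)` where the scalar offset `b`
#' is calibrated so the positive:negative ratio matches
#' `model$sign_ratio : 1`. Signs are then flipped independently with
#' probability `noise_rate`. Regulators left without any edge are dropped
#' with a message.
#'
#' @param model A [latent_model()].
#' @return A list with `graph` (a [causal_graph()]), `gene_vectors` (ground
#'   truth, restricted to retained regulators), and the calibrated `offset`.
#' @export
generate_expression_graph <- function(model) {
  stopifnot(inherits(model, "latent_model"))
  D <- model$gene_vectors %*% t(model$target_vectors)
  b <- calibrate_sign_offset(as.vector(D),
                             model$sign_ratio / (model$sign_ratio + 1))
  signs <- ifelse(D + b > 0, 1L, -1L)
  nm <- model$n_genes * model$n_targets
  present <- with_seed(sub_seed(model$seed, 2L),
                       stats::runif(nm) < model$density)
  if (model$noise_rate > 0) {
    flip <- with_seed(sub_seed(model$seed, 3L),
                      stats::runif(nm) < model$noise_rate)
    signs[flip] <- -signs[flip]
  }
  idx <- which(matrix(present, model$n_genes, model$n_targets),
               arr.ind = TRUE)
  edges <- tibble(
    source = rownames(model$gene_vectors)[idx[, 1]],
    target = rownames(model$target_vectors)[idx[, 2]],
    sign = signs[idx]
  )
  if (nrow(edges) == 0L) abort("Density too low: no edges emitted.")
  lost <- setdiff(rownames(model$gene_vectors), unique(edges$source))
  if (length(lost) > 0L) {
    inform(sprintf("Dropped %d regulator(s) with no emitted edges.",
                   length(lost)))
  }
  graph <- causal_graph(edges)
  list(
    graph = graph,
    gene_vectors = model$gene_vectors[graph$regulators, , drop = FALSE],
    offset = b
  )
}

#' Generate a planted signed gene-function association matrix
#'
#' For each function `j`, the `genes_per_function` genes with the largest
#' absolute latent affinity `|g_i . f_j|` receive `Y_ij = sign(g_i . f_j)`,
#' flipped with probability `noise_rate`.
#'
#' @param model A [latent_model()].
#' @param genes_per_function Number of associated genes per function.
#' @return An [association_matrix()] over all model genes.
#' @export
generate_function_associations <- function(model, genes_per_function = 20L) {
  stopifnot(inherits(model, "latent_model"))
  A <- model$gene_vectors %*% t(model$function_vectors)
  gene_ids <- rownames(model$gene_vectors)
  fun_ids <- rownames(model$function_vectors)
  per_fun <- lapply(seq_len(model$n_functions), function(j) {
    top <- order(abs(A[, j]), decreasing = TRUE)[seq_len(genes_per_function)]
    tibble(gene = gene_ids[top], function_id = fun_ids[j],
           sign = ifelse(A[top, j] > 0, 1L, -1L))
  })
  assoc <- dplyr::bind_rows(per_fun)
  if (model$noise_rate > 0) {
    flip <- with_seed(sub_seed(model$seed, 4L),
                      stats::runif(nrow(assoc)) < model$noise_rate)
    assoc$sign[flip] <- -assoc$sign[flip]
  }
  association_matrix(assoc, genes = gene_ids, functions = lex_sort(fun_ids))
}

#' Generate a drug extension with planted drug-disease labels
#'
#' Drugs receive latent vectors like genes and emit signed expression edges
#' against the same targets (same density, same sign-calibration offset). A
#' drug is labeled positive for disease `j` when its latent affinity
#' `drug . f_j` exceeds the disease's planted threshold (the
#' `1 - positive_rate` quantile of affinities across drugs), i.e. positives
#' are the drugs most strongly aligned with the disease direction.
#'
#' @param model A [latent_model()].
#' @param n_drugs Number of drugs.
#' @param n_diseases Number of diseases (taken from the model's function
#'   vectors, which must contain at least this many).
#' @param positive_rate Fraction of drugs labeled positive per disease.
#' @return A list with `drug_edges` (tibble source/target/sign),
#'   `drug_vectors`, `labels` (tibble drug/disease/positive) and the
#'   per-disease `thresholds`.
#' @export
generate_drug_extension <- function(model, n_drugs = 100L, n_diseases = 5L,
                                    positive_rate = 0.2) {
  stopifnot(inherits(model, "latent_model"))
  if (n_diseases > model$n_functions) {
    abort("Model has fewer function vectors than requested diseases.")
  }
  drug_ids <- sprintf("drug%04d", seq_len(n_drugs))
  drug_vectors <- with_seed(sub_seed(model$seed, 5L),
                            matrix(stats::rnorm(n_drugs * model$d), n_drugs,
                                   model$d, dimnames = list(drug_ids, NULL)))
  D <- drug_vectors %*% t(model$target_vectors)
  b <- calibrate_sign_offset(
    as.vector(model$gene_vectors %*% t(model$target_vectors)),
    model$sign_ratio / (model$sign_ratio + 1))
  signs <- ifelse(D + b > 0, 1L, -1L)
  nm <- n_drugs * model$n_targets
  present <- with_seed(sub_seed(model$seed, 6L),
                       stats::runif(nm) < model$density)
  if (model$noise_rate > 0) {
    flip <- with_seed(sub_seed(model$seed, 7L),
                      stats::runif(nm) < model$noise_rate)
    signs[flip] <- -signs[flip]
  }
  idx <- which(matrix(present, n_drugs, model$n_targets), arr.ind = TRUE)
  drug_edges <- tibble(
    source = drug_ids[idx[, 1]],
    target = rownames(model$target_vectors)[idx[, 2]],
    sign = signs[idx]
  )
  disease_ids <- rownames(model$function_vectors)[seq_len(n_diseases)]
  Aff <- drug_vectors %*% t(model$function_vectors[disease_ids, , drop = FALSE])
  thresholds <- apply(Aff, 2, stats::quantile, probs = 1 - positive_rate,
                      names = FALSE, type = 1)
  labels <- tidyr::expand_grid(drug = drug_ids, disease = disease_ids)
  labels$positive <- as.vector(t(sweep(Aff, 2, thresholds, `>`)))
  list(drug_edges = drug_edges, drug_vectors = drug_vectors,
       labels = labels,
       thresholds = stats::setNames(thresholds, disease_ids))
}

# Evaluate code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
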