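# Small in-code fixtures shared across test files.

# Write a TSV with the given rows (list of character vectors) and header.
write_tsv_fixture <- function(header, rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

# Tiny deterministic causal graph: 4 regulators x 6 targets with mixed signs.
toy_graph <- function() {
  edges <- tibble::tribble(
    ~source, ~target, ~sign,
    "gA", "t1", 1L, "gA", "t2", 1L, "gA", "t3", -1L,
    "gB", "t1", 1L, "gB", "t2", 1L, "gB", "t3", -1L,   # identical to gA
    "gC", "t1", -1L, "gC", "t2", -1L, "gC", "t3", 1L,  # opposite of gA
    "gD", "t4", 1L, "gD", "t5", -1L, "gD", "t6", 1L    # disjoint targets
  )
  causal_graph(edges)
}

empty_ontology <- function() {
  ontology(tibble::tibble(child = character(), parent = character()))
}

# Mid-sized planted instance reused by scoring / CV / network tests.
planted_instance <- function(n_genes = 200L, n_targets = 800L,
                             n_functions = 40L, d = 8L, density = 0.08,
                             noise_rate = 0, seed = 42L, K = 16L,
                             genes_per_function = 15L) {
  m <- latent_model(n_genes = n_genes, n_targets = n_targets,
                    n_functions = n_functions, d = d, density = density,
                    noise_rate = noise_rate, seed = seed)
  sim <- generate_expression_graph(m)
  W <- build_weight_matrix(sim$graph)
  emb <- spectral_embed(W, K)
  Y <- generate_function_associations(m, genes_per_function)
  list(model = m, graph = sim$graph, gene_vectors = sim$gene_vectors,
       W = W, emb = emb, Y = Y)
}
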