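#' Extend gene embeddings to drugs
#'
#' Drugs enter the expression bipartite graph as additional regulator rows
#' (their signed effects on target-gene expression), and the chosen
#' embedding pipeline runs unchanged on the enlarged graph. Drug rows obey
#' the same unit-norm weight normalization as genes.
#'
#' @param graph Gene [causal_graph()].
#' @param drug_edges Tibble of signed drug-to-target edges (`source`,
#'   `target`, `sign`).
#' @param method `"spectral"`, `"neural"` or `"graph"`.
#' @param K Embedding dimension.
#' @param ... Further arguments for the chosen embedding function.
#' @return An `embedding_matrix` covering genes and drugs, with attribute
#'   `kinds` (named vector, `"gene"`/`"drug"`).
#' @export
embed_with_drugs <- function(graph, drug_edges,
                             method = c("spectral", "neural", "graph"),
                             K, ...) {
  method <- match.arg(method)
  drug_ids <- unique(drug_edges$source)
  overlap <- intersect(drug_ids, graph$regulators)
  if (length(overlap) > 0L) {
    abort(sprintf("Drug ids collide with gene regulators: %s.",
                  paste(utils::head(overlap, 3), collapse = ", ")))
  }
  kinds <- c(
    stats::setNames(rep("gene", length(graph$regulators)),
                    graph$regulators),
    stats::setNames(rep("drug", length(drug_ids)), drug_ids)
  )
  combined <- causal_graph(
    dplyr::bind_rows(graph$edges, as_tibble(drug_edges)), kinds = kinds)
  emb <- switch(method,
    spectral = spectral_embed(build_weight_matrix(combined), K),
    neural = train_neural_embedding(build_weight_matrix(combined), K, ...),
    graph = graph_embed(combined, K, ...)
  )
  attr(emb, "kinds") <- combined$kinds[rownames(emb$U)]
  emb
}

#' Train and evaluate an MLP drug-disease predictor
#'
#' A multilayer perceptron with one hidden layer (default 200 nodes,
#' sigmoid output, binary cross-entropy loss, full-batch Adam updates) is
#' trained on drug embedding vectors to separate the known positive drugs of
#' a disease from an equally sized negative sample drawn from all other
#' drugs, using a random 70/30 train/test split. Features are standardized
#' on each training split. Training and testing are repeated with fresh
#' negative draws and splits, and ROC/PR curves are averaged across repeats.
#'
#' @param X_drugs Matrix of drug embedding rows (rownames = drug ids).
#' @param positives Character vector of positive drug ids (>= 10).
#' @param hidden Hidden-layer width (default 200).
#' @param split Training fraction (default 0.7).
#' @param repeats Number of repeats (default 100).
#' @param seed Integer seed.
#' @param epochs Adam epochs per fit.
#' @param decay L2 weight decay of the MLP (default 0.01; the small balanced
#'   training sets need regularization to generalize).
#' @return A `drug_mlp_result`: `metrics` (per-repeat AUC/precision),
#'   `predictions` (per-repeat test scores and labels), `splits`
#'   (per-repeat train/test drug ids).
#' @export
train_drug_mlp <- function(X_drugs, positives, hidden = 200L, split = 0.7,
                           repeats = 100L, seed = 1L, epochs = 300L,
                           decay = 1e-2) {
  positives <- intersect(positives, rownames(X_drugs))
  if (length(positives) < 10L) {
    abort("Need at least 10 positive drugs with embedding vectors.")
  }
  pool <- setdiff(rownames(X_drugs), positives)
  if (length(pool) < length(positives)) {
    abort("Not enough non-positive drugs to draw a balanced negative set.")
  }
  n_pos <- length(positives)
  runs <- lapply(seq_len(repeats), function(r) {
    with_seed(sub_seed(seed, 200L + r), {
      negatives <- sample(pool, n_pos)
      ids <- c(positives, negatives)
      y <- c(rep(1L, n_pos), rep(0L, n_pos))
      n_tr <- max(2L, floor(split * length(ids)))
      tr <- sample.int(length(ids), n_tr)
      te <- setdiff(seq_along(ids), tr)
      if (length(unique(y[tr])) < 2L || length(te) == 0L) {
        return(NULL)
      }
      # standardize features on the training split only
      Xtr <- X_drugs[ids[tr], , drop = FALSE]
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      scale_x <- function(M) sweep(sweep(M, 2, mu), 2, sdv, `/`)
      fit <- mlp_binary_fit(scale_x(Xtr), y[tr], hidden = hidden,
                            epochs = epochs, l2 = decay)
      sc <- mlp_binary_predict(fit,
                               scale_x(X_drugs[ids[te], , drop = FALSE]))
      list(
        preds = tibble(replicate = r, drug = ids[te], score = sc,
                       label = y[te]),
        split = list(train = ids[tr], test = ids[te])
      )
    })
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  preds <- dplyr::bind_rows(lapply(runs, `[[`, "preds"))
  metrics <- preds |>
    dplyr::group_by(.data$replicate) |>
    dplyr::filter(dplyr::n_distinct(.data$label) == 2L) |>
    dplyr::summarise(
      auc = auc(roc_prc(.data$score, .data$label)),
      .groups = "drop")
  structure(
    list(metrics = metrics, predictions = preds,
         splits = lapply(runs, `[[`, "split"),
         hidden = hidden, split = split, n_positives = n_pos),
    class = "drug_mlp_result"
  )
}

#' @exportS3Method base::print
print.drug_mlp_result <- function(x, ...) {
  g <- glance.drug_mlp_result(x)
  cat(sprintf(
    "<drug_mlp_result> %d positives, %d repeats: mean AUC %.3f (SD %.3f)\n",
    x$n_positives, g$repeats, g$auc_mean, g$auc_sd))
  invisible(x)
}

#' Per-repeat drug-disease prediction metrics
#' @param x A `drug_mlp_result`.
#' @param ... Unused.
#' @return Tibble with one row per repeat.
#' @export
tidy.drug_mlp_result <- function(x, ...) x$metrics

#' Aggregate drug-disease prediction performance
#' @param x A `drug_mlp_result`.
#' @param ... Unused.
#' @return One-row tibble: mean and SD of AUC across repeats.
#' @export
glance.drug_mlp_result <- function(x, ...) {
  tibble(
    repeats = nrow(x$metrics),
    auc_mean = mean(x$metrics$auc),
    auc_sd = stats::sd(x$metrics$auc),
    n_positives = x$n_positives
  )
}

#' Plot the averaged ROC curve of a drug-disease predictor
#'
#' @param object A `drug_mlp_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drug_mlp_result <- function(object, ...) {
  curves <- object$predictions |>
    dplyr::group_by(.data$replicate) |>
    dplyr::filter(dplyr::n_distinct(.data$label) == 2L) |>
    dplyr::group_split() |>
    purrr::map(~roc_prc(.x$score, .x$label))
  agg <- aggregate_curves(curves)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$x, y = .data$y_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$y_mean - .data$y_sd,
                                      ymax = .data$y_mean + .data$y_sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dashed", alpha = 0.4) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = "Drug-disease prediction (averaged ROC)")
}

# One-hidden-layer MLP for balanced binary classification: sigmoid output,
# binary cross-entropy + L2, full-batch Adam. Uses the ambient RNG (callers
# seed it), so repeats stay reproducible.
mlp_binary_fit <- function(X, y, hidden = 200L, epochs = 300L, lr = 1e-2,
                           l2 = 1e-2) {
  n <- nrow(X); d <- ncol(X)
  par <- list(
    W1 = matrix(stats::rnorm(d * hidden, sd = sqrt(1 / d)), d, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(hidden, sd = sqrt(1 / hidden)), hidden, 1),
    b2 = 0
  )
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    pre <- sweep(X %*% par$W1, 2, par$b1, `+`)
    h <- pmax(pre, 0)
    logit <- as.vector(h %*% par$W2) + par$b2
    prob <- 1 / (1 + exp(-logit))
    g_logit <- (prob - y) / n
    grad <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(h, g_logit) + l2 * par$W2,
      b2 = sum(g_logit)
    )
    g_h <- outer(g_logit, as.vector(par$W2)) * (pre > 0)
    grad$W1 <- crossprod(X, g_h) + l2 * par$W1
    grad$b1 <- colSums(g_h)
    for (nm in names(par)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grad[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grad[[nm]]^2
      par[[nm]] <- par[[nm]] - lr * (mom[[nm]] / (1 - beta1^t)) /
        (sqrt(vel[[nm]] / (1 - beta2^t)) + eps)
    }
  }
  par
}

mlp_binary_predict <- function(par, X) {
  h <- pmax(sweep(X %*% par$W1, 2, par$b1, `+`), 0)
  as.vector(1 / (1 + exp(-(as.vector(h %*% par$W2) + par$b2))))
}
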