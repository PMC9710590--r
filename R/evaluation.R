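#' Draw balanced masked test sets from an association matrix
#'
#' Each replicate samples `n` entries with `Y = +1`, `n` with `Y = -1`, and
#' `2n` zero entries, restricted to functions that are leaves of the
#' hierarchy and supported by at least `min_genes` associated genes (so that
#' masking cannot leak through ontology inheritance). Zero cells are drawn
#' uniformly over eligible (gene, leaf-function) cells. Replicates are drawn
#' independently (they may overlap).
#'
#' @param Y An [association_matrix()].
#' @param ont An [ontology()]; functions absent from it count as leaves.
#' @param n Entries per sign class; a test set holds `4n` entries.
#' @param k Number of replicates.
#' @param min_genes Minimum associated genes for an eligible function
#'   (default 10).
#' @param seed Integer seed.
#' @return List of `k` test sets, each a tibble with columns `gene`,
#'   `function_id`, `truth` (-1, 0, +1).
#' @export
make_test_sets <- function(Y, ont, n = 1000L, k = 50L, min_genes = 10L,
                           seed = 1L) {
  stopifnot(inherits(Y, "assoc_matrix"))
  leaf <- is_leaf(ont, Y$functions)
  support <- Matrix::colSums(Y$Y != 0)
  eligible_fun <- which(leaf & support >= min_genes)
  if (length(eligible_fun) == 0L) {
    abort("No eligible leaf functions with enough associated genes.")
  }
  sub <- Y$Y[, eligible_fun, drop = FALSE]
  tr <- as(sub, "TsparseMatrix")
  pos <- which(tr@x > 0)
  neg <- which(tr@x < 0)
  if (length(pos) < n || length(neg) < n) {
    abort(sprintf(
      "Eligible pool too small: need %d of each sign, have %d positive / %d negative.",
      n, length(pos), length(neg)))
  }
  n_zero_cells <- length(Y$genes) * length(eligible_fun) - length(tr@x)
  if (n_zero_cells < 2L * n) abort("Not enough eligible zero cells.")
  fun_ids <- Y$functions[eligible_fun]
  lapply(seq_len(k), function(r) {
    with_seed(sub_seed(seed, 100L + r), {
      ip <- sample(pos, n)
      im <- sample(neg, n)
      nz_key <- paste(tr@i[c(ip, im)], tr@j[c(ip, im)])
      all_nz <- paste(tr@i, tr@j)
      zeros <- matrix(0L, 0, 2)
      while (nrow(zeros) < 2L * n) {
        gi <- sample.int(length(Y$genes), 2L * n, replace = TRUE) - 1L
        fj <- sample.int(length(fun_ids), 2L * n, replace = TRUE) - 1L
        cand <- cbind(gi, fj)
        ok <- !paste(gi, fj) %in% all_nz
        zeros <- unique(rbind(zeros, cand[ok, , drop = FALSE]))
      }
      zeros <- zeros[seq_len(2L * n), , drop = FALSE]
      tibble(
        gene = c(Y$genes[tr@i[ip] + 1L], Y$genes[tr@i[im] + 1L],
                 Y$genes[zeros[, 1] + 1L]),
        function_id = c(fun_ids[tr@j[ip] + 1L], fun_ids[tr@j[im] + 1L],
                        fun_ids[zeros[, 2] + 1L]),
        truth = c(rep(1L, n), rep(-1L, n), rep(0L, 2L * n))
      )
    })
  })
}

#' Run the masking cross-validation for gene-function prediction
#'
#' For every replicate, the test entries are set to zero in `Y`, the
#' per-function regression is refit (gene embeddings depend only on the
#' expression graph and are never retrained), and the masked cells are
#' scored. Two tasks are evaluated: *absolute* prediction (is there any
#' relationship? score `|s|`, all `4n` entries) and *sign* prediction
#' (activation vs inhibition, signed score `s`, the `2n` nonzero entries).
#' `Y` is left unmodified.
#'
#' @param emb Gene `embedding_matrix`.
#' @param Y An [association_matrix()].
#' @param test_sets Output of [make_test_sets()].
#' @return A `crossval_result`: tibble `predictions` with columns
#'   `replicate`, `task` ("absolute"/"sign"), `score`, `label` (0/1), plus
#'   per-replicate `metrics` (AUC and precision at 5% recall per task).
#' @export
run_cross_validation <- function(emb, Y, test_sets) {
  preds <- purrr::map_dfr(seq_along(test_sets), function(r) {
    ts <- test_sets[[r]]
    Ymask <- Y$Y
    ij <- cbind(match(ts$gene, Y$genes), match(ts$function_id, Y$functions))
    Ymask[ij] <- 0
    Ym <- structure(list(Y = Ymask, genes = Y$genes,
                         functions = Y$functions), class = "assoc_matrix")
    fe <- fit_function_embeddings(emb, Ym)
    ok <- ts$function_id %in% rownames(fe$P_norm)
    ts <- ts[ok, , drop = FALSE]
    s <- rowSums(emb$U[ts$gene, , drop = FALSE] *
                   fe$P_norm[ts$function_id, , drop = FALSE])
    nz <- ts$truth != 0
    dplyr::bind_rows(
      tibble(replicate = r, task = "absolute", score = abs(s),
             label = as.integer(nz)),
      tibble(replicate = r, task = "sign", score = s[nz],
             label = as.integer(ts$truth[nz] > 0))
    )
  })
  metrics <- preds |>
    dplyr::group_by(.data$replicate, .data$task) |>
    dplyr::summarise(
      auc = auc(roc_prc(.data$score, .data$label)),
      precision_at_5pct = precision_at_recall(
        roc_prc(.data$score, .data$label), 0.05),
      .groups = "drop"
    )
  structure(list(predictions = preds, metrics = metrics),
            class = "crossval_result")
}

#' @exportS3Method base::print
print.crossval_result <- function(x, ...) {
  agg <- glance.crossval_result(x)
  cat("<crossval_result>\n")
  print(as.data.frame(agg))
  invisible(x)
}

#' Per-replicate cross-validation metrics
#'
#' @param x A `crossval_result`.
#' @param ... Unused.
#' @return Tibble with one row per (replicate, task).
#' @export
tidy.crossval_result <- function(x, ...) x$metrics

#' Aggregate cross-validation metrics (mean and SD across replicates)
#'
#' @param x A `crossval_result`.
#' @param ... Unused.
#' @return Tibble with one row per task.
#' @export
glance.crossval_result <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(
      k = dplyr::n(),
      auc_mean = mean(.data$auc), auc_sd = stats::sd(.data$auc),
      precision_mean = mean(.data$precision_at_5pct),
      precision_sd = stats::sd(.data$precision_at_5pct),
      .groups = "drop"
    )
}

#' ROC and precision-recall curve points
#'
#' Thresholds sweep the distinct score values from high to low; tied scores
#' cross the threshold together. Points include the (0, 0) origin.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 (or logical) true labels.
#' @return A tibble with columns `threshold`, `tp`, `fp`, `tpr` (= recall),
#'   `fpr`, `precision`, of class `roc_curve`.
#' @export
roc_prc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  P <- sum(labels == 1L)
  Nn <- sum(labels == 0L)
  if (P == 0L || Nn == 0L) abort("Need both positive and negative labels.")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp_cum <- cumsum(l); fp_cum <- cumsum(1L - l)
  last <- which(c(diff(grp) != 0, TRUE))
  tp_g <- tp_cum[last]; fp_g <- fp_cum[last]
  out <- tibble(
    threshold = c(Inf, s[last]),
    tp = c(0L, tp_g), fp = c(0L, fp_g),
    tpr = c(0, tp_g / P), fpr = c(0, fp_g / Nn),
    precision = c(NA_real_, tp_g / (tp_g + fp_g))
  )
  class(out) <- c("roc_curve", class(out))
  out
}

#' Area under a curve by the trapezoidal rule (ROC by default)
#'
#' @param curve A [roc_prc()] tibble.
#' @param x,y Column names to integrate (defaults: `fpr` vs `tpr`).
#' @return The AUC as a single number.
#' @export
auc <- function(curve, x = "fpr", y = "tpr") {
  xs <- curve[[x]]; ys <- curve[[y]]
  keep <- !is.na(xs) & !is.na(ys)
  xs <- xs[keep]; ys <- ys[keep]
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Precision at a recall floor
#'
#' Returns the precision at the smallest achieved recall that is at least
#' `r` ("precision in the limit of low recall").
#'
#' @param curve A [roc_prc()] tibble.
#' @param r Recall floor in (0, 1].
#' @return Precision at that operating point.
#' @export
precision_at_recall <- function(curve, r = 0.05) {
  ok <- which(!is.na(curve$precision) & curve$tpr >= r)
  if (length(ok) == 0L) return(NA_real_)
  curve$precision[ok[which.min(curve$tpr[ok])]]
}

#' Average curves across replicates on a fixed grid
#'
#' Interpolates every replicate's curve onto 101 evenly spaced points of the
#' x variable and averages vertically (mean and SD).
#'
#' @param curves List of [roc_prc()] tibbles.
#' @param x,y Columns to average (`fpr`/`tpr` for ROC, `tpr`/`precision` for
#'   PRC).
#' @return Tibble with columns `x`, `y_mean`, `y_sd`.
#' @export
aggregate_curves <- function(curves, x = "fpr", y = "tpr") {
  grid <- seq(0, 1, length.out = 101L)
  ys <- vapply(curves, function(cv) {
    xs <- cv[[x]]; yv <- cv[[y]]
    keep <- !is.na(xs) & !is.na(yv)
    stats::approx(xs[keep], yv[keep], xout = grid, ties = mean, rule = 2)$y
  }, numeric(101L))
  ys <- matrix(ys, nrow = 101L)
  tibble(x = grid, y_mean = rowMeans(ys),
         y_sd = apply(ys, 1, stats::sd))
}

#' Plot averaged cross-validation ROC curves
#'
#' @param object A `crossval_result`.
#' @param ... Unused.
#' @return A ggplot object: mean ROC per task with an SD ribbon.
#' @export
autoplot.crossval_result <- function(object, ...) {
  tasks <- unique(object$predictions$task)
  df <- purrr::map_dfr(tasks, function(tk) {
    curves <- object$predictions |>
      dplyr::filter(.data$task == tk) |>
      dplyr::group_split(.data$replicate) |>
      purrr::map(~roc_prc(.x$score, .x$label))
    agg <- aggregate_curves(curves)
    agg$task <- tk
    agg
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$y_mean - .data$y_sd,
                                      ymax = .data$y_mean + .data$y_sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dashed", alpha = 0.4) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = "Cross-validated gene-function prediction")
}
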