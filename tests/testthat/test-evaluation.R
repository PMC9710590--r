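toy_assoc_for_cv <- function() {
  # 30 genes x 6 functions; f5 is a parent of f1 in the ontology
  set.seed(11)
  genes <- sprintf("g%02d", 1:30)
  rows <- do.call(rbind, lapply(1:6, function(j) {
    data.frame(gene = sample(genes, 12),
               function_id = sprintf("f%d", j),
               sign = sample(c(1L, 1L, -1L), 12, replace = TRUE))
  }))
  Y <- association_matrix(rows, genes = genes)
  ont <- ontology(tibble::tibble(child = "f1", parent = "f5"))
  list(Y = Y, ont = ont)
}

test_that("test sets are balanced, leaves-only, and respect min_genes", {
  tc <- toy_assoc_for_cv()
  sets <- make_test_sets(tc$Y, tc$ont, n = 5, k = 3, min_genes = 10,
                         seed = 2)
  expect_length(sets, 3)
  for (ts in sets) {
    expect_equal(sum(ts$truth == 1), 5)
    expect_equal(sum(ts$truth == -1), 5)
    expect_equal(sum(ts$truth == 0), 10)
    # f5 is a parent -> never eligible
    expect_false("f5" %in% ts$function_id)
    # sampled nonzero cells really carry that sign in Y
    nz <- ts[ts$truth != 0, ]
    vals <- tc$Y$Y[cbind(match(nz$gene, tc$Y$genes),
                         match(nz$function_id, tc$Y$functions))]
    expect_equal(as.numeric(vals), as.numeric(nz$truth))
    z <- ts[ts$truth == 0, ]
    vals0 <- tc$Y$Y[cbind(match(z$gene, tc$Y$genes),
                          match(z$function_id, tc$Y$functions))]
    expect_true(all(vals0 == 0))
  }
  # independent replicates differ
  expect_false(identical(sets[[1]], sets[[2]]))
  # too-small pool errors with a size hint
  expect_error(make_test_sets(tc$Y, tc$ont, n = 500, k = 1, min_genes = 10,
                              seed = 1), "pool too small|Eligible pool")
})

test_that("cross-validation leaves Y untouched and masking is per-function local", {
  p <- planted_instance(n_genes = 100, n_targets = 400, n_functions = 20,
                        d = 6, density = 0.1, K = 8,
                        genes_per_function = 12)
  before <- as.matrix(p$Y$Y)
  sets <- make_test_sets(p$Y, empty_ontology(), n = 10, k = 2,
                         min_genes = 5, seed = 3)
  cv <- run_cross_validation(p$emb, p$Y, sets)
  expect_equal(as.matrix(p$Y$Y), before)
  expect_setequal(unique(cv$predictions$task), c("absolute", "sign"))
  # masking a single entry changes only that function's column of P
  fe_full <- fit_function_embeddings(p$emb, p$Y)
  Ym <- p$Y
  tr <- as(p$Y$Y, "TsparseMatrix")
  Ym$Y[tr@i[1] + 1L, tr@j[1] + 1L] <- 0
  fe_masked <- fit_function_embeddings(p$emb, Ym)
  touched <- p$Y$functions[tr@j[1] + 1L]
  others <- setdiff(p$Y$functions, touched)
  expect_equal(fe_masked$P[others, ], fe_full$P[others, ],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fe_masked$P[touched, ],
                                fe_full$P[touched, ])))
})

test_that("ROC/PRC agree with a brute-force threshold enumeration oracle", {
  scores <- c(0.9, 0.8, 0.8, 0.6, 0.4, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0)
  cv <- roc_prc(scores, labels)
  # oracle: enumerate all distinct thresholds by hand
  oracle <- t(vapply(sort(unique(scores), decreasing = TRUE),
                     function(th) {
    pred <- scores >= th
    c(tpr = sum(pred & labels == 1) / 3, fpr = sum(pred & labels == 0) / 3,
      prec = sum(pred & labels == 1) / sum(pred))
  }, numeric(3)))
  expect_equal(cv$tpr[-1], oracle[, "tpr"])
  expect_equal(cv$fpr[-1], oracle[, "fpr"])
  expect_equal(cv$precision[-1], oracle[, "prec"])
  # trapezoidal AUC equals the probabilistic (Mann-Whitney) definition
  pairs <- expand.grid(p = scores[labels == 1], n = scores[labels == 0])
  mw <- mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
  expect_equal(auc(cv), mw)
  # and agrees with pROC on random data
  set.seed(5)
  s2 <- rnorm(200); l2 <- rbinom(200, 1, 0.4)
  expect_equal(auc(roc_prc(s2, l2)),
               as.numeric(pROC::auc(pROC::roc(
                 l2, s2, quiet = TRUE, direction = "<",
                 levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("AUC is 1 for separated scores and ~0.5 for permuted labels", {
  set.seed(8)
  sc <- c(runif(50, 0.6, 1), runif(150, 0, 0.4))
  lb <- c(rep(1, 50), rep(0, 150))
  cv <- roc_prc(sc, lb)
  expect_equal(auc(cv), 1)
  expect_equal(precision_at_recall(cv, 0.05), 1)
  null_auc <- auc(roc_prc(sc, sample(lb)))
  se <- sqrt((50 + 150 + 1) / (12 * 50 * 150))
  expect_lt(abs(null_auc - 0.5), 3 * se)
})

test_that("the sign-task ROC flips into its complementary task", {
  set.seed(13)
  s <- rnorm(100)
  lab <- as.integer(s + rnorm(100) > 0)
  roc_act <- roc_prc(s, lab)        # predict activation
  roc_inh <- roc_prc(-s, 1 - lab)   # predict inhibition
  expect_equal(auc(roc_act), auc(roc_inh), tolerance = 1e-12)
  # flipping TPR -> 1 - TPR, FPR -> 1 - FPR maps one curve onto the other:
  # with distinct scores the two staircases share the same point set
  # (up to the trivial endpoints)
  key <- function(fpr, tpr) paste(round(fpr, 10), round(tpr, 10))
  flipped <- key(c(0, 1, 1 - roc_act$tpr), c(0, 1, 1 - roc_act$fpr))
  orig <- key(c(0, 1, roc_inh$fpr), c(0, 1, roc_inh$tpr))
  expect_setequal(flipped, orig)
})

test_that("replicate aggregation matches hand computation and interpolates monotonically", {
  c1 <- roc_prc(c(4, 3, 2, 1), c(1, 1, 0, 0))
  c2 <- roc_prc(c(4, 3, 2, 1), c(1, 0, 1, 0))
  agg <- aggregate_curves(list(c1, c2))
  # identical replicates -> SD 0
  agg_same <- aggregate_curves(list(c1, c1))
  expect_true(all(agg_same$y_sd == 0))
  # hand case at fpr = 0.5 under the stated tie rule (vertical mean at
  # duplicated x): c1 gives tpr 1; c2 has points (0.5, 0.5) and (0.5, 1)
  # -> 0.75; mean of replicates = 0.875
  at <- which.min(abs(agg$x - 0.5))
  expect_equal(agg$y_mean[at], mean(c(1, 0.75)))
  expect_equal(agg$y_sd[at], sd(c(1, 0.75)))
  expect_true(all(diff(agg$y_mean) > -1e-12))
})

test_that("precision at a recall floor picks the smallest achieved recall >= r", {
  cv <- roc_prc(c(5, 4, 3, 2, 1), c(1, 0, 1, 0, 1))
  # recall grid: 1/3 (prec 1), 2/3 (prec 2/3), 1 (prec 3/5)
  expect_equal(precision_at_recall(cv, 0.05), 1)
  expect_equal(precision_at_recall(cv, 0.5), 2 / 3)
  expect_equal(precision_at_recall(cv, 0.9), 3 / 5)
})

test_that("prediction quality degrades monotonically with generator noise", {
  aucs <- vapply(c(0, 0.1, 0.2), function(nr) {
    p <- planted_instance(n_genes = 150, n_targets = 600, n_functions = 30,
                          d = 6, density = 0.1, noise_rate = nr, seed = 21,
                          K = 10, genes_per_function = 12)
    sets <- make_test_sets(p$Y, empty_ontology(), n = 25, k = 4,
                           min_genes = 8, seed = 4)
    g <- glance(run_cross_validation(p$emb, p$Y, sets))
    g$auc_mean[g$task == "absolute"]
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})
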