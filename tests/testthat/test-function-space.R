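orthonormal_embedding <- function(N, K, seed = 1) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(N * K), N, K)))
  rownames(U) <- sprintf("g%03d", seq_len(N))
  causalembed:::new_embedding(U, method = "E1")
}

test_that("regression embeddings match the orthonormal shortcut and an LS oracle", {
  emb <- orthonormal_embedding(10, 3, seed = 2)
  assoc <- tibble::tibble(
    gene = sprintf("g%03d", c(1, 2, 3, 4, 5, 1, 6)),
    function_id = c(rep("f1", 5), "f2", "f2"),
    sign = c(1L, 1L, -1L, 1L, -1L, -1L, 1L))
  Y <- association_matrix(assoc, genes = rownames(emb$U))
  fe <- fit_function_embeddings(emb, Y)
  # dense least-squares oracle via qr.solve on the normal equations
  U <- emb$U
  for (j in Y$functions) {
    y <- as.numeric(Y$Y[, j])
    p_oracle <- qr.solve(crossprod(U), crossprod(U, y))
    expect_equal(unname(fe$P[j, ]), unname(as.vector(p_oracle)),
                 tolerance = 1e-10)
  }
  # orthonormal shortcut agrees with the general solution
  expect_equal(fe$P, t(as.matrix(Matrix::crossprod(U, Y$Y))),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(sqrt(rowSums(fe$P_norm^2))),
               rep(1, nrow(fe$P_norm)), tolerance = 1e-12)
})

test_that("single-gene functions embed to that gene's direction", {
  emb <- orthonormal_embedding(8, 4, seed = 5)
  Y <- association_matrix(
    tibble::tibble(gene = "g003", function_id = "f1", sign = 1L),
    genes = rownames(emb$U))
  fe <- fit_function_embeddings(emb, Y)
  x <- emb$U["g003", ]
  expect_equal(unname(fe$P["f1", ]), unname(x), tolerance = 1e-10)
  expect_equal(unname(fe$P_norm["f1", ]), unname(x / sqrt(sum(x^2))),
               tolerance = 1e-10)
  sc <- score_genes(emb, fe)
  expect_equal(sc$scores["g003", "f1"], sqrt(sum(x^2)), tolerance = 1e-10)
})

test_that("all-zero association columns are flagged and excluded", {
  emb <- orthonormal_embedding(6, 2, seed = 3)
  Y <- association_matrix(
    tibble::tibble(gene = "g001", function_id = "f1", sign = 1L),
    genes = rownames(emb$U), functions = c("f1", "fempty"))
  fe <- fit_function_embeddings(emb, Y)
  expect_equal(fe$flagged, "fempty")
  expect_false("fempty" %in% rownames(fe$P_norm))
})

test_that("scores are exactly antisymmetric under sign flips and scale-invariant in y", {
  p <- planted_instance(n_genes = 60, n_targets = 250, n_functions = 10,
                        d = 5, density = 0.15, K = 6,
                        genes_per_function = 8)
  fe <- fit_function_embeddings(p$emb, p$Y)
  sc <- score_genes(p$emb, fe)
  # gene-vector negation flips that gene's whole score row
  emb_neg <- p$emb
  emb_neg$U[3, ] <- -emb_neg$U[3, ]
  sc2 <- score_genes(emb_neg, fe)
  expect_equal(sc2$scores[3, ], -sc$scores[3, ], tolerance = 1e-12)
  expect_equal(sc2$scores[-3, ], sc$scores[-3, ], tolerance = 1e-12)
  # function-vector negation flips that function's column
  fe_neg <- fe
  fe_neg$P_norm[2, ] <- -fe_neg$P_norm[2, ]
  sc3 <- score_genes(p$emb, fe_neg)
  expect_equal(sc3$scores[, 2], -sc$scores[, 2], tolerance = 1e-12)
  # scaling y leaves the normalized vector unchanged
  Y2 <- p$Y
  Y2$Y <- p$Y$Y * 3
  fe3 <- suppressWarnings(fit_function_embeddings(p$emb, Y2))
  expect_equal(fe3$P_norm, fe$P_norm, tolerance = 1e-10)
})

test_that("planted associations rank above zeros which rank above anti-associations", {
  p <- planted_instance(n_genes = 150, n_targets = 600, n_functions = 25,
                        d = 6, density = 0.1, K = 10,
                        genes_per_function = 15)
  fe <- fit_function_embeddings(p$emb, p$Y)
  sc <- score_genes(p$emb, fe)
  Ym <- as.matrix(p$Y$Y[, rownames(fe$P_norm)])
  S <- sc$scores[, rownames(fe$P_norm)]
  expect_gt(mean(S[Ym == 1]), mean(S[Ym == 0]))
  expect_gt(mean(S[Ym == 0]), mean(S[Ym == -1]))
})

test_that("analytic z-scores standardize against the isotropic null", {
  # fixed gene with unit embedding vector, K = 500: s = 0.0894 -> z ~ 2
  emb <- causalembed:::new_embedding(
    matrix(c(1, rep(0, 499)), 1, 500, dimnames = list("g1", NULL)),
    method = "E1")
  Z <- score_zscores(matrix(0.0894427, 1, 1), emb)
  expect_equal(Z[1, 1], 2, tolerance = 1e-4)
  expect_equal(score_zscores(matrix(0, 1, 1), emb)[1, 1], 0)

  # Monte-Carlo: scores of one gene against random unit function vectors
  # are standard normal (Kolmogorov-Smirnov at 1e4 draws)
  set.seed(20)
  K <- 25
  x <- rnorm(K)
  emb2 <- causalembed:::new_embedding(
    matrix(x, 1, K, dimnames = list("g1", NULL)), method = "E1")
  P <- matrix(rnorm(1e4 * K), 1e4, K)
  P <- P / sqrt(rowSums(P^2))
  s <- as.vector(P %*% x)
  z <- score_zscores(matrix(s, 1), emb2)[1, ]
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 1e-4)
  # empirical column standardization is monotone within each column
  Zc <- score_zscores(matrix(s, ncol = 1), emb2, zmethod = "empirical")
  expect_equal(order(Zc[, 1]), order(s))
})

test_that("cosine similarity and its significance threshold obey the closed forms", {
  p <- planted_instance(n_genes = 40, n_targets = 150, n_functions = 8,
                        d = 4, density = 0.2, K = 5,
                        genes_per_function = 6)
  fe <- fit_function_embeddings(p$emb, p$Y)
  f1 <- rownames(fe$P_norm)[1]; f2 <- rownames(fe$P_norm)[2]
  expect_equal(cosine_similarity(fe, f1, f1), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(fe, f1, f2),
               sum(fe$P_norm[f1, ] * fe$P_norm[f2, ]), tolerance = 1e-12)

  expect_equal(similarity_threshold(500), 2 / sqrt(500))
  expect_equal(round(similarity_threshold(500), 2), 0.09)
  expect_equal(similarity_threshold(4), 1)

  # sigma_c from simulated random unit-vector components matches K^(-1/2)
  set.seed(7)
  K <- 50
  V <- matrix(rnorm(1e5 * K), ncol = K)
  V <- V / sqrt(rowSums(V^2))
  expect_equal(sd(V[, 1]), 1 / sqrt(K), tolerance = 0.02)
})

test_that("PCA projection of process pairs matches an eigendecomposition oracle", {
  set.seed(9)
  P <- matrix(rnorm(12 * 6), 12, 6)
  P <- P / sqrt(rowSums(P^2))
  rownames(P) <- sprintf("f%02d", 1:12)
  fe <- structure(list(P = P, P_norm = P, functions = rownames(P),
                       flagged = character(), K = 6),
                  class = "function_embeddings")
  pairs <- tibble::tibble(a = sprintf("f%02d", 1:6),
                          b = sprintf("f%02d", 7:12))
  coords <- project_process_pairs(fe, pairs)
  # centering: coordinates sum to zero per axis
  expect_equal(sum(coords$pc1), 0, tolerance = 1e-10)
  expect_equal(sum(coords$pc2), 0, tolerance = 1e-10)
  # oracle: eigendecomposition of the covariance of the selected vectors
  X <- scale(P, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X) / (nrow(X) - 1))
  proj <- X %*% ev$vectors[, 1:2]
  expect_equal(abs(coords$pc1), abs(proj[, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(abs(coords$pc2), abs(proj[, 2]), tolerance = 1e-8,
               ignore_attr = TRUE)
  # PC1 variance >= PC2 variance
  expect_gte(stats::var(coords$pc1), stats::var(coords$pc2))
})

test_that("the angle test attains its minimal p on parallel segments", {
  set.seed(4)
  n <- 10
  a <- matrix(runif(2 * n, -1, 1), n, 2)
  off <- c(0.7, 0.3)
  coords <- tibble::tibble(
    function_id = c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n)),
    pc1 = c(a[, 1], a[, 1] + off[1]),
    pc2 = c(a[, 2], a[, 2] + off[2]))
  pairs <- tibble::tibble(a = sprintf("a%02d", 1:n), b = sprintf("b%02d", 1:n))
  res <- angle_parallelism_test(coords, pairs, n_permutations = 999,
                                seed = 3)
  expect_equal(res$angle_sd, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1 / 1000)
})

test_that("the angle test p-value is uniform under the null", {
  pvals <- vapply(1:100, function(r) {
    set.seed(1000 + r)
    n <- 8
    coords <- tibble::tibble(
      function_id = c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n)),
      pc1 = rnorm(2 * n), pc2 = rnorm(2 * n))
    pairs <- tibble::tibble(a = sprintf("a%02d", 1:n),
                            b = sprintf("b%02d", 1:n))
    angle_parallelism_test(coords, pairs, n_permutations = 99,
                           seed = r)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 1e-3)
})

test_that("additive process+context structure yields a significant angle test", {
  # f_{X,Y} = v_X + w_Y + noise: the word-analogy structure
  set.seed(12)
  K <- 20
  vX <- matrix(rnorm(2 * K), 2, K)          # two processes
  wY <- matrix(rnorm(10 * K), 10, K)        # ten contexts
  P <- rbind(vX[rep(1, 10), ] + wY, vX[rep(2, 10), ] + wY) +
    matrix(rnorm(20 * K, sd = 0.05), 20, K)
  P <- P / sqrt(rowSums(P^2))
  rownames(P) <- c(sprintf("p1_c%02d", 1:10), sprintf("p2_c%02d", 1:10))
  fe <- structure(list(P = P, P_norm = P, functions = rownames(P),
                       flagged = character(), K = K),
                  class = "function_embeddings")
  pairs <- tibble::tibble(a = sprintf("p1_c%02d", 1:10),
                          b = sprintf("p2_c%02d", 1:10))
  coords <- project_process_pairs(fe, pairs)
  res <- angle_parallelism_test(coords, pairs, n_permutations = 1999,
                                seed = 8)
  expect_lt(res$p_value, 0.01)
})

test_that("disease map runs PCA exactly and lays out deterministically", {
  p <- planted_instance(n_genes = 80, n_targets = 300, n_functions = 30,
                        d = 6, density = 0.12, K = 8,
                        genes_per_function = 10)
  fe <- fit_function_embeddings(p$emb, p$Y)
  ids <- rownames(fe$P_norm)[1:25]
  dm <- disease_map_coordinates(fe, ids, n_components = 20,
                                perplexity = 5, seed = 2, max_iter = 120)
  expect_equal(nrow(dm$map), 25)
  expect_equal(ncol(dm$pca) - 1L, min(20L, ncol(fe$P_norm)))
  # PCA stage equals prcomp oracle
  pc <- stats::prcomp(fe$P_norm[ids, ], center = TRUE, scale. = FALSE)
  expect_equal(as.matrix(dm$pca[, -1]), pc$x[, 1:(ncol(dm$pca) - 1L)],
               tolerance = 1e-10, ignore_attr = TRUE)
  # identical layout under the same seed
  dm2 <- disease_map_coordinates(fe, ids, n_components = 20,
                                 perplexity = 5, seed = 2, max_iter = 120)
  expect_identical(dm$map, dm2$map)
})
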