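test_that("linear embedding is exact for intrinsically 3-D data", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3))) # 3-D subspace of R^20
  latent <- matrix(rnorm(3 * 80, sd = 2), 3, 80)
  x <- basis %*% latent # units x points
  emb <- embed_population(x, rep(1:2, each = 40), method = "linear")
  d_true <- dist(t(x)[1:40, ])
  d_emb <- dist(emb[[1]])
  expect_equal(as.vector(d_emb), as.vector(d_true), tolerance = 1e-8)
  # duplicated maze data embeds to identical point sets
  emb2 <- embed_population(cbind(x[, 1:40], x[, 1:40]), rep(1:2, each = 40),
                           method = "linear")
  expect_equal(emb2[[1]], emb2[[2]], ignore_attr = TRUE)
})

test_that("isomap preserves manifold ordering better than PCA on a roll", {
  set.seed(2)
  n <- 120
  t_par <- sort(runif(n, 0, 3 * pi))
  roll <- rbind((1 + t_par) * cos(t_par), (1 + t_par) * sin(t_par),
                runif(n, 0, 4))
  x <- rbind(roll, matrix(0, 5, n)) # pad into a higher-dimensional space
  lab <- rep(1, n)
  lin <- embed_population(x, lab, "linear", n_components = 2)[[1]]
  iso <- embed_population(x, lab, "nonlinear", n_components = 2,
                          n_neighbors = 10)[[1]]
  d_t <- as.vector(dist(t_par))
  rc <- function(emb) cor(as.vector(dist(emb)), d_t, method = "spearman")
  expect_gt(rc(iso), rc(lin))
  expect_gt(rc(iso), 0.9)
})

test_that("procrustes distance vanishes exactly on similarity transforms", {
  set.seed(3)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(procrustes_dissimilarity(a, a), 0, tolerance = 1e-12)
  theta <- 0.7
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  b <- 2.5 * a %*% rot + matrix(rep(c(1, -2, 3), each = 10), 10, 3)
  expect_lt(procrustes_dissimilarity(a, b), 1e-10)
  # perturbed copies are strictly positive and the measure is symmetric
  b2 <- b + rnorm(30, sd = 0.3)
  expect_gt(procrustes_dissimilarity(a, b2), 1e-4)
  expect_equal(procrustes_dissimilarity(a, b2), procrustes_dissimilarity(b2, a),
               tolerance = 1e-10)
  expect_error(procrustes_dissimilarity(a, matrix(1, 10, 3)), "degenerate")
  expect_error(procrustes_dissimilarity(a, a[1:5, ]), "equal dimensions")
})

test_that("procrustes matches a hand-rolled orthogonal alignment oracle", {
  # independent closed-form solution: center, scale to unit norm, rotate by
  # the SVD of the cross-product, residual = 2 (1 - sum of singular values)
  oracle <- function(x, y) {
    cx <- scale(x, scale = FALSE); cy <- scale(y, scale = FALSE)
    cx <- cx / sqrt(sum(cx^2)); cy <- cy / sqrt(sum(cy^2))
    sv <- svd(crossprod(cy, cx))
    1 - sum(sv$d)^2
  }
  set.seed(4)
  for (i in 1:5) {
    x <- matrix(rnorm(24), 8, 3)
    y <- matrix(rnorm(24), 8, 3)
    expect_equal(procrustes_dissimilarity(x, y), oracle(x, y),
                 tolerance = 1e-10)
  }
  # 3-point planar toy, hand-worked: a right triangle vs its reflection-free
  # rotation has zero residual, vs a stretched copy nonzero
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  rot90 <- rbind(c(0, -1), c(1, 0))
  expect_lt(procrustes_dissimilarity(tri, tri %*% rot90), 1e-12)
  stretched <- tri %*% diag(c(3, 1))
  expect_equal(procrustes_dissimilarity(tri, stretched),
               oracle(tri, stretched), tolerance = 1e-10)
})

test_that("canonical-variable silhouettes separate and calibrate", {
  set.seed(5)
  n_per <- 40
  centers <- rbind(c(8, 0, 0), c(-8, 8, 0), c(0, -8, 8), c(-8, -8, -8))
  x <- do.call(rbind, lapply(1:4, function(k)
    matrix(rnorm(n_per * 40, sd = 0.5), n_per, 40) +
      matrix(rep(c(centers[k, ], rep(0, 37)), each = n_per), n_per, 40)))
  labels <- rep(letters[1:4], each = n_per)
  res <- lda_cluster_silhouette(x, labels, n_pcs = 30)
  expect_gt(mean(res$silhouette), 0.9)
  expect_true(all(res$silhouette >= -1 & res$silhouette <= 1))
  expect_equal(ncol(res$scores), 2L)
  # label shuffling destroys the clustering
  res0 <- lda_cluster_silhouette(x, sample(labels), n_pcs = 30)
  expect_lt(abs(mean(res0$silhouette)), 0.15)
  expect_error(lda_cluster_silhouette(x, rep("a", nrow(x))), "two distinct")
})

test_that("nonnegative tensor decomposition recovers planted components", {
  set.seed(6)
  rank_true <- 3
  u <- matrix(runif(15 * rank_true), 15, rank_true)
  v <- matrix(runif(9 * rank_true), 9, rank_true)
  w <- matrix(runif(40 * rank_true), 40, rank_true)
  x <- array(0, c(15, 9, 40))
  for (r in 1:rank_true)
    x <- x + outer(outer(u[, r], v[, r]), w[, r])
  fit <- tca_decompose(x, rank = 3, n_restarts = 8, seed = 7)
  expect_lt(fit$error, 0.01)
  expect_true(all(fit$factors$unit >= 0) && all(fit$factors$epoch >= 0) &&
                all(fit$factors$trial >= 0))
  # factor congruence with the planted components (up to permutation)
  congr <- function(a, b) {
    an <- sweep(a, 2, sqrt(colSums(a^2)), "/")
    bn <- sweep(b, 2, sqrt(colSums(b^2)), "/")
    crossprod(an, bn)
  }
  cu <- congr(u, fit$factors$unit)
  perm <- apply(cu, 1, which.max)
  expect_equal(sort(perm), 1:3) # one-to-one match
  score <- sapply(1:3, function(r)
    congr(u, fit$factors$unit)[r, perm[r]] *
      congr(v, fit$factors$epoch)[r, perm[r]] *
      congr(w, fit$factors$trial)[r, perm[r]])
  expect_true(all(score > 0.95))
})

test_that("tensor fit error is nonincreasing in rank and inputs validated", {
  set.seed(8)
  pop <- lapply(1:6, function(u) {
    em <- synthetic_em(function(epoch, rewarded, ...)
      runif(1, 1, 3) * seq(1, 3, length.out = 9) * (1 + rewarded),
      unit_id = paste0("u", u), noise_sd = 0.2)
    em$values <- pmax(em$values, 0)
    em
  })
  tens <- population_tensor(pop)
  expect_equal(dim(tens$values), c(6L, 9L, 160L))
  f3 <- tca_decompose(tens, rank = 3, n_restarts = 4, seed = 9)
  f5 <- tca_decompose(tens, rank = 5, n_restarts = 4, seed = 9)
  expect_lte(f5$error, f3$error + 1e-6)
  expect_error(tca_decompose(array(-1, c(2, 2, 2)), 2), "nonnegative")
})
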