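test_that("euclidean distances match a brute-force loop with missing data", {
  set.seed(91)
  m <- matrix(sample(c(0:4, NA), 8 * 12, replace = TRUE,
                     prob = c(rep(0.18, 5), 0.1)), 8, 12)
  dm <- toy_dosage(m)
  ed <- euclidean_distances(dm)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      shared <- !is.na(m[i, ]) & !is.na(m[j, ])
      want <- if (any(shared)) sqrt(sum((m[i, shared] - m[j, shared])^2))
              else NA_real_
      expect_equal(ed$d[i, j], want)
      expect_equal(unname(ed$shared[i, j]), sum(shared))
    }
  }
  expect_equal(ed$d, t(ed$d))
  expect_equal(unname(diag(ed$d)), rep(0, 8))
})

test_that("simple distance identities hold", {
  dm <- toy_dosage(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L), c(2L, 1L, 0L),
                         c(4L, 1L, 2L)))
  ed <- euclidean_distances(dm)
  expect_equal(ed$d[1, 2], 0)           # identical columns
  expect_equal(ed$d[1, 4], 4)           # single differing locus, 0 vs 4
  expect_equal(ed$d[1, 3], sqrt(8))     # (0,1,2) vs (2,1,0)
})

test_that("distances satisfy the metric axioms on complete data", {
  set.seed(92)
  m <- matrix(sample(0:4, 10 * 20, replace = TRUE), 10, 20)
  ed <- euclidean_distances(toy_dosage(m))
  d <- ed$d
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
  }
})

test_that("upgma reproduces the hand-worked three-sample example", {
  dm <- toy_dosage(matrix(c(0, 0, 4, 0, 2, 4), 3),
                   samples = c("X", "Y", "Z"))
  tr <- upgma(euclidean_distances(dm))
  expect_equal(tr$height[1], 1)
  expect_equal(tr$height[2], mean(c(sqrt(32), sqrt(20))) / 2,
               tolerance = 1e-12)
  ## first merge joins X and Y
  first <- sort(tr$labels[-tr$merge[1, ]])
  expect_equal(first, c("X", "Y"))
})

test_that("identical samples merge at height zero", {
  dm <- toy_dosage(rbind(c(1L, 2L), c(1L, 2L), c(4L, 0L)))
  tr <- upgma(euclidean_distances(dm))
  expect_equal(min(tr$height), 0)
})

test_that("upgma agrees with average-linkage hclust on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(8 * 6, 0, 4), 8)
    rownames(m) <- letters[1:8]
    d <- dist(m)
    ref <- hclust(d, method = "average")
    tr <- upgma(as.matrix(d))
    expect_equal(sort(tr$height * 2), sort(ref$height), tolerance = 1e-9)
    co_ref <- as.matrix(stats::cophenetic(ref))
    co_our <- cophenetic_distances(tr)[rownames(co_ref), colnames(co_ref)]
    expect_equal(co_our, co_ref, tolerance = 1e-9)
  }
})

test_that("upgma trees are ultrametric", {
  set.seed(93)
  m <- matrix(sample(0:4, 9 * 15, replace = TRUE), 9, 15)
  tr <- upgma(euclidean_distances(toy_dosage(m)))
  co <- cophenetic_distances(tr)
  n <- nrow(co)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    trio <- sort(c(co[i, j], co[i, k], co[j, k]), decreasing = TRUE)
    expect_lt(trio[1] - trio[2], 1e-9)
  }
  ## merge heights never decrease
  expect_true(all(diff(tr$height) >= -1e-12))
})

test_that("missing pairwise distances stop the clustering with guidance", {
  m <- rbind(c(0L, NA), c(NA, 2L), c(1L, 1L))
  ed <- euclidean_distances(toy_dosage(m))
  expect_true(anyNA(ed$d))
  expect_error(upgma(ed), "impute or drop")
})

test_that("pca separates duplicated-column clusters on PC1", {
  base_a <- rep(0L, 12)
  base_b <- rep(4L, 12)
  m <- rbind(base_a, base_a, base_a, base_b, base_b, base_b)
  pc <- quietly(pca_scores(toy_dosage(m), n_components = 2))
  expect_equal(pc$explained_variance[1], 1)
  s1 <- pc$scores$PC1
  expect_true(all(s1[1:3] * s1[4:6] < 0))
  expect_equal(sd(s1[1:3]), 0)
})

test_that("pca matches an independent eigendecomposition up to sign", {
  set.seed(94)
  m <- matrix(sample(0:4, 20 * 30, replace = TRUE), 20, 30)
  pc <- pca_scores(toy_dosage(m), n_components = 3)
  cm <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(cm) / (nrow(m) - 1))
  scores_ref <- cm %*% eig$vectors[, 1:3]
  for (j in 1:3) {
    got <- pc$scores[[j + 1]]
    expect_true(max(abs(got - scores_ref[, j])) < 1e-8 ||
                  max(abs(got + scores_ref[, j])) < 1e-8)
  }
  ev_ref <- eig$values / sum(eig$values)
  expect_equal(pc$explained_variance, ev_ref[1:3], tolerance = 1e-8)
})

test_that("degenerate pca inputs behave predictably", {
  same <- toy_dosage(matrix(2L, 4, 5))
  pc <- pca_scores(same)
  expect_true(all(abs(as.matrix(pc$scores[, -1])) < 1e-12))
  expect_equal(pc$explained_variance, c(0, 0))
  expect_error(pca_scores(toy_dosage(matrix(0:3, 2, 2)), n_components = 5),
               "components")
})
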