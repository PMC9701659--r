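test_that("normalization applies transform then per-feature scaling", {
  ab <- cbind(a = c(2, 4, 6), b = c(1, 2, 3), c = c(27, 27, 27))
  rownames(ab) <- paste0("s", 1:3)
  fm <- feature_matrix(ab, tibble::tibble(sample_id = paste0("s", 1:3)),
                       features = tibble::tibble(label = c("a", "b", "c"),
                                                 mz = 1:3, rt = 1:3))
  expect_warning(auto <- normalize_features(fm, scaling = "autoscale"),
                 "zero-variance")
  expect_equal(unname(auto$abundance[, "a"]), c(-1, 0, 1))
  expect_false("c" %in% colnames(auto$abundance))  # constant feature dropped

  expect_warning(rng <- normalize_features(fm, scaling = "range"))
  expect_equal(unname(rng$abundance[, "b"]), c(-0.5, 0, 0.5))

  cr <- normalize_features(fm, transform = "cube_root", scaling = "none")
  expect_equal(unname(cr$abundance[, "c"]), c(3, 3, 3))

  expect_warning(par <- normalize_features(fm, scaling = "pareto"))
  expect_equal(unname(par$abundance[, "a"]), (c(2, 4, 6) - 4) / sqrt(2))
  expect_equal(attr(par, "normalization")$scaling, "pareto")
})

test_that("PCA explains variance consistently and handles rank-1 input", {
  s <- c(1, 2, 3, 4)
  rank1 <- outer(s, c(2, -1, 0.5))
  colnames(rank1) <- c("a", "b", "c")
  pca <- run_pca(rank1, n_components = 2)
  expect_equal(pca$var_explained[1], 100)

  set.seed(3)
  m <- matrix(rnorm(80), 8, 10, dimnames = list(NULL, paste0("f", 1:10)))
  p <- run_pca(m, n_components = 3)
  expect_equal(sum(p$var_explained), 100, tolerance = 1e-6)
  expect_true(all(diff(p$var_explained) <= 1e-9))
  # loadings are orthonormal
  expect_equal(crossprod(p$loadings), diag(3), ignore_attr = TRUE)
  # sign convention: dominant entry of each loading is positive
  for (c_i in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, c_i])), c_i], 0)
  }
  expect_error(run_pca(matrix(c(1, NA), 2, 1, dimnames = list(NULL, "x"))),
               "finite")
})

test_that("full-rank scores preserve pairwise sample distances", {
  set.seed(4)
  m <- matrix(rnorm(60), 6, 10, dimnames = list(NULL, paste0("f", 1:10)))
  p <- run_pca(m, n_components = 6)
  d_scores <- dist(p$scores)
  d_centered <- dist(sweep(m, 2, colMeans(m)))
  expect_equal(as.numeric(d_scores), as.numeric(d_centered), tolerance = 1e-10)
})

test_that("autoscaled PCA eigenvalues equal the correlation-matrix spectrum", {
  set.seed(5)
  ab <- matrix(rlnorm(15 * 8, 2, 0.6), 15, 8,
               dimnames = list(paste0("s", 1:15), paste0("f", 1:8)))
  fm <- feature_matrix(ab, tibble::tibble(sample_id = paste0("s", 1:15)),
                       features = tibble::tibble(label = paste0("f", 1:8),
                                                 mz = 1:8, rt = 1:8))
  norm <- normalize_features(fm, scaling = "autoscale")
  p <- run_pca(norm, n_components = 8)
  eig <- eigen(cor(ab), only.values = TRUE)$values
  # autoscaled covariance is the correlation matrix, so the spectra coincide
  expect_equal(p$eigenvalues, eig, tolerance = 1e-8)
  expect_equal(100 * eig / sum(eig), p$var_explained, tolerance = 1e-8)
})

test_that("elbow selection picks a sensible component count", {
  set.seed(6)
  # two dominant directions plus isotropic noise
  base <- matrix(rnorm(20 * 2), 20, 2) %*% matrix(c(5, 0, 0, 3), 2)
  m <- cbind(base, matrix(rnorm(20 * 6, 0, 0.2), 20, 6))
  colnames(m) <- paste0("f", 1:8)
  p <- run_pca(m, n_components = "elbow")
  expect_gte(p$n_components, 1)
  expect_lte(p$n_components, 3)
  p5 <- run_pca(m, n_components = 5)
  expect_equal(p5$n_components, 5)
  expect_equal(ncol(p5$scores), 5)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(7)
  ab <- matrix(rlnorm(40), 8, 5, dimnames = list(paste0("s", 1:8), paste0("f", 1:5)))
  ab[, 2] <- ab[, 1]          # duplicate feature
  ab[, 3] <- max(ab[, 1]) - ab[, 1]  # anti-correlated
  r <- correlation_matrix(ab, axis = "features")
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)

  ab[, 5] <- 4  # constant feature: NA correlations with a warning
  expect_warning(r2 <- correlation_matrix(ab), "constant")
  expect_true(all(is.na(r2[5, -5])))

  rs <- correlation_matrix(ab[, 1:4], axis = "samples")
  expect_equal(dim(rs), c(8, 8))
})

test_that("hierarchical clustering merges identical and near rows first", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  hc <- hierarchical_cluster(m, distance = "euclidean", linkage = "average")
  expect_equal(hc$merge_heights[1], 0)  # identical rows merge at height 0
  # the identical pair merges before c joins
  expect_equal(sort(hc$hclust$merge[1, ]), c(-2, -1))

  line <- rbind(p0 = c(0, 0), p1 = c(1, 0), p10 = c(10, 0))
  hc2 <- hierarchical_cluster(line, distance = "euclidean", linkage = "average")
  expect_equal(sort(hc2$hclust$merge[1, ]), c(-2, -1))
  expect_true(all(diff(hc2$merge_heights) >= 0))  # monotone linkage

  set.seed(8)
  m3 <- matrix(rnorm(50), 10, 5)
  hc3 <- hierarchical_cluster(m3, distance = "correlation", linkage = "complete")
  expect_true(all(diff(hc3$merge_heights) >= -1e-12))
  expect_error(hierarchical_cluster(m3[1, , drop = FALSE]), "at least 2")
})

test_that("the relative-abundance threshold filter keeps qualifying features", {
  ab <- cbind(lo = c(0.5, 1, 1.5), hi = c(0.1, 2.5, 0.3), mid = c(2, 0, 0))
  rownames(ab) <- paste0("s", 1:3)
  fm <- feature_matrix(ab, tibble::tibble(sample_id = paste0("s", 1:3)),
                       features = tibble::tibble(label = colnames(ab),
                                                 mz = 1:3, rt = 1:3))
  kept <- abundance_filter(fm, min_value = 2)
  expect_equal(colnames(kept$abundance), c("hi", "mid"))
  expect_warning(abundance_filter(fm, min_value = 100), "No feature")
})
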