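test_that("autoscaling centres and scales every column", {
  m <- tibble::tibble(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- autoscale(m)
  expect_equal(colMeans(as.matrix(s)), c(a = 0, b = 0))
  expect_equal(apply(as.matrix(s), 2, sd), c(a = 1, b = 1))
  expect_error(autoscale(tibble::tibble(a = c(1, 1, 1))), "constant")
  expect_equal(autoscale(s), s)
})

test_that("two perfectly correlated variables collapse onto one component", {
  m <- tibble::tibble(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 1)
  p <- qsrr_pca(m)
  expect_equal(p$explained_fraction[1], 1, tolerance = 1e-12)
})

test_that("equicorrelated variables give the analytic eigenvalues", {
  set.seed(33)
  n <- 12
  base <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, 2:5]
  r <- 0.5
  x <- sapply(1:3, function(k) sqrt(r) * base[, 4] + sqrt(1 - r) * base[, k])
  m <- tibble::as_tibble(as.data.frame(x))
  p <- qsrr_pca(m)
  expect_equal(p$eigenvalues, c(1 + 2 * r, 1 - r, 1 - r), tolerance = 1e-10)
})

test_that("pca satisfies the spectral invariants and matches prcomp", {
  gen <- generate_qsrr(synthetic_spec(n_candidates = 8, seed = 3))
  m <- gen$data[, c("code", sprintf("D%03d", 1:8))]
  p <- qsrr_pca(m)
  expect_equal(sum(p$eigenvalues), 8, tolerance = 1e-10)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  L <- p$loadings
  expect_equal(t(L) %*% L, diag(8), tolerance = 1e-8, ignore_attr = TRUE)
  scores <- as.matrix(p$scores[, -1])
  expect_equal(colMeans(scores), rep(0, 8), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(diag(stats::cov(scores)), p$eigenvalues, tolerance = 1e-8,
               ignore_attr = TRUE)
  # independent route: SVD-based PCA of the scaled data
  pr <- stats::prcomp(as.matrix(m[, -1]), center = TRUE, scale. = TRUE)
  expect_equal(p$eigenvalues, pr$sdev^2, tolerance = 1e-9)
})

test_that("pca of autoscaled data ignores affine column transforms", {
  gen <- generate_qsrr(synthetic_spec(n_candidates = 5, seed = 13))
  m <- gen$data[, c("code", sprintf("D%03d", 1:5))]
  m2 <- m
  m2$D002 <- 10 * m2$D002 - 3
  m2$D004 <- -0.5 * m2$D004
  p1 <- qsrr_pca(m)
  p2 <- qsrr_pca(m2)
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-9)
  # scores agree up to the fixed sign convention
  s1 <- as.matrix(p1$scores[, -1]); s2 <- as.matrix(p2$scores[, -1])
  for (k in seq_len(ncol(s1))) {
    expect_equal(abs(s1[, k]), abs(s2[, k]), tolerance = 1e-8)
  }
})

test_that("biplot truncation is lossless at full rank", {
  gen <- generate_qsrr(synthetic_spec(n_candidates = 6, seed = 19))
  m <- gen$data[, c("code", sprintf("D%03d", 1:6))]
  p <- qsrr_pca(m)
  bd <- biplot_data(p, k = 6)
  recon <- as.matrix(bd$scores[, -1]) %*% t(as.matrix(bd$loadings[, -1]))
  scaled <- as.matrix(autoscale(m)[, -1])
  expect_equal(recon, scaled, tolerance = 1e-8, ignore_attr = TRUE)
  bd2 <- biplot_data(p, k = 2)
  expect_equal(nrow(bd2$scores), 29)
  expect_error(biplot_data(p, k = 7), "exceeds")
})

test_that("the Z and U variable sets give nearly identical biplots", {
  d <- qsrr_data()
  pz <- response_pca("Z", d)
  pu <- response_pca("U", d)
  sz <- as.matrix(pz$scores[, c("PC1", "PC2")])
  su <- as.matrix(pu$scores[, c("PC1", "PC2")])
  for (k in 1:2) if (sum(sz[, k] * su[, k]) < 0) su[, k] <- -su[, k]
  expect_lt(max(abs(sz - su)), 0.3)
})

test_that("removing the response changes the projection only modestly (reported)", {
  d <- qsrr_data()
  with_r <- response_pca("X", d, include_response = TRUE)
  without_r <- response_pca("X", d, include_response = FALSE)
  # report, not assert: Procrustes-style distance between 2-PC score sets
  sa <- as.matrix(with_r$scores[, c("PC1", "PC2")])
  sb <- as.matrix(without_r$scores[, c("PC1", "PC2")])
  for (k in 1:2) if (sum(sa[, k] * sb[, k]) < 0) sb[, k] <- -sb[, k]
  dist <- sqrt(mean((sa - sb)^2))
  expect_true(is.finite(dist))
  # SILAR phases order along PC1 follows the cyanopropyl:phenyl ratio
  px <- response_pca("X", d)
  silar <- c("SILAR 5CP", "SILAR 7CP", "SILAR 9CP", "SILAR 10CP")
  pc1 <- px$scores$PC1[match(silar, px$scores$code)]
  expect_gt(stats::cor(pc1, 1:4, method = "spearman"), 0.7)
})

test_that("autoplot returns a ggplot biplot", {
  p <- response_pca("X", qsrr_data())
  gg <- ggplot2::autoplot(p)
  expect_s3_class(gg, "ggplot")
})
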