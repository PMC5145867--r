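# PCA with supplementary projection and complete-linkage clustering.

test_that("pca: explained variance matches the correlation-matrix
           eigendecomposition", {
  set.seed(21)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X[, "b"] <- 0.6 * X[, "a"] + 0.8 * X[, "b"]
  p <- pca_params(X)
  ev <- eigen(cor(X), symmetric = TRUE)$values   # independent oracle
  expect_equal(p$explained, ev / sum(ev), tolerance = 1e-12)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  # scores are centered
  expect_equal(colMeans(p$scores), rep(0, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pca: perfectly correlated pair loads on one component", {
  x <- seq(-3, 3, length.out = 50)
  p <- pca_params(cbind(x, 2 * x + 1))
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  # loadings on component 1 are correlations: both 1 in magnitude
  expect_equal(abs(p$loadings[, 1]), c(1, 1), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("pca: reconstruction to machine precision, deterministic sign", {
  set.seed(22)
  X <- matrix(rnorm(120), 30, 4)
  p <- pca_params(X)
  Z <- scale(X, center = p$center, scale = p$scale)
  rot <- sweep(p$loadings, 2, p$sdev, "/")
  expect_equal(p$scores %*% t(rot), unclass(Z), tolerance = 1e-10,
               ignore_attr = TRUE)
  # per-component sign convention: largest |loading| entry positive
  for (k in 1:4)
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  expect_error(pca_params(cbind(X, 0)), "zero-variance")
  expect_error(pca_params(X[, 1, drop = FALSE]), "two columns")
})

test_that("supplementary projection is the score correlation", {
  set.seed(23)
  X <- matrix(rnorm(300), 100, 3)
  p <- pca_params(X)
  # a supplementary variable equal to a score has coordinate 1 there
  co <- project_supplementary(p, cbind(v = p$scores[, 2]))
  expect_equal(co[1, 2], 1, tolerance = 1e-12)
  expect_equal(co[1, ], drop(cor(p$scores[, 2], p$scores)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # sign flip
  co2 <- project_supplementary(p, cbind(v = -p$scores[, 2]))
  expect_equal(co2[1, ], -co[1, ], tolerance = 1e-12)
  # independent noise stays inside the null band
  co3 <- project_supplementary(p, cbind(noise = rnorm(100)))
  expect_true(all(abs(co3) < 0.3))
  expect_warning(project_supplementary(p, cbind(flat = rep(1, 100))),
                 "zero-variance")
  expect_error(project_supplementary(p, cbind(v = 1:5)), "row mismatch")
})

test_that("complete-linkage clustering: blobs, singletons, monotone
           merges", {
  set.seed(24)
  blob1 <- matrix(rnorm(60, 0, 0.1), 30, 2)
  blob2 <- matrix(rnorm(60, 5, 0.1), 30, 2)
  sc <- rbind(blob1, blob2)
  cl <- hcluster_scores(sc, k = 2, nComponents = 2)
  expect_equal(length(unique(cl$labels[1:30])), 1)
  expect_equal(length(unique(cl$labels[31:60])), 1)
  expect_false(cl$labels[1] == cl$labels[31])
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  cln <- hcluster_scores(sc, k = nrow(sc), nComponents = 2)
  expect_equal(sort(unique(cln$labels)), seq_len(nrow(sc)))
  expect_error(hcluster_scores(sc, k = 100), "exceeds")
  expect_error(hcluster_scores(sc, k = 1), ">= 2")
})

test_that("skew transform renames and transforms the QTL-style columns", {
  X <- cbind(phiMax = c(1e-3, 2e-3), nuM = c(0.01, 0.1),
             lp1 = c(1e-3, 1e-2), rxp = c(0.2, 0.5), Lp = c(0.1, 0.2))
  tx <- skew_transform(X)
  expect_true(all(c("log10_nuM", "log10_lp1", "log10_lx", "log10_lx1",
                    "inv_rxp") %in% colnames(tx)))
  expect_equal(tx[, "log10_nuM"], log10(X[, "nuM"]), ignore_attr = TRUE)
  expect_equal(tx[, "inv_rxp"], 1 / X[, "rxp"], ignore_attr = TRUE)
  expect_equal(10^tx[, "log10_lx"], X[, "rxp"] * X[, "Lp"],
               ignore_attr = TRUE)
})

test_that("calibrated parameters cluster by truth region above chance", {
  # two truth regions far apart in (nuM, lp1); PCA + clustering on the
  # true vectors recovers the split (pipeline smoke at the analysis end)
  set.seed(25)
  lowA <- cbind(phiMax = runif(10, 1e-4, 3e-4), Lp = runif(10, 1e-3, 3e-3),
                nuM = runif(10, 0.002, 0.004), tstar = runif(10, 50, 100),
                tauA = runif(10, 10, 50), tauS = runif(10, 5e-6, 7e-6),
                lp1 = runif(10, 1e-4, 3e-4), rxp = runif(10, 0.1, 0.2))
  hiB <- cbind(phiMax = runif(10, 5e-3, 9e-3), Lp = runif(10, 0.1, 0.3),
               nuM = runif(10, 0.1, 0.15), tstar = runif(10, 700, 900),
               tauA = runif(10, 500, 900), tauS = runif(10, 1.2e-5, 1.5e-5),
               lp1 = runif(10, 0.05, 0.1), rxp = runif(10, 0.5, 0.6))
  X <- log10(rbind(lowA, hiB))
  p <- pca_params(X)
  cl <- hcluster_scores(p, k = 2)
  truth <- rep(1:2, each = 10)
  agree <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_gt(agree, 0.9)
})
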