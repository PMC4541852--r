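test_that("ANOVA F and p match hand sums of squares on the worked case", {
  x <- matrix(c(1, 2, 3, 3, 4, 5), ncol = 1)
  g <- rep(c("soil", "tree"), each = 3)
  rep <- anovaFilter(x, g)
  # between-SS 6 on 1 df, within-SS 4 on 4 df -> F = 6 / (4/4) = 6
  expect_equal(fValues(rep), 6, tolerance = 1e-10)
  expect_equal(pValues(rep), 0.0705, tolerance = 1e-3)
  expect_false(keepMask(rep))  # p >= 0.05: dropped despite F > 2
})

test_that("ANOVA degenerate components follow the stated conventions", {
  x <- cbind(rep(4, 6),                       # constant everywhere
             c(0, 0, 0, 1, 1, 1),             # perfectly separated
             c(1, 2, 3, 3, 4, 5))
  g <- rep(c("soil", "tree"), each = 3)
  rep <- anovaFilter(x, g)
  expect_equal(fValues(rep)[1], 0)
  expect_equal(pValues(rep)[1], 1)
  expect_false(keepMask(rep)[1])
  expect_true(is.infinite(fValues(rep)[2]))
  expect_equal(pValues(rep)[2], 0)
  expect_true(keepMask(rep)[2])
  expect_error(anovaFilter(x, rep("soil", 6)), "2 classes")
  expect_error(anovaFilter(x, c("soil", rep("tree", 5))), "at least 2")
})

test_that("vectorized F values agree with R's linear-model ANOVA", {
  set.seed(31)
  for (trial in 1:5) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- matrix(rnorm((n1 + n2) * 7), n1 + n2, 7)
    g <- c(rep("soil", n1), rep("tree", n2))
    expect_equal(unname(fValues(anovaFilter(x, g))),
                 unname(anovaOracleF(x, g)), tolerance = 1e-10)
  }
})

test_that("F values are invariant to positive affine per-component scaling", {
  set.seed(32)
  x <- matrix(rnorm(80), 10, 8)
  g <- rep(c("soil", "tree"), each = 5)
  y <- sweep(sweep(x, 2, runif(8, 0.5, 3), "*"), 2, rnorm(8), "+")
  expect_equal(fValues(anovaFilter(x, g)), fValues(anovaFilter(y, g)),
               tolerance = 1e-9)
})

test_that("PCA recovers the eigenstructure of a known covariance", {
  # four points whose sample covariance is exactly diag(4, 1)
  x <- rbind(c(sqrt(6), 0), c(-sqrt(6), 0),
             c(0, sqrt(1.5)), c(0, -sqrt(1.5)))
  m <- pcaFit(x)
  expect_equal(eigenvalues(m), c(4, 1), tolerance = 1e-8)
  expect_equal(varExplained(m), c(0.8, 0.2), tolerance = 1e-8)
  expect_equal(abs(loadings(m)), diag(2), tolerance = 1e-8)
  # 1-component scores live on the variance-4 axis
  s <- pcaTransform(m, x, 1)
  expect_equal(drop(s), x[, 1], tolerance = 1e-8)
})

test_that("PCA explained variances match eigen() on random covariances", {
  set.seed(33)
  for (trial in 1:5) {
    x <- matrix(rnorm(20 * 4), 20, 4) %*% matrix(runif(16, -1, 1), 4, 4)
    m <- pcaFit(x)
    ev <- eigen(cov(x), symmetric = TRUE)$values
    ev <- ev[ev > max(ev) * 1e-12]
    expect_equal(eigenvalues(m), ev, tolerance = 1e-8)
    expect_equal(sum(eigenvalues(m)), sum(diag(cov(x))), tolerance = 1e-8)
  }
})

test_that("PCA model properties: orthonormality, isometry, decorrelation", {
  set.seed(34)
  x <- matrix(rnorm(15 * 6), 15, 6)
  m <- pcaFit(x)
  k <- ncol(loadings(m))
  expect_equal(crossprod(loadings(m)), diag(k), tolerance = 1e-8)
  # transform of the model's own mean is zero
  expect_equal(drop(pcaTransform(m, m@center, k)), rep(0, k),
               tolerance = 1e-10)
  # full transform is an isometry of the centered rows
  ctr <- sweep(x, 2, m@center)
  s <- pcaTransform(m, x, k)
  expect_equal(sqrt(rowSums(s^2)), sqrt(rowSums(ctr^2)), tolerance = 1e-8)
  # scores are uncorrelated, full reconstruction recovers the data
  expect_lt(max(abs(cov(s) - diag(eigenvalues(m)))), 1e-8)
  expect_equal(s %*% t(loadings(m)), ctr, tolerance = 1e-8)
  # sign convention: each loading's largest-magnitude entry is positive
  for (j in seq_len(k))
    expect_gt(loadings(m)[which.max(abs(loadings(m)[, j])), j], 0)
  expect_error(pcaTransform(m, x, k + 1), "outside")
  expect_error(pcaFit(x[1, , drop = FALSE]), "at least 2")
})

test_that("collinear data put all variance on the first component", {
  x <- cbind(1:8, 2 * (1:8) - 3)
  m <- pcaFit(x)
  expect_equal(varExplained(m)[1], 1, tolerance = 1e-12)
})

test_that("component-count selection returns the smallest best n", {
  fs <- smallDataset()
  sel <- selectComponentCount(fs, "fda", maxN = 1L, seed = 42)
  expect_equal(sel$bestN, 1L)
  expect_equal(nrow(sel$curve), 1L)
  sel5 <- selectComponentCount(fs, "fda", maxN = 5L, seed = 42)
  expect_equal(nrow(sel5$curve), 5L)
  best <- max(sel5$curve$meanCCP)
  expect_equal(sel5$bestN, min(which(sel5$curve$meanCCP == best)))
  # separable synthetic data reaches 100% somewhere on the curve
  expect_equal(best, 100)
})

test_that("texture components dominate color components on wrinkle-led data", {
  fs <- smallDataset()
  x <- t(featureMatrix(fs))
  z <- applyStandardizer(fitStandardizer(x), x)
  rep <- anovaFilter(z, batchLabels(fs))
  fv <- fValues(rep)
  # block-wide medians (Inf sorts above any finite value; zeros count):
  # texture is informative across far more bins than either color block
  expect_gt(median(fv[1:256]), median(fv[257:768]))
})
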