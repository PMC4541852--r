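test_that("histograms are normalized 256-bin frequencies", {
  h <- histogram256(matrix(0L, 4, 4))
  expect_length(h, 256L)
  expect_equal(h[1], 1)
  expect_equal(sum(h[-1]), 0)
  half <- histogram256(matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4))
  expect_equal(half[1], 0.5)
  expect_equal(half[256], 0.5)
  set.seed(21)
  g <- matrix(sample(0:255, 60, replace = TRUE), 6, 10)
  expect_equal(sum(histogram256(g)), 1)
  expect_true(all(histogram256(g) >= 0))
})

test_that("feature vectors concatenate the three histograms in order", {
  set.seed(22)
  img <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), dim = c(8, 8, 3))
  tr <- processSample(img)
  v <- concatFeatures(tr)
  expect_length(v, 768L)
  expect_equal(unname(v[1]), histogram256(tr@gradient)[1])
  expect_equal(unname(v[257]), histogram256(tr@crg)[1])
  expect_equal(unname(v[513]), histogram256(tr@crb)[1])
  # all-white source: every derived image is constant zero
  vw <- concatFeatures(processSample(flatRgb(255, 255, 255, 4, 4)))
  expect_equal(unname(vw[c(1, 257, 513)]), c(1, 1, 1))
  expect_equal(sum(vw), 3)
})

test_that("histograms are invariant to pixel permutation", {
  set.seed(23)
  g <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  gp <- matrix(sample(g), 8, 8)
  expect_equal(histogram256(g), histogram256(gp))
})

test_that("standardizer centers and scales with the n-1 denominator", {
  m <- fitStandardizer(matrix(c(1, 3), ncol = 1))
  z <- applyStandardizer(m, matrix(c(1, 3), ncol = 1))
  expect_equal(drop(z), c(-1, 1) / sqrt(2), tolerance = 1e-9)
  # constant components become all-zero columns, not NaN
  mc <- fitStandardizer(matrix(5, 3, 1))
  expect_equal(drop(applyStandardizer(mc, matrix(5, 3, 1))), c(0, 0, 0))
  expect_error(fitStandardizer(matrix(1, 1, 4)), "at least 2")
})

test_that("standardization is idempotent on its own statistics", {
  set.seed(24)
  x <- matrix(rnorm(60), 10, 6)
  z1 <- applyStandardizer(fitStandardizer(x), x)
  expect_equal(unname(colMeans(z1)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(z1, 2, sd)), rep(1, 6), tolerance = 1e-9)
  z2 <- applyStandardizer(fitStandardizer(z1), z1)
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("applying stored statistics to held-out rows never divides by zero", {
  set.seed(25)
  x <- cbind(rnorm(6), 7, rnorm(6))        # middle column constant
  m <- fitStandardizer(x)
  held <- cbind(rnorm(4), c(7, 8, 9, 7), rnorm(4))
  z <- applyStandardizer(m, held)
  expect_true(all(is.finite(z)))
  expect_equal(z[, 2], rep(0, 4))           # constant-at-fit column maps to 0
  # a row equal to the stored means maps to zero
  expect_equal(drop(applyStandardizer(m, m@center)), rep(0, 3))
  # one stored sd above each mean maps to one on non-constant components
  up <- m@center + m@scale * ifelse(m@constant, 0, 1)
  expect_equal(drop(applyStandardizer(m, up)), c(1, 0, 1))
})

test_that("extractFeatures assembles a labeled 768-row container", {
  imgs <- list(flatRgb(200, 120, 80, 6, 6), flatRgb(90, 130, 60, 6, 6))
  fs <- extractFeatures(imgs, labels = c("soil", "tree"))
  expect_s4_class(fs, "OliveFeatureSet")
  expect_equal(dim(featureMatrix(fs)), c(768L, 2L))
  expect_equal(as.character(batchLabels(fs)), c("soil", "tree"))
  expect_equal(colSums(featureMatrix(fs)), c(batch001 = 3, batch002 = 3))
  expect_error(extractFeatures(imgs, labels = c("soil", "ground")), "soil")
})
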