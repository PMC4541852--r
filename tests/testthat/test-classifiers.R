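# Fisher criterion in its scale-invariant form: squared projected mean
# difference over summed projected class scatters
fisherJ <- function(w, xs, xt) {
  ys <- drop(xs %*% w); yt <- drop(xt %*% w)
  (mean(ys) - mean(yt))^2 /
    (sum((ys - mean(ys))^2) + sum((yt - mean(yt))^2))
}

test_that("FDA direction is the mean difference under isotropic scatter", {
  # each class: mean +- c*e_i points, so within-class scatter is c^2*2*I
  mu <- c(3, 1, 2)
  spread <- rbind(diag(3), -diag(3)) * 1.5
  xs <- spread                       # class soil at the origin
  xt <- sweep(spread, 2, mu, "+")    # class tree at mu
  m <- fdaFit(rbind(xs, xt), rep(c("soil", "tree"), each = 6))
  cosine <- abs(sum(m@w * mu)) / sqrt(sum(m@w^2) * sum(mu^2))
  expect_gte(cosine, 1 - 1e-6)
})

test_that("fitted direction locally maximizes the Fisher criterion", {
  set.seed(41)
  for (trial in 1:4) {
    xs <- matrix(rnorm(8 * 3), 8, 3)
    xt <- matrix(rnorm(8 * 3, mean = 1.5), 8, 3)
    m <- fdaFit(rbind(xs, xt), rep(c("soil", "tree"), each = 8))
    j0 <- fisherJ(m@w, xs, xt)
    for (p in 1:25) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      wp <- m@w + 0.01 * sqrt(sum(m@w^2)) * u
      expect_lte(fisherJ(wp, xs, xt), j0 + 1e-9)
    }
  }
})

test_that("1-D well-separated classes put the boundary near the midpoint", {
  set.seed(42)
  ys <- matrix(rnorm(500, 0, 1), ncol = 1)
  yt <- matrix(rnorm(500, 10, 1), ncol = 1)
  m <- fdaFit(rbind(ys, yt), rep(c("soil", "tree"), each = 500))
  # find where the tree posterior crosses 0.5 on the original scale
  f <- function(v) fdaPredict(m, matrix(v, 1, 1))$tree - 0.5
  boundary <- uniroot(f, c(2, 8))$root
  expect_gt(boundary, 4.5)
  expect_lt(boundary, 5.5)
  # rows at the training means are classified with near certainty
  expect_gt(fdaPredict(m, matrix(10, 1, 1))$tree, 0.99)
  expect_gt(fdaPredict(m, matrix(0, 1, 1))$soil, 0.99)
})

test_that("FDA posteriors normalize, tie-break to soil, and identical means degrade gracefully", {
  set.seed(43)
  xs <- matrix(rnorm(12), 6, 2); xt <- matrix(rnorm(12), 6, 2)
  x <- rbind(xs, xt); g <- rep(c("soil", "tree"), each = 6)
  m <- fdaFit(x, g)
  pred <- fdaPredict(m, x)
  expect_equal(pred$soil + pred$tree, rep(1, 12), tolerance = 1e-12)
  # symmetric construction: equal priors/variances, midpoint row ties -> soil
  sym <- rbind(matrix(c(-1, -1, -3, 1, 1, 3), 3, 2),
               matrix(c(1, 1, 3, 1, 1, 3), 3, 2))
  ms <- fdaFit(sym, rep(c("soil", "tree"), each = 3))
  mid <- matrix(colMeans(sym), 1, 2)
  pmid <- fdaPredict(ms, mid)
  expect_equal(pmid$soil, 0.5, tolerance = 1e-9)
  expect_equal(as.character(pmid$label), "soil")
  expect_error(fdaFit(xs, rep("soil", 6)), "class")
})

test_that("FDA predictions are invariant to rescaling the projection", {
  set.seed(44)
  x <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 2), 10, 2))
  g <- rep(c("soil", "tree"), each = 10)
  m <- fdaFit(x, g)
  m2 <- m
  k <- 7.3
  m2@w <- m@w * k
  m2@means <- m@means * k
  m2@vars <- m@vars * k^2
  xnew <- matrix(rnorm(12, 1), 6, 2)
  expect_equal(fdaPredict(m, xnew)$tree, fdaPredict(m2, xnew)$tree,
               tolerance = 1e-9)
})

test_that("the perceptron learns linearly separable blobs perfectly", {
  set.seed(45)
  x <- rbind(matrix(rnorm(20, 0, 0.5), 10, 2),
             matrix(rnorm(20, 4, 0.5), 10, 2))
  g <- rep(c("soil", "tree"), each = 10)
  m <- mlpFit(x, g, seed = 99)
  pred <- mlpPredict(m, x)
  expect_equal(as.character(pred$label), g)
  expect_true(all(pred$score > 0 & pred$score < 1))
})

test_that("one hidden neuron cannot solve XOR above 75%", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  g <- c("soil", "soil", "tree", "tree")
  acc <- sapply(1:5, function(s) {
    m <- mlpFit(x, g, seed = s, maxEpochs = 2000)
    mean(as.character(mlpPredict(m, x)$label) == g)
  })
  expect_true(all(acc <= 0.75))
})

test_that("MLP training is deterministic and its loss non-increasing", {
  set.seed(46)
  x <- rbind(matrix(rnorm(16), 8, 2), matrix(rnorm(16, 2), 8, 2))
  g <- rep(c("soil", "tree"), each = 8)
  m1 <- mlpFit(x, g, seed = 7)
  m2 <- mlpFit(x, g, seed = 7)
  expect_identical(m1@iw, m2@iw)
  expect_identical(c(m1@b1, m1@ow, m1@b2), c(m2@b1, m2@ow, m2@b2))
  expect_true(all(diff(m1@lossTrace) <= 1e-12))
  expect_error(mlpFit(x, g), "seed")
  # boundary convention: score exactly 0.5 grades tree
  mb <- m1; mb@iw <- c(0, 0); mb@b1 <- 0; mb@ow <- 0; mb@b2 <- 0
  pb <- mlpPredict(mb, matrix(0, 1, 2))
  expect_equal(pb$score, 0.5)
  expect_equal(as.character(pb$label), "tree")
  expect_error(mlpPredict(m1, matrix(0, 1, 5)), "dimension")
})

test_that("FDA direction agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(47)
  x <- rbind(matrix(rnorm(40), 20, 2),
             matrix(rnorm(40, 1.2), 20, 2))
  g <- rep(c("soil", "tree"), each = 20)
  m <- fdaFit(x, g)
  ld <- MASS::lda(x, grouping = g)$scaling[, 1]
  cosine <- abs(sum(m@w * ld)) / sqrt(sum(m@w^2) * sum(ld^2))
  expect_gte(cosine, 1 - 1e-6)
})
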