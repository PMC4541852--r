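test_that("CCP is the trace over the total, times 100", {
  expect_equal(ccp(matrix(c(10, 0, 0, 10), 2, 2)), 100)
  expect_equal(ccp(matrix(c(8, 3, 2, 7), 2, 2)), 75)
  expect_equal(ccp(matrix(c(0, 5, 5, 0), 2, 2)), 0)
  set.seed(51)
  for (trial in 1:10) {
    cm <- matrix(sample(0:30, 4, replace = TRUE), 2, 2)
    if (sum(cm) == 0) next
    expect_equal(ccp(cm), 100 * (cm[1, 1] + cm[2, 2]) / sum(cm))
  }
  expect_error(ccp(matrix(0, 2, 2)), "empty")
  expect_error(ccp(matrix(1, 2, 3)), "square")
})

test_that("cross-validation folds partition the data and are stratified", {
  fs <- smallDataset()
  y <- batchLabels(fs)
  folds <- oliveGrade:::.cvFoldFits(fs, "text+rg+rb", anova = FALSE,
                                    repeats = 3L, seed = 42L)
  expect_length(folds, 6L)
  for (r in 1:3) {
    a <- folds[[2 * r - 1]]; b <- folds[[2 * r]]
    # fold swap: a's training labels are b's validation labels
    expect_equal(length(a$trainLabels), length(b$validLabels))
    expect_equal(table(a$trainLabels), table(b$validLabels))
    # stratification: each half holds half of each class
    expect_equal(sum(a$trainLabels == "soil"), 5)
    expect_equal(sum(a$trainLabels == "tree"), 5)
    expect_equal(sum(a$validLabels == "soil"), 5)
  }
})

test_that("cross-validation is bit-reproducible and aggregates fold CCPs", {
  fs <- smallDataset()
  r1 <- twoFoldCV(fs, "fda", nComponents = 2, seed = 42)
  r2 <- twoFoldCV(fs, "fda", nComponents = 2, seed = 42)
  expect_identical(r1@confusion, r2@confusion)
  expect_identical(repeatCCP(r1), repeatCCP(r2))
  expect_identical(meanCCP(r1), meanCCP(r2))
  expect_equal(r1@seeds, 42:44)
  # per-repeat CCP is the average of its two fold CCPs
  for (r in 1:3)
    expect_equal(repeatCCP(r1)[r],
                 mean(sapply(r1@confusion[[r]], ccp)))
  expect_equal(meanCCP(r1), mean(repeatCCP(r1)))
  # every confusion matrix accounts for the whole validation fold
  expect_true(all(sapply(unlist(r1@confusion, recursive = FALSE), sum)
                  == 10))
})

test_that("an out-of-range component request names both numbers", {
  fs <- smallDataset()
  expect_error(twoFoldCV(fs, "fda", nComponents = 500, seed = 42),
               "500.*exceeds")
})

test_that("permuted labels drive accuracy to chance", {
  fs <- smallDataset()
  set.seed(52)
  perm <- sample(ncol(fs))
  x <- featureMatrix(fs)
  fsPerm <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = x),
    rowData = SummarizedExperiment::rowData(fs),
    colData = S4Vectors::DataFrame(label = batchLabels(fs)[perm]))
  fsPerm <- new("OliveFeatureSet", fsPerm)
  res <- twoFoldCV(fsPerm, "fda", anova = FALSE, nComponents = 2,
                   seed = 42)
  expect_gt(meanCCP(res), 20)
  expect_lt(meanCCP(res), 80)
})

test_that("the variant grid reports all twelve pipeline combinations", {
  fs <- smallDataset()
  tab <- evaluateTable(fs, seed = 42, maxN = 3, repeats = 2)
  expect_equal(nrow(tab), 12L)
  expect_equal(sort(unique(tab$processing)),
               c("NORM+ANOVA+PCA", "NORM+PCA"))
  expect_equal(sort(unique(tab$information)),
               c("TEXT", "TEXT+RG", "TEXT+RG+RB"))
  expect_true(all(tab$meanCCP >= 0 & tab$meanCCP <= 100))
  expect_true(all(tab$nComponents >= 1))
})

test_that("a fitted grader serializes, round-trips and grades new images", {
  fs <- smallDataset()
  grader <- fitGrader(fs, "fda", nComponents = 2)
  pred <- gradeBatches(grader, fs)
  expect_gt(mean(as.character(pred$label) ==
                 as.character(batchLabels(fs))), 0.9)
  path1 <- tempfile(fileext = ".json")
  path2 <- tempfile(fileext = ".json")
  writeGrader(grader, path1)
  back <- readGrader(path1)
  writeGrader(back, path2)
  expect_identical(readLines(path1), readLines(path2))
  p <- smallParams()
  img <- generateBatch("tree", p, seed = 4242)
  expect_equal(as.character(gradeBatches(back, list(img))$label), "tree")
})
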