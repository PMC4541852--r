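#' Correct classification percentage of a confusion matrix
#'
#' The trace of the confusion matrix divided by the total number of
#' validated samples, times 100.
#'
#' @param cm a square numeric matrix of counts (rows = true class,
#'   columns = predicted class).
#' @return the percentage in [0, 100].
#' @examples
#' ccp(matrix(c(8, 3, 2, 7), 2, 2))  # 75
#' @export
ccp <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  100 * sum(diag(cm)) / total
}

# stratified half/half split: per class, the ceiling-half goes to fold 1
# (the fold that trains first), the rest to fold 2
.stratifiedHalves <- function(labels) {
  f1 <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    f1 <- c(f1, idx[seq_len(ceiling(length(idx) / 2))])
  }
  sort(f1)
}

# Fit the pipeline front end (standardizer -> optional ANOVA mask -> PCA)
# on the training fold only and project both folds onto all available
# components. Returns train/valid score matrices, labels, and a seed for
# classifier-side randomness.
.fitFrontEnd <- function(xtr, xva, ytr, information, anova) {
  cols <- .infoColumns(information)
  xtr <- xtr[, cols, drop = FALSE]
  xva <- xva[, cols, drop = FALSE]
  std <- fitStandardizer(xtr)
  ztr <- applyStandardizer(std, xtr)
  zva <- applyStandardizer(std, xva)
  report <- NULL
  if (anova) {
    report <- anovaFilter(ztr, ytr)
    mask <- keepMask(report)
    if (!any(mask))
      stop("ANOVA filter retained no components; disable the filter or ",
           "provide more discriminative data")
    ztr <- ztr[, mask, drop = FALSE]
    zva <- zva[, mask, drop = FALSE]
  }
  pca <- pcaFit(ztr)
  k <- ncol(loadings(pca))
  list(standardizer = std, report = report, pca = pca,
       trainScores = pcaTransform(pca, ztr, k),
       validScores = pcaTransform(pca, zva, k))
}

# All per-fold front-end fits for `repeats` repetitions of stratified
# 2-fold CV. Repeat r uses seed + r - 1 for its split and derives the two
# per-fold MLP initialization seeds from the same stream.
.cvFoldFits <- function(dataset, information, anova, repeats, seed) {
  stopifnot(is(dataset, "OliveFeatureSet"))
  xAll <- t(featureMatrix(dataset))
  y <- batchLabels(dataset)
  if (any(table(y) < 2L))
    stop("each class needs at least 2 samples for 2-fold CV")
  folds <- list()
  for (r in seq_len(repeats)) {
    seedR <- as.integer(seed) + r - 1L
    plan <- .withSeed(seedR, {
      f1 <- .stratifiedHalves(y)
      list(f1 = f1, mlpSeeds = sample.int(.Machine$integer.max - 1L, 2L))
    })
    inF1 <- seq_len(nrow(xAll)) %in% plan$f1
    for (it in 1:2) {
      tr <- if (it == 1L) inF1 else !inF1
      fit <- .fitFrontEnd(xAll[tr, , drop = FALSE],
                          xAll[!tr, , drop = FALSE],
                          y[tr], information, anova)
      fit$trainLabels <- y[tr]
      fit$validLabels <- y[!tr]
      fit$repeatIndex <- r
      fit$splitSeed <- seedR
      fit$mlpSeed <- plan$mlpSeeds[it]
      folds[[length(folds) + 1L]] <- fit
    }
  }
  folds
}

# Train/validate the classifier at a given component count over
# pre-computed fold fits and aggregate confusion matrices and CCPs.
.cvAggregate <- function(folds, classifier, nComponents, repeats) {
  confusion <- vector("list", repeats)
  foldCCP <- matrix(NA_real_, repeats, 2L)
  it <- integer(repeats)
  for (fit in folds) {
    avail <- ncol(fit$trainScores)
    if (nComponents > avail)
      stop("nComponents = ", nComponents, " exceeds the ", avail,
           " components available after filtering in a training fold")
    str <- fit$trainScores[, seq_len(nComponents), drop = FALSE]
    sva <- fit$validScores[, seq_len(nComponents), drop = FALSE]
    pred <- if (classifier == "fda") {
      fdaPredict(fdaFit(str, fit$trainLabels), sva)
    } else {
      mlpPredict(mlpFit(str, fit$trainLabels, seed = fit$mlpSeed), sva)
    }
    cm <- table(true = fit$validLabels, predicted = pred$label)
    cm <- matrix(as.integer(cm), 2L, 2L,
                 dimnames = list(true = c("soil", "tree"),
                                 predicted = c("soil", "tree")))
    r <- fit$repeatIndex
    it[r] <- it[r] + 1L
    confusion[[r]] <- c(confusion[[r]], list(cm))
    foldCCP[r, it[r]] <- ccp(cm)
  }
  repCCP <- rowMeans(foldCCP)
  list(confusion = confusion, repeatCCP = repCCP, meanCCP = mean(repCCP))
}

#' Stratified 2-fold cross-validation, repeated
#'
#' The evaluation protocol: each repetition splits the dataset into two
#' stratified halves; each half serves once as the training fold — fitting
#' the standardizer, the optional ANOVA mask, the PCA model and the
#' classifier — and once as the validation fold, scored with the
#' training-fold statistics only (no leakage). A repetition's CCP is the
#' average of its two fold CCPs; the result averages over repetitions.
#' Repetition r uses seed + r - 1, so results are bit-reproducible.
#'
#' @param dataset an \linkS4class{OliveFeatureSet}.
#' @param classifier \code{"fda"} (Fisher discriminant) or \code{"ann"}
#'   (the sigmoid perceptron).
#' @param information \code{"text"}, \code{"text+rg"} or
#'   \code{"text+rg+rb"} — which histogram blocks enter the feature
#'   vector.
#' @param anova logical: apply the ANOVA filter (the NORM+ANOVA+PCA
#'   processing) or not (NORM+PCA)?
#' @param nComponents number of leading PCA components for the classifier.
#' @param repeats number of repetitions (default 3).
#' @param seed integer RNG seed.
#' @return a \linkS4class{CvResult}.
#' @export
twoFoldCV <- function(dataset, classifier = c("fda", "ann"),
                      information = "text+rg+rb", anova = TRUE,
                      nComponents = 3L, repeats = 3L, seed = 42L) {
  classifier <- match.arg(classifier)
  information <- match.arg(information, c("text", "text+rg", "text+rg+rb"))
  nComponents <- as.integer(nComponents)
  repeats <- as.integer(repeats)
  folds <- .cvFoldFits(dataset, information, anova, repeats, seed)
  agg <- .cvAggregate(folds, classifier, nComponents, repeats)
  new("CvResult", confusion = agg$confusion, repeatCCP = agg$repeatCCP,
      meanCCP = agg$meanCCP,
      variant = list(classifier = classifier, information = information,
                     anova = anova, nComponents = nComponents),
      seeds = as.integer(seed) + seq_len(repeats) - 1L)
}

#' Evaluate the full grid of pipeline variants
#'
#' Runs every combination of classifier (FDA, ANN), feature processing
#' (NORM+PCA, NORM+ANOVA+PCA) and image information (TEXT, TEXT+RG,
#' TEXT+RG+RB) — twelve variants — selecting each variant's component
#' count with [selectComponentCount()] and reporting its mean CCP.
#'
#' @param dataset an \linkS4class{OliveFeatureSet}.
#' @param seed integer RNG seed shared by all variants.
#' @param maxN largest PCA component count tried per variant.
#' @param repeats repetitions of the 2-fold protocol.
#' @return a data.frame with columns \code{classifier}, \code{processing},
#'   \code{information}, \code{nComponents}, \code{meanCCP} (12 rows).
#' @export
evaluateTable <- function(dataset, seed = 42L, maxN = 15L, repeats = 3L) {
  grid <- expand.grid(classifier = c("fda", "ann"),
                      anova = c(FALSE, TRUE),
                      information = c("text", "text+rg", "text+rg+rb"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sel <- selectComponentCount(dataset, classifier = g$classifier,
                                information = g$information,
                                anova = g$anova, maxN = maxN,
                                repeats = repeats, seed = seed)
    data.frame(classifier = toupper(ifelse(g$classifier == "fda",
                                           "fda", "ann")),
               processing = if (g$anova) "NORM+ANOVA+PCA" else "NORM+PCA",
               information = toupper(g$information),
               nComponents = sel$bestN,
               meanCCP = sel$curve$meanCCP[sel$bestN])
  })
  do.call(rbind, rows)
}

#' Fit an end-to-end grader on a full dataset
#'
#' Convenience wrapper fitting the whole pipeline — standardizer, optional
#' ANOVA mask, PCA, classifier — on all samples of a dataset, producing a
#' deployable \linkS4class{OliveGrader}.
#'
#' @inheritParams twoFoldCV
#' @param seed RNG seed (used for ANN weight initialization).
#' @return an \linkS4class{OliveGrader}.
#' @export
fitGrader <- function(dataset, classifier = c("fda", "ann"),
                      information = "text+rg+rb", anova = TRUE,
                      nComponents = 3L, seed = 42L) {
  classifier <- match.arg(classifier)
  information <- match.arg(information, c("text", "text+rg", "text+rg+rb"))
  x <- t(featureMatrix(dataset))
  y <- batchLabels(dataset)
  cols <- .infoColumns(information)
  x <- x[, cols, drop = FALSE]
  std <- fitStandardizer(x)
  z <- applyStandardizer(std, x)
  report <- NULL
  if (anova) {
    report <- anovaFilter(z, y)
    if (!any(keepMask(report)))
      stop("ANOVA filter retained no components")
    z <- z[, keepMask(report), drop = FALSE]
  }
  pca <- pcaFit(z)
  nComponents <- as.integer(nComponents)
  k <- ncol(loadings(pca))
  if (nComponents > k)
    stop("nComponents = ", nComponents, " exceeds the ", k,
         " components available after filtering")
  s <- pcaTransform(pca, z, nComponents)
  model <- if (classifier == "fda") fdaFit(s, y)
           else mlpFit(s, y, seed = seed)
  new("OliveGrader", information = information, anova = anova,
      standardizer = std, report = report, pca = pca,
      nComponents = nComponents, model = model)
}

#' Grade new batch images with a fitted grader
#'
#' Applies the stored front end (standardizer, ANOVA mask, PCA) and
#' classifier to new data.
#'
#' @param grader an \linkS4class{OliveGrader}.
#' @param x an \linkS4class{OliveFeatureSet}, a samples x 768 feature
#'   matrix, a manifest data.frame/path, or a list of RGB arrays.
#' @return a data.frame with a \code{label} column plus the classifier's
#'   probability or score columns.
#' @export
gradeBatches <- function(grader, x) {
  stopifnot(is(grader, "OliveGrader"))
  if (is(x, "OliveFeatureSet")) {
    feats <- t(featureMatrix(x))
  } else if (is.matrix(x) && ncol(x) == 768L) {
    feats <- x
  } else if (is.list(x) && !is.data.frame(x)) {
    feats <- t(vapply(x, function(im) concatFeatures(processSample(im)),
                      numeric(768L)))
  } else {
    df <- if (is.data.frame(x)) x else readManifest(x)
    feats <- t(vapply(df$path,
                      function(p) concatFeatures(processSample(
                        readBatchImage(p))), numeric(768L)))
  }
  z <- applyStandardizer(grader@standardizer,
                         feats[, .infoColumns(grader@information),
                               drop = FALSE])
  if (grader@anova) z <- z[, keepMask(grader@report), drop = FALSE]
  s <- pcaTransform(grader@pca, z, grader@nComponents)
  if (is(grader@model, "FdaModel")) fdaPredict(grader@model, s)
  else mlpPredict(grader@model, s)
}
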