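#' One-way ANOVA feature filter
#'
#' Scores every component with the two-class one-way ANOVA F statistic
#' (between-class mean square over within-class mean square, df 1 and
#' n - 2) and its p-value, and retains a component iff F > 2 and p < 0.05.
#' A component with zero within-class variance but distinct class means is
#' infinitely discriminative: F = Inf, p = 0, kept. A component constant
#' across all samples carries no information: F = 0, p = 1, dropped.
#'
#' @param x a samples x components numeric matrix (standardized features).
#' @param labels a factor or character vector with exactly two distinct
#'   classes, at least two samples each.
#' @return an \linkS4class{AnovaReport}.
#' @export
anovaFilter <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L)
    stop("exactly 2 classes required, got ", nlevels(labels))
  n <- nrow(x)
  n1 <- sum(labels == levels(labels)[1L]); n2 <- n - n1
  if (min(n1, n2) < 2L)
    stop("each class needs at least 2 samples (got ", n1, " and ", n2, ")")
  g1 <- labels == levels(labels)[1L]
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  gm <- colMeans(x)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums(sweep(x[g1, , drop = FALSE], 2L, m1)^2) +
         colSums(sweep(x[!g1, , drop = FALSE], 2L, m2)^2)
  # degenerate bookkeeping: sswZero at machine scale relative to total SS
  tot <- ssb + ssw
  sswZero <- ssw <= tot * 1e-12
  fv <- numeric(ncol(x)); pv <- numeric(ncol(x))
  ok <- !sswZero
  fv[ok] <- (ssb[ok] / 1) / (ssw[ok] / (n - 2L))
  pv[ok] <- stats::pf(fv[ok], 1, n - 2L, lower.tail = FALSE)
  sep <- sswZero & ssb > 0      # perfectly separated component
  fv[sep] <- Inf; pv[sep] <- 0
  flat <- sswZero & ssb <= 0    # constant everywhere
  fv[flat] <- 0; pv[flat] <- 1
  new("AnovaReport", fValues = fv, pValues = pv,
      keepMask = fv > 2 & pv < 0.05)
}

#' Fit a principal component model
#'
#' Eigendecomposition of the sample covariance of the mean-centered rows
#' (computed through the singular value decomposition of the centered data
#' matrix, which yields the same eigenvectors and eigenvalues).
#' Components are ordered by decreasing eigenvalue; numerically zero
#' eigenvalues are discarded; each loading's sign is fixed so its
#' largest-magnitude entry is positive, making serialized models
#' reproducible.
#'
#' @param x a samples x components numeric matrix with at least two rows.
#' @return a \linkS4class{PcaModel}.
#' @export
pcaFit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("PCA needs at least 2 samples, got ", nrow(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  totalVar <- sum(ev)
  keep <- ev > max(ev, 0) * 1e-12 & ev > 0
  if (!any(keep)) stop("input has no variance; PCA is undefined")
  rot <- pc$rotation[, keep, drop = FALSE]
  ev <- ev[keep]
  # sign convention: largest-|entry| coordinate positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  new("PcaModel", center = unname(pc$center), loadings = unname(rot),
      eigenvalues = ev,
      varExplained = if (totalVar > 0) ev / totalVar else ev * 0)
}

#' Project rows onto the leading principal components
#'
#' Centers rows with the model's training mean and projects them onto the
#' first \code{nComponents} loadings.
#'
#' @param model a \linkS4class{PcaModel}.
#' @param x a samples x components matrix (or single row vector).
#' @param nComponents how many leading components to keep.
#' @return a samples x nComponents score matrix.
#' @export
pcaTransform <- function(model, x, nComponents) {
  stopifnot(is(model, "PcaModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  k <- ncol(model@loadings)
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L || nComponents > k)
    stop("nComponents = ", nComponents, " is outside 1..", k,
         " (components available in the model)")
  if (ncol(x) != length(model@center))
    stop("row dimension ", ncol(x), " does not match the fitted ",
         length(model@center), " inputs")
  sweep(x, 2L, model@center) %*% model@loadings[, seq_len(nComponents),
                                                drop = FALSE]
}

#' Select the number of PCA components by iterative evaluation
#'
#' Reproduces the iterative selection procedure: components are ordered by
#' explained variance; for n = 1..maxN the full cross-validated pipeline is
#' run with n components and the mean correct classification percentage
#' recorded; the smallest n attaining the maximum is returned, favouring
#' compact models when accuracy ties.
#'
#' @param dataset an \linkS4class{OliveFeatureSet}.
#' @param classifier \code{"fda"} or \code{"ann"}.
#' @param information \code{"text"}, \code{"text+rg"} or
#'   \code{"text+rg+rb"}.
#' @param anova logical: apply the ANOVA filter before PCA?
#' @param maxN largest component count to try; truncated (with a warning)
#'   to the components actually available in every training fold.
#' @param repeats number of 2-fold cross-validation repetitions.
#' @param seed RNG seed; repeats use seed, seed + 1, ...
#' @return a list with \code{bestN} (integer) and \code{curve} (a
#'   data.frame with columns \code{nComponents}, \code{meanCCP}).
#' @export
selectComponentCount <- function(dataset, classifier = c("fda", "ann"),
                                 information = "text+rg+rb", anova = TRUE,
                                 maxN = 15L, repeats = 3L, seed = 42L) {
  classifier <- match.arg(classifier)
  maxN <- as.integer(maxN)
  if (maxN < 1L) stop("maxN must be at least 1")
  folds <- .cvFoldFits(dataset, information, anova, repeats, seed)
  avail <- min(vapply(folds, function(f) ncol(f$trainScores), integer(1L)))
  if (maxN > avail) {
    warning("maxN = ", maxN, " exceeds the ", avail,
            " components available in the smallest training fold; using ",
            avail)
    maxN <- avail
  }
  mean_ccp <- vapply(seq_len(maxN), function(n)
    .cvAggregate(folds, classifier, n, repeats)$meanCCP, numeric(1L))
  best <- which.max(mean_ccp)  # first index at the max = smallest n
  list(bestN = as.integer(best),
       curve = data.frame(nComponents = seq_len(maxN), meanCCP = mean_ccp))
}
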