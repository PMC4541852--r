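#' 256-bin normalized gray-level histogram
#'
#' Bin k (k = 0..255) holds the fraction of pixels with value k, so the
#' bins are non-negative and sum to 1 regardless of image size.
#'
#' @param gray an H x W matrix of integer gray levels in [0, 255].
#' @return a numeric vector of 256 frequencies.
#' @examples
#' h <- histogram256(matrix(0L, 4, 4))
#' h[1]  # 1: every pixel is level 0
#' @export
histogram256 <- function(gray) {
  .assertGray(gray)
  tabulate(as.integer(gray) + 1L, nbins = 256L) / length(gray)
}

#' Concatenate the three histograms into a 768-component feature vector
#'
#' Component order is fixed: gradient histogram (1-256), red-green
#' difference histogram (257-512), red-blue difference histogram (513-768).
#' The prefix structure lets the textural-only (TEXT) and TEXT+RG
#' information variants be selected by slicing.
#'
#' @param triple a \linkS4class{ProcessedTriple}.
#' @return a named numeric vector of 768 histogram frequencies.
#' @export
concatFeatures <- function(triple) {
  stopifnot(is(triple, "ProcessedTriple"))
  v <- c(histogram256(triple@gradient),
         histogram256(triple@crg),
         histogram256(triple@crb))
  names(v) <- paste0(rep(c("gradient", "crg", "crb"), each = 256L),
                     "_bin", rep(0:255, 3L))
  v
}

#' Build an OliveFeatureSet from images or a manifest
#'
#' Runs the full image-analysis front end — grayscale conversion, Roberts
#' gradient, channel differences, histogram extraction, concatenation —
#' over a collection of batch images and assembles the labeled dataset
#' container.
#'
#' @param x either a manifest \code{data.frame} with columns \code{path}
#'   and \code{label} (see [readManifest()]), a path to a manifest CSV, or
#'   a list of H x W x 3 RGB arrays.
#' @param labels class labels (\code{"soil"}/\code{"tree"}), required when
#'   \code{x} is a list of arrays, ignored otherwise.
#' @return an \linkS4class{OliveFeatureSet}.
#' @export
extractFeatures <- function(x, labels = NULL) {
  if (is.character(x) && length(x) == 1L) x <- readManifest(x)
  if (is.data.frame(x)) {
    labels <- x$label
    imgs <- lapply(x$path, readBatchImage)
    ids <- basename(as.character(x$path))
  } else if (is.list(x)) {
    if (is.null(labels)) stop("'labels' is required for a list of images")
    imgs <- x
    ids <- if (!is.null(names(x))) names(x)
           else sprintf("batch%03d", seq_along(x))
  } else stop("'x' must be a manifest (path or data.frame) or image list")
  if (length(imgs) != length(labels))
    stop("got ", length(imgs), " images but ", length(labels), " labels")
  labels <- factor(as.character(labels), levels = c("soil", "tree"))
  if (anyNA(labels)) stop("labels must be 'soil' or 'tree'")
  feats <- vapply(imgs, function(im) concatFeatures(processSample(im)),
                  numeric(768L))
  colnames(feats) <- make.unique(ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feats),
    rowData = S4Vectors::DataFrame(
      block = rep(c("gradient", "crg", "crb"), each = 256L),
      bin = rep(0:255, 3L)),
    colData = S4Vectors::DataFrame(label = labels))
  new("OliveFeatureSet", se)
}

#' Fit a per-component standardizer
#'
#' Learns each component's mean and sample standard deviation (n - 1
#' denominator) from the training rows. Transformed components have mean 0
#' and standard deviation 1 over the fitting rows; zero-variance components
#' are flagged and map to all-zero columns instead of being dropped, so
#' component indices stay aligned with the 768-slot layout.
#'
#' @param x a samples x components numeric matrix (one feature vector per
#'   row), with at least two rows.
#' @return a \linkS4class{FeatureStandardizer}.
#' @export
fitStandardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("standardization needs at least 2 samples, got ", nrow(x))
  ctr <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  const <- s == 0
  s[const] <- 1  # placeholder; constant columns standardize to 0
  new("FeatureStandardizer", center = ctr, scale = s, constant = const)
}

#' Apply a fitted standardizer
#'
#' Transforms rows with the stored training statistics:
#' \code{(x - center) / scale} per component; components that were constant
#' at fit time map to 0. Using training-fold statistics on validation rows
#' is what keeps cross-validation leakage-free.
#'
#' @param standardizer a \linkS4class{FeatureStandardizer}.
#' @param x a samples x components matrix (or a single row vector).
#' @return the standardized matrix, same shape as \code{x}.
#' @export
applyStandardizer <- function(standardizer, x) {
  stopifnot(is(standardizer, "FeatureStandardizer"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(standardizer@center))
    stop("row dimension ", ncol(x), " does not match the fitted ",
         length(standardizer@center), " components")
  z <- sweep(sweep(x, 2L, standardizer@center), 2L, standardizer@scale, "/")
  z[, standardizer@constant] <- 0
  z
}

# column indices for the three information variants (prefix slicing)
.infoColumns <- function(information) {
  switch(information,
         "text" = 1:256,
         "text+rg" = 1:512,
         "text+rg+rb" = 1:768,
         stop("unknown information variant '", information,
              "'; use 'text', 'text+rg' or 'text+rg+rb'"))
}
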