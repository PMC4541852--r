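#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' The three derived grayscale images of one batch photograph
#'
#' Holds the Roberts-gradient texture image and the red-green / red-blue
#' channel-difference images computed from one RGB batch photograph. All
#' three share the source image's height and width and store integer
#' intensities in [0, 255].
#'
#' @slot gradient matrix, Roberts gradient magnitude of the grayscale image.
#' @slot crg matrix, red minus green channel, negatives clipped to 0.
#' @slot crb matrix, red minus blue channel, negatives clipped to 0.
#' @seealso [processSample()]
#' @export
setClass("ProcessedTriple",
  representation(gradient = "matrix", crg = "matrix", crb = "matrix"),
  validity = function(object) {
    d <- dim(object@gradient)
    if (!identical(d, dim(object@crg)) || !identical(d, dim(object@crb)))
      return("gradient, crg and crb must share dimensions")
    for (m in list(object@gradient, object@crg, object@crb))
      if (anyNA(m) || min(m) < 0 || max(m) > 255)
        return("all intensities must lie in [0, 255]")
    TRUE
  })

#' Container for a labeled olive-batch feature dataset
#'
#' Extends \linkS4class{SummarizedExperiment}: the single assay
#' \code{"features"} is a 768 x n matrix of raw (un-standardized) normalized
#' histogram frequencies, one column per batch image; \code{rowData} records
#' each component's source block (\code{gradient}, \code{crg}, \code{crb})
#' and gray-level bin (0-255); \code{colData$label} holds the class, a factor
#' with levels \code{soil}, \code{tree}.
#'
#' @seealso [extractFeatures()], [featureMatrix()], [batchLabels()]
#' @export
setClass("OliveFeatureSet", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"features" %in% SummarizedExperiment::assayNames(object))
      return("assay 'features' is required")
    if (nrow(object) != 768L)
      return("feature sets carry exactly 768 components")
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
      return("colData must contain a 'label' column")
    lab <- SummarizedExperiment::colData(object)$label
    if (!is.factor(lab) || !identical(levels(lab), c("soil", "tree")))
      return("labels must be a factor with levels 'soil', 'tree'")
    TRUE
  })

#' Per-component standardization parameters
#'
#' Stores the per-component mean and sample standard deviation (n - 1
#' denominator) learned from a training set of feature vectors.
#' Zero-variance components are flagged so they standardize to 0.
#'
#' @slot center numeric, per-component means.
#' @slot scale numeric, per-component sample standard deviations.
#' @slot constant logical, TRUE where the training column had zero variance.
#' @seealso [fitStandardizer()], [applyStandardizer()]
#' @export
setClass("FeatureStandardizer",
  representation(center = "numeric", scale = "numeric", constant = "logical"),
  validity = function(object) {
    n <- length(object@center)
    if (length(object@scale) != n || length(object@constant) != n)
      return("center, scale and constant must have equal length")
    if (any(object@scale[!object@constant] <= 0))
      return("non-constant components must have positive scale")
    TRUE
  })

#' One-way ANOVA feature-filter report
#'
#' Per-component F statistic (between-class over within-class mean square,
#' df 1 and n - 2), its p-value, and the keep mask: a component is retained
#' iff F > 2 and p < 0.05. Components with zero within-class variance but
#' distinct class means get F = Inf, p = 0 and are kept; components constant
#' across all samples get F = 0, p = 1 and are dropped.
#'
#' @slot fValues numeric, non-negative F statistics (possibly Inf).
#' @slot pValues numeric in [0, 1].
#' @slot keepMask logical.
#' @seealso [anovaFilter()]
#' @export
setClass("AnovaReport",
  representation(fValues = "numeric", pValues = "numeric",
                 keepMask = "logical"),
  validity = function(object) {
    n <- length(object@fValues)
    if (length(object@pValues) != n || length(object@keepMask) != n)
      return("fValues, pValues and keepMask must have equal length")
    if (any(object@fValues < 0, na.rm = TRUE))
      return("F values must be non-negative")
    if (any(object@pValues < 0 | object@pValues > 1))
      return("p values must lie in [0, 1]")
    expect <- object@fValues > 2 & object@pValues < 0.05
    if (!identical(unname(object@keepMask), unname(expect)))
      return("keepMask must equal (F > 2 & p < 0.05)")
    TRUE
  })

#' Principal component model
#'
#' Eigendecomposition of the sample covariance of mean-centered rows.
#' Loadings are orthonormal columns ordered by decreasing eigenvalue, each
#' sign-fixed so its largest-magnitude entry is positive.
#'
#' @slot center numeric, the training mean vector.
#' @slot loadings matrix, d x k orthonormal loading vectors.
#' @slot eigenvalues numeric, variances along each component.
#' @slot varExplained numeric, fractions of total variance, non-increasing.
#' @seealso [pcaFit()], [pcaTransform()]
#' @export
setClass("PcaModel",
  representation(center = "numeric", loadings = "matrix",
                 eigenvalues = "numeric", varExplained = "numeric"),
  validity = function(object) {
    k <- ncol(object@loadings)
    if (length(object@eigenvalues) != k || length(object@varExplained) != k)
      return("eigenvalues/varExplained must match loading count")
    if (nrow(object@loadings) != length(object@center))
      return("loadings must have one row per input dimension")
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(k))) > 1e-8)
      return("loadings must be orthonormal")
    if (is.unsorted(rev(object@varExplained)))
      return("explained-variance fractions must be non-increasing")
    if (sum(object@varExplained) > 1 + 1e-8)
      return("explained-variance fractions must sum to at most 1")
    TRUE
  })

#' Fisher discriminant model with Gaussian class densities
#'
#' The projection vector w maximizing the ratio of squared projected mean
#' difference to summed projected class variances, together with a 1-D normal
#' density per class fitted to the projections and class priors.
#'
#' @slot w numeric, the discriminant direction.
#' @slot means numeric, projected class means, named soil/tree.
#' @slot vars numeric, projected class variances (regularized > 0).
#' @slot priors numeric, class frequencies, sum to 1.
#' @seealso [fdaFit()], [fdaPredict()]
#' @export
setClass("FdaModel",
  representation(w = "numeric", means = "numeric", vars = "numeric",
                 priors = "numeric"),
  validity = function(object) {
    nm <- c("soil", "tree")
    if (!identical(names(object@means), nm) ||
        !identical(names(object@vars), nm) ||
        !identical(names(object@priors), nm))
      return("means, vars and priors must be named soil, tree")
    if (any(object@vars <= 0))
      return("projected class variances must be positive")
    if (abs(sum(object@priors) - 1) > 1e-12)
      return("priors must sum to 1")
    TRUE
  })

#' Single-hidden-neuron sigmoid perceptron
#'
#' The network topology is fixed: one sigmoid hidden neuron and one sigmoid
#' output neuron, so the score is
#' \eqn{f(b_2 + OW \cdot f(b_1 + IW^T x))} with \eqn{f} the logistic
#' function. Trained on soil = 0 / tree = 1 targets by minimizing mean
#' squared error with scaled conjugate gradient.
#'
#' @slot iw numeric, input weights (one per feature).
#' @slot b1 numeric(1), hidden bias.
#' @slot ow numeric(1), output weight.
#' @slot b2 numeric(1), output bias.
#' @slot lossTrace numeric, training loss at accepted steps.
#' @slot converged logical(1), TRUE if the gradient tolerance was met.
#' @seealso [mlpFit()], [mlpPredict()]
#' @export
setClass("MlpModel",
  representation(iw = "numeric", b1 = "numeric", ow = "numeric",
                 b2 = "numeric", lossTrace = "numeric",
                 converged = "logical"),
  validity = function(object) {
    if (length(object@b1) != 1L || length(object@ow) != 1L ||
        length(object@b2) != 1L)
      return("exactly one hidden neuron and one output neuron")
    TRUE
  })

#' A fitted end-to-end grading pipeline
#'
#' Bundles everything needed to grade a new batch image: the information
#' block in use, the standardizer, the optional ANOVA keep mask, the PCA
#' model with its retained component count, and the classifier.
#'
#' @slot information character(1), one of text, text+rg, text+rg+rb.
#' @slot anova logical(1), whether the ANOVA filter was applied.
#' @slot standardizer FeatureStandardizer.
#' @slot report AnovaReport or NULL.
#' @slot pca PcaModel.
#' @slot nComponents integer(1), retained principal components.
#' @slot model FdaModel or MlpModel.
#' @seealso [fitGrader()], [gradeBatches()]
#' @export
setClass("OliveGrader",
  representation(information = "character", anova = "logical",
                 standardizer = "FeatureStandardizer", report = "ANY",
                 pca = "PcaModel", nComponents = "integer", model = "ANY"))

#' Cross-validation result
#'
#' Result of stratified 2-fold cross-validation repeated several times:
#' per-repeat per-fold confusion matrices (rows = true class soil/tree,
#' columns = predicted), per-repeat correct classification percentages
#' (each the average of its two fold CCPs), their mean, the pipeline variant
#' descriptor and the seeds used.
#'
#' @slot confusion list of lists of 2 x 2 integer matrices.
#' @slot repeatCCP numeric, one CCP per repeat.
#' @slot meanCCP numeric(1) in [0, 100].
#' @slot variant list: classifier, information, anova, nComponents.
#' @slot seeds integer, one per repeat.
#' @seealso [twoFoldCV()]
#' @export
setClass("CvResult",
  representation(confusion = "list", repeatCCP = "numeric",
                 meanCCP = "numeric", variant = "list", seeds = "integer"),
  validity = function(object) {
    if (object@meanCCP < 0 || object@meanCCP > 100)
      return("mean CCP must lie in [0, 100]")
    if (length(object@repeatCCP) != length(object@confusion))
      return("one CCP per repeat required")
    TRUE
  })

#' Synthetic batch-image generator parameters
#'
#' Controls the synthetic olive-batch imagery: canvas size, olives per
#' batch, the tree-picked color palette, and the three orthogonal
#' class-effect channels — skin-wrinkle texture amplitude, oxidation brown
#' shift of the red channel, and dark debris spots — that distinguish
#' ground-collected batches. Setting all three effects to zero makes the two
#' class distributions coincide.
#'
#' @slot imageSize integer(2), height and width in pixels.
#' @slot nOlives integer(2), inclusive range of olives per batch.
#' @slot oliveAxes numeric(2), semi-axis range in pixels.
#' @slot palette matrix, 3 x k RGB base colors of tree-picked fruit.
#' @slot wrinkleAmplitude numeric(1), texture noise amplitude in gray levels.
#' @slot brownShift numeric(1), levels added to R relative to G and B.
#' @slot debrisCount integer(1), dark spots added to ground-class images.
#' @seealso [generatorParams()], [generateBatch()], [generateDataset()]
#' @export
setClass("GeneratorParams",
  representation(imageSize = "integer", nOlives = "integer",
                 oliveAxes = "numeric", palette = "matrix",
                 wrinkleAmplitude = "numeric", brownShift = "numeric",
                 debrisCount = "integer"),
  validity = function(object) {
    if (any(object@imageSize < 16L))
      return("imageSize must be at least 16 x 16")
    if (object@nOlives[1L] < 1L || object@nOlives[2L] < object@nOlives[1L])
      return("nOlives must be a non-empty positive range")
    if (object@oliveAxes[1L] <= 1 || object@oliveAxes[2L] < object@oliveAxes[1L])
      return("oliveAxes must be an increasing range above 1 pixel")
    if (nrow(object@palette) != 3L || any(object@palette < 0) ||
        any(object@palette > 255))
      return("palette must be a 3 x k matrix of RGB values in [0, 255]")
    if (object@wrinkleAmplitude < 0 || object@brownShift < 0 ||
        object@debrisCount < 0L)
      return("effect sizes must be non-negative")
    TRUE
  })
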