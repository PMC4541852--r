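#' Accessors for oliveGrade model objects
#'
#' Small accessor generics: \code{fValues}, \code{pValues} and
#' \code{keepMask} read an \linkS4class{AnovaReport}; \code{loadings},
#' \code{eigenvalues} and \code{varExplained} read a
#' \linkS4class{PcaModel}; \code{meanCCP} and \code{repeatCCP} read a
#' \linkS4class{CvResult}; \code{featureMatrix} and \code{batchLabels} read
#' an \linkS4class{OliveFeatureSet}.
#'
#' @param object the model or container object.
#' @return the stored component (a vector, matrix or factor).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fValues", function(object) standardGeneric("fValues"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("keepMask", function(object) standardGeneric("keepMask"))
#' @rdname accessors
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("varExplained", function(object) standardGeneric("varExplained"))
#' @rdname accessors
#' @export
setGeneric("meanCCP", function(object) standardGeneric("meanCCP"))
#' @rdname accessors
#' @export
setGeneric("repeatCCP", function(object) standardGeneric("repeatCCP"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("batchLabels", function(object) standardGeneric("batchLabels"))

setMethod("fValues", "AnovaReport", function(object) object@fValues)
setMethod("pValues", "AnovaReport", function(object) object@pValues)
setMethod("keepMask", "AnovaReport", function(object) object@keepMask)
setMethod("loadings", "PcaModel", function(object) object@loadings)
setMethod("eigenvalues", "PcaModel", function(object) object@eigenvalues)
setMethod("varExplained", "PcaModel", function(object) object@varExplained)
setMethod("meanCCP", "CvResult", function(object) object@meanCCP)
setMethod("repeatCCP", "CvResult", function(object) object@repeatCCP)
setMethod("featureMatrix", "OliveFeatureSet", function(object)
  SummarizedExperiment::assay(object, "features"))
setMethod("batchLabels", "OliveFeatureSet", function(object)
  SummarizedExperiment::colData(object)$label)

setMethod("show", "ProcessedTriple", function(object) {
  d <- dim(object@gradient)
  cat("ProcessedTriple:", d[1L], "x", d[2L],
      "gradient / C_rg / C_rb images\n")
})

setMethod("show", "AnovaReport", function(object) {
  fin <- is.finite(object@fValues)
  cat("AnovaReport on", length(object@fValues), "components\n",
      " kept:", sum(object@keepMask), "(F > 2 and p < 0.05)\n",
      " median finite F:", format(stats::median(object@fValues[fin]),
                                  digits = 4), "\n")
})

setMethod("show", "PcaModel", function(object) {
  k <- ncol(object@loadings)
  cat("PcaModel:", nrow(object@loadings), "->", k, "components\n",
      " variance explained by first", min(3L, k), "components:",
      format(100 * sum(object@varExplained[seq_len(min(3L, k))]),
             digits = 4), "%\n")
})

setMethod("show", "FdaModel", function(object) {
  cat("FdaModel on", length(object@w), "inputs\n",
      " projected means (soil, tree):",
      format(object@means, digits = 4), "\n",
      " priors:", format(object@priors, digits = 3), "\n")
})

setMethod("show", "MlpModel", function(object) {
  cat("MlpModel: ", length(object@iw),
      "-1-1 sigmoid network, trained ", length(object@lossTrace),
      " accepted steps, final MSE ",
      format(utils::tail(object@lossTrace, 1L), digits = 4),
      if (object@converged) " (converged)" else "", "\n", sep = "")
})

setMethod("show", "CvResult", function(object) {
  v <- object@variant
  cat("CvResult —", toupper(v$classifier), "|",
      if (isTRUE(v$anova)) "NORM+ANOVA+PCA" else "NORM+PCA", "|",
      toupper(v$information), "|", v$nComponents, "components\n",
      " per-repeat CCP:", paste(format(object@repeatCCP, digits = 4),
                                collapse = ", "), "\n",
      " mean CCP:", format(object@meanCCP, digits = 4), "%\n")
})

setMethod("show", "OliveGrader", function(object) {
  cat("OliveGrader:", toupper(class(object@model)), "on",
      object@nComponents, "PCA components,",
      if (object@anova) "ANOVA-filtered," else "unfiltered,",
      "information:", object@information, "\n")
})

setMethod("show", "GeneratorParams", function(object) {
  cat("GeneratorParams:", object@imageSize[1L], "x", object@imageSize[2L],
      "px,", object@nOlives[1L], "-", object@nOlives[2L], "olives\n",
      " wrinkle:", object@wrinkleAmplitude,
      " brown shift:", object@brownShift,
      " debris:", object@debrisCount, "\n")
})

setMethod("show", "OliveFeatureSet", function(object) {
  cat("OliveFeatureSet with", ncol(object), "batches (",
      sum(batchLabels(object) == "soil"), "soil /",
      sum(batchLabels(object) == "tree"), "tree ) x",
      nrow(object), "histogram components\n")
})
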