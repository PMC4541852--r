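#' Serialize a fitted grader to JSON
#'
#' Writes every parameter of the pipeline — information variant, ANOVA
#' report, standardizer statistics, PCA model, classifier weights — to a
#' single JSON file at full double precision. Round-trips are exact:
#' write, read and write again produces byte-identical files.
#'
#' @param grader an \linkS4class{OliveGrader}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @seealso [readGrader()]
#' @export
writeGrader <- function(grader, path) {
  stopifnot(is(grader, "OliveGrader"))
  m <- grader@model
  model <- if (is(m, "FdaModel")) {
    list(kind = "fda", w = m@w, means = as.list(m@means),
         vars = as.list(m@vars), priors = as.list(m@priors))
  } else {
    list(kind = "ann", iw = m@iw, b1 = m@b1, ow = m@ow, b2 = m@b2,
         lossTrace = m@lossTrace, converged = m@converged)
  }
  obj <- list(
    format = "oliveGrade-grader-v1",
    information = grader@information,
    anova = grader@anova,
    standardizer = list(center = grader@standardizer@center,
                        scale = grader@standardizer@scale,
                        constant = grader@standardizer@constant),
    report = if (is.null(grader@report)) NULL else
      list(fValues = grader@report@fValues,
           pValues = grader@report@pValues),
    pca = list(center = grader@pca@center,
               loadings = grader@pca@loadings,
               eigenvalues = grader@pca@eigenvalues,
               varExplained = grader@pca@varExplained),
    nComponents = grader@nComponents,
    model = model)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized grader back from JSON
#'
#' @param path a file written by [writeGrader()].
#' @return an \linkS4class{OliveGrader}.
#' @export
readGrader <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "oliveGrade-grader-v1"))
    stop("not an oliveGrade grader file: ", path)
  report <- NULL
  if (!is.null(obj$report)) {
    fv <- as.numeric(obj$report$fValues)
    pv <- as.numeric(obj$report$pValues)
    report <- new("AnovaReport", fValues = fv, pValues = pv,
                  keepMask = fv > 2 & pv < 0.05)
  }
  model <- if (identical(obj$model$kind, "fda")) {
    new("FdaModel", w = as.numeric(obj$model$w),
        means = unlist(obj$model$means)[c("soil", "tree")],
        vars = unlist(obj$model$vars)[c("soil", "tree")],
        priors = unlist(obj$model$priors)[c("soil", "tree")])
  } else {
    new("MlpModel", iw = as.numeric(obj$model$iw),
        b1 = as.numeric(obj$model$b1), ow = as.numeric(obj$model$ow),
        b2 = as.numeric(obj$model$b2),
        lossTrace = as.numeric(obj$model$lossTrace),
        converged = as.logical(obj$model$converged))
  }
  new("OliveGrader",
      information = obj$information, anova = obj$anova,
      standardizer = new("FeatureStandardizer",
                         center = as.numeric(obj$standardizer$center),
                         scale = as.numeric(obj$standardizer$scale),
                         constant = as.logical(obj$standardizer$constant)),
      report = report,
      pca = new("PcaModel", center = as.numeric(obj$pca$center),
                loadings = as.matrix(obj$pca$loadings),
                eigenvalues = as.numeric(obj$pca$eigenvalues),
                varExplained = as.numeric(obj$pca$varExplained)),
      nComponents = as.integer(obj$nComponents),
      model = model)
}

#' Serialize a cross-validation result to JSON
#'
#' Emits the variant descriptor, all seeds, per-repeat fold confusion
#' matrices, per-repeat CCPs and the mean CCP — the machine-readable
#' record of one evaluation run.
#'
#' @param result a \linkS4class{CvResult}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeCvResult <- function(result, path) {
  stopifnot(is(result, "CvResult"))
  obj <- list(
    format = "oliveGrade-cvresult-v1",
    variant = result@variant,
    seeds = result@seeds,
    confusion = lapply(result@confusion, function(rep)
      lapply(rep, function(cm) unname(apply(cm, 1L, identity,
                                            simplify = FALSE)))),
    repeatCCP = result@repeatCCP,
    meanCCP = result@meanCCP)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
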