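#' @name accessors
#' @title Accessors for ultraweed result objects
#'
#' @description Slot accessors for the S4 classes of the package; user code
#' should use these rather than \code{@}.
#'
#' @param object an ultraweed S4 object.
#' @return The corresponding slot value.
#'
#' @examples
#' cal <- defaultCalibration()
#' slope(cal)
#' intercept(cal)
NULL

#' @rdname accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))
#' @rdname accessors
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("adjRSquared", function(object) standardGeneric("adjRSquared"))
#' @rdname accessors
#' @export
setGeneric("roiCenter", function(object) standardGeneric("roiCenter"))
#' @rdname accessors
#' @export
setGeneric("roiRadius", function(object) standardGeneric("roiRadius"))
#' @rdname accessors
#' @export
setGeneric("houghScore", function(object) standardGeneric("houghScore"))
#' @rdname accessors
#' @export
setGeneric("plantPixels", function(object) standardGeneric("plantPixels"))
#' @rdname accessors
#' @export
setGeneric("backgroundPixels",
           function(object) standardGeneric("backgroundPixels"))
#' @rdname accessors
#' @export
setGeneric("coverageFraction",
           function(object) standardGeneric("coverageFraction"))
#' @rdname accessors
#' @export
setGeneric("canonicalCoefficients",
           function(object) standardGeneric("canonicalCoefficients"))
#' @rdname accessors
#' @export
setGeneric("canonicalEigenvalues",
           function(object) standardGeneric("canonicalEigenvalues"))
#' @rdname accessors
#' @export
setGeneric("groupCentroids", function(object) standardGeneric("groupCentroids"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("priors", function(object) standardGeneric("priors"))
#' @rdname accessors
#' @export
setGeneric("excludedPredictors",
           function(object) standardGeneric("excludedPredictors"))
#' @rdname accessors
#' @export
setGeneric("coefficientTable",
           function(object) standardGeneric("coefficientTable"))
#' @rdname accessors
#' @export
setGeneric("confusionPercent",
           function(object) standardGeneric("confusionPercent"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts",
           function(object) standardGeneric("confusionCounts"))

#' @rdname accessors
#' @export
setMethod("slope", "CalibrationModel", function(object) object@slope)
#' @rdname accessors
#' @export
setMethod("intercept", "CalibrationModel", function(object) object@intercept)
#' @rdname accessors
#' @export
setMethod("rSquared", "CalibrationModel", function(object) object@rSquared)
#' @rdname accessors
#' @export
setMethod("rSquared", "RegressionResult", function(object) object@rSquared)
#' @rdname accessors
#' @export
setMethod("adjRSquared", "RegressionResult",
          function(object) object@adjRSquared)
#' @rdname accessors
#' @export
setMethod("roiCenter", "ROICircle",
          function(object) c(x0 = object@x0, y0 = object@y0))
#' @rdname accessors
#' @export
setMethod("roiRadius", "ROICircle", function(object) object@r)
#' @rdname accessors
#' @export
setMethod("houghScore", "ROICircle", function(object) object@score)
#' @rdname accessors
#' @export
setMethod("plantPixels", "CoverageResult", function(object) object@pf)
#' @rdname accessors
#' @export
setMethod("backgroundPixels", "CoverageResult", function(object) object@pb)
#' @rdname accessors
#' @export
setMethod("coverageFraction", "CoverageResult", function(object) object@coverage)
#' @rdname accessors
#' @export
setMethod("canonicalCoefficients", "CDAModel",
          function(object) object@coefficients)
#' @rdname accessors
#' @export
setMethod("canonicalEigenvalues", "CDAModel",
          function(object) object@eigenvalues)
#' @rdname accessors
#' @export
setMethod("groupCentroids", "CDAModel", function(object) object@centroids)
#' @rdname accessors
#' @export
setMethod("groupLabels", "CDAModel", function(object) object@groupLabels)
#' @rdname accessors
#' @export
setMethod("priors", "CDAModel", function(object) object@priors)
#' @rdname accessors
#' @export
setMethod("excludedPredictors", "RegressionResult",
          function(object) object@excluded)
#' @rdname accessors
#' @export
setMethod("coefficientTable", "RegressionResult",
          function(object) object@coefficients)
#' @rdname accessors
#' @export
setMethod("confusionPercent", "ConfusionMatrix", function(object) object@percent)
#' @rdname accessors
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(object) object@counts)

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel: d [cm] =", format(object@slope), "* v [V] +",
      format(object@intercept), "\n  R-squared:", format(object@rSquared), "\n")
})

setMethod("show", "ROICircle", function(object) {
  cat(sprintf("ROICircle: centre (x0 = %g, y0 = %g), r = %g px, score = %g\n",
              object@x0, object@y0, object@r, object@score))
})

setMethod("show", "CoverageResult", function(object) {
  cat(sprintf("CoverageResult: pf = %d, pb = %d, coverage = %.4f\n",
              as.integer(object@pf), as.integer(object@pb), object@coverage))
})

setMethod("show", "RegressionResult", function(object) {
  cat("RegressionResult for response '", object@response, "'\n", sep = "")
  print(object@coefficients, row.names = FALSE, digits = 4)
  if (length(object@excluded))
    cat("Excluded by backward elimination:",
        paste(object@excluded, collapse = ", "), "\n")
  cat(sprintf("R-squared = %.4f, adjusted R-squared = %.4f\n",
              object@rSquared, object@adjRSquared))
})

setMethod("show", "CDAModel", function(object) {
  cat("CDAModel:", length(object@groupLabels), "groups,",
      ncol(object@coefficients), "canonical axes\n")
  cat("  eigenvalues:", paste(format(object@eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  cat("  groups:", paste(object@groupLabels, collapse = ", "), "\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (row percentages, rows = true group):\n")
  print(round(object@percent, 1))
})
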