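#' @import methods
NULL

#' Linear voltage-to-distance calibration
#'
#' Maps the 0--10 V output of an ultrasonic distance sensor to a distance in
#' centimetres via \code{d = slope * v + intercept}. The default model is the
#' factory-style field calibration \code{d = 7.0275 v + 29.658} (R^2 = 0.99).
#'
#' @slot slope cm per volt; must be strictly positive.
#' @slot intercept cm; distance returned at 0 V.
#' @slot rSquared coefficient of determination of the calibration fit, in
#'   \code{[0, 1]}.
#'
#' @seealso [defaultCalibration()], [fitCalibration()], [voltageToDistance()]
#' @export
setClass("CalibrationModel",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric"),
  prototype(slope = 7.0275, intercept = 29.658, rSquared = 0.99))

setValidity("CalibrationModel", function(object) {
  msg <- NULL
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    msg <- c(msg, "'slope' must be a single positive finite number")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "'intercept' must be a single finite number")
  if (length(object@rSquared) != 1L || is.na(object@rSquared) ||
      object@rSquared < 0 || object@rSquared > 1)
    msg <- c(msg, "'rSquared' must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Ultrasonic sensor configuration
#'
#' Operating parameters of the downward-pointing ultrasonic sensor: the
#' reference distance to bare ground, the configured sensing range (echoes
#' outside it are flagged by the device), and the error sentinel voltage the
#' device emits for out-of-range echoes (its full-scale output).
#'
#' @slot referenceDistance cm; sensor height over weed-free ground
#'   (default 80, i.e. 0.80 m).
#' @slot rangeMin,rangeMax sensing window in mm (defaults 350 and 1000).
#' @slot errorSentinel volts; emitted for erroneous measurements
#'   (default 10 V, the full-scale output).
#' @slot fullScale volts; upper end of the output range (default 10).
#'
#' @export
setClass("SensorConfig",
  representation(referenceDistance = "numeric", rangeMin = "numeric",
                 rangeMax = "numeric", errorSentinel = "numeric",
                 fullScale = "numeric"),
  prototype(referenceDistance = 80, rangeMin = 350, rangeMax = 1000,
            errorSentinel = 10, fullScale = 10))

setValidity("SensorConfig", function(object) {
  msg <- NULL
  if (!(object@rangeMin > 0 && object@rangeMin < object@rangeMax))
    msg <- c(msg, "need 0 < rangeMin < rangeMax (mm)")
  refmm <- object@referenceDistance * 10
  if (!(refmm >= object@rangeMin && refmm <= object@rangeMax))
    msg <- c(msg, "referenceDistance (cm) must fall inside the sensing window")
  if (object@fullScale <= 0)
    msg <- c(msg, "fullScale must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Per-channel HSV thresholds for frame segmentation
#'
#' Inclusive intervals on the 8-bit HSV scale used to segment the grey
#' circular measurement frame. Defaults are H in [116, 255], S in [0, 128],
#' V in [31, 255].
#'
#' @slot h,s,v numeric length-2 inclusive intervals on the 0--255 scale.
#'
#' @seealso [segmentFrame()]
#' @export
setClass("HsvThresholds",
  representation(h = "numeric", s = "numeric", v = "numeric"),
  prototype(h = c(116, 255), s = c(0, 128), v = c(31, 255)))

setValidity("HsvThresholds", function(object) {
  ok <- function(iv) length(iv) == 2L && all(is.finite(iv)) &&
    iv[1] <= iv[2] && iv[1] >= 0 && iv[2] <= 255
  msg <- NULL
  for (ch in c("h", "s", "v"))
    if (!ok(slot(object, ch)))
      msg <- c(msg, sprintf("'%s' must be an interval [lo, hi] within [0, 255]",
                            ch))
  if (is.null(msg)) TRUE else msg
})

#' Detected circular region of interest
#'
#' A circle \code{(x - x0)^2 + (y - y0)^2 = r^2} in image coordinates
#' (0-based, \code{x} = column, \code{y} = row), together with the number of
#' object pixels supporting it in the Hough accumulator.
#'
#' @slot x0,y0 centre, 0-based pixel coordinates.
#' @slot r radius in pixels.
#' @slot score accumulator support (number of voting object pixels).
#'
#' @seealso [houghCircle()], [shrinkRoi()], [applyRoi()]
#' @export
setClass("ROICircle",
  representation(x0 = "numeric", y0 = "numeric", r = "numeric",
                 score = "numeric"),
  prototype(x0 = 0, y0 = 0, r = 1, score = 1))

setValidity("ROICircle", function(object) {
  msg <- NULL
  if (object@r <= 0) msg <- c(msg, "'r' must be positive")
  if (object@score < 1) msg <- c(msg, "'score' must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Plant-coverage measurement within an ROI
#'
#' Counts of plant (foreground) and background pixels inside the region of
#' interest, and the coverage ratio \code{C = pf / (pf + pb)}.
#'
#' @slot pf plant-pixel count.
#' @slot pb background-pixel count.
#' @slot coverage fraction \code{pf / (pf + pb)}.
#'
#' @seealso [plantCoverage()]
#' @export
setClass("CoverageResult",
  representation(pf = "numeric", pb = "numeric", coverage = "numeric"),
  prototype(pf = 0, pb = 1, coverage = 0))

setValidity("CoverageResult", function(object) {
  msg <- NULL
  if (object@pf < 0 || object@pb < 0)
    msg <- c(msg, "pixel counts must be non-negative")
  if (object@pf + object@pb > 0 &&
      abs(object@coverage - object@pf / (object@pf + object@pb)) > 1e-12)
    msg <- c(msg, "coverage must equal pf / (pf + pb)")
  if (is.null(msg)) TRUE else msg
})

#' Multiple-regression report with backward elimination
#'
#' Final ordinary-least-squares model after backward elimination of
#' non-significant predictors, with raw and standardized coefficients
#' (standardized = raw * sd(x) / sd(y)), standard errors, p-values, the list
#' of excluded predictors, and (adjusted) R-squared.
#'
#' @slot coefficients data.frame with columns \code{term}, \code{estimate},
#'   \code{std_estimate}, \code{std_error}, \code{p_value} (intercept row has
#'   \code{NA} standardized coefficient).
#' @slot excluded character; predictors removed by elimination.
#' @slot rSquared,adjRSquared fit statistics of the final model.
#' @slot response name of the response variable.
#'
#' @seealso [multipleRegression()]
#' @export
setClass("RegressionResult",
  representation(coefficients = "data.frame", excluded = "character",
                 rSquared = "numeric", adjRSquared = "numeric",
                 response = "character"))

setValidity("RegressionResult", function(object) {
  need <- c("term", "estimate", "std_estimate", "std_error", "p_value")
  msg <- NULL
  if (!all(need %in% names(object@coefficients)))
    msg <- c(msg, paste("coefficients table needs columns:",
                        paste(need, collapse = ", ")))
  if (length(object@adjRSquared) == 1L && length(object@rSquared) == 1L &&
      is.finite(object@adjRSquared) && is.finite(object@rSquared) &&
      object@adjRSquared > object@rSquared + 1e-12)
    msg <- c(msg, "adjusted R-squared cannot exceed R-squared")
  if (is.null(msg)) TRUE else msg
})

#' Canonical discriminant model
#'
#' Canonical directions maximizing between-group relative to within-group
#' scatter, obtained from the eigen-decomposition of \code{W^-1 B}. Axes are
#' scaled to unit pooled within-group variance (\code{a' W a = 1}).
#'
#' @slot coefficients features x axes matrix of canonical coefficients.
#' @slot eigenvalues canonical eigenvalues, sorted decreasing, all >= 0.
#' @slot centroids groups x axes matrix of group centroids in canonical space.
#' @slot groupLabels group labels, in the (factor) order used for tie-breaks.
#' @slot priors per-group prior probabilities (sum to 1).
#' @slot featureMeans grand means used for centring before projection.
#'
#' @seealso [cdaFit()], [cdaClassify()]
#' @export
setClass("CDAModel",
  representation(coefficients = "matrix", eigenvalues = "numeric",
                 centroids = "matrix", groupLabels = "character",
                 priors = "numeric", featureMeans = "numeric"))

setValidity("CDAModel", function(object) {
  msg <- NULL
  g <- length(object@groupLabels)
  p <- nrow(object@coefficients)
  k <- ncol(object@coefficients)
  if (k > min(g - 1L, p))
    msg <- c(msg, "number of canonical axes exceeds min(groups - 1, features)")
  if (any(object@eigenvalues < -1e-8))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be sorted decreasing")
  if (length(object@priors) != g || abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must be one probability per group, summing to 1")
  if (nrow(object@centroids) != g || ncol(object@centroids) != k)
    msg <- c(msg, "centroids must be groups x axes")
  if (is.null(msg)) TRUE else msg
})

#' Row-normalized confusion matrix
#'
#' Classification outcome as row percentages (rows = true group, columns =
#' predicted group) together with the raw counts.
#'
#' @slot percent matrix of row percentages; each row sums to 100.
#' @slot counts matrix of raw counts in the same layout.
#'
#' @seealso [confusionPercentages()]
#' @export
setClass("ConfusionMatrix",
  representation(percent = "matrix", counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  rs <- rowSums(object@percent)
  if (any(abs(rs - 100) > 0.1))
    "each percentage row must sum to 100 (within 0.1)"
  else TRUE
})

#' Study-level processing configuration
#'
#' Bundles every tunable of the per-sample processing chain and the
#' study-level statistics: sensor configuration and calibration, HSV
#' thresholds, median-filter size, Hough radius search range, ROI shrink
#' margin, excess-green threshold fraction, regression/discriminant options
#' and the random seed.
#'
#' @slot sensor a [SensorConfig-class].
#' @slot calibration a [CalibrationModel-class].
#' @slot thresholds an [HsvThresholds-class].
#' @slot radii integer vector of candidate Hough radii (pixels).
#' @slot medianSize binary median window size (pixels, default 10).
#' @slot shrinkMargin ROI shrink margin (pixels, default 10).
#' @slot exgFraction excess-green threshold fraction (default 0.08).
#' @slot alphaDrop backward-elimination p-value threshold (default 0.10).
#' @slot priors "equal" or "proportional" CDA priors.
#' @slot cdaFeatures features used by the discriminant analyses.
#' @slot regressionPredictors candidate predictors of ultrasonic height.
#' @slot seed integer seed for anything stochastic downstream.
#'
#' @seealso [studyConfig()], [runStudy()]
#' @export
setClass("StudyConfig",
  representation(sensor = "SensorConfig", calibration = "CalibrationModel",
                 thresholds = "HsvThresholds", radii = "integer",
                 medianSize = "integer", shrinkMargin = "integer",
                 exgFraction = "numeric", alphaDrop = "numeric",
                 priors = "character", cdaFeatures = "character",
                 regressionPredictors = "character", seed = "integer"))

setValidity("StudyConfig", function(object) {
  msg <- NULL
  if (length(object@radii) < 1L || any(object@radii < 1L))
    msg <- c(msg, "radii must be a non-empty vector of positive integers")
  if (object@medianSize < 1L) msg <- c(msg, "medianSize must be >= 1")
  if (object@shrinkMargin < 0L) msg <- c(msg, "shrinkMargin must be >= 0")
  if (object@exgFraction <= 0 || object@exgFraction >= 1)
    msg <- c(msg, "exgFraction must lie in (0, 1)")
  if (!(object@priors %in% c("equal", "proportional")))
    msg <- c(msg, "priors must be 'equal' or 'proportional'")
  if (is.null(msg)) TRUE else msg
})
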