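#' Default ultrasonic calibration model
#'
#' The field calibration of the downward-pointing ultrasonic sensor,
#' converting its 0--10 V output into a distance in cm:
#' \code{d = 7.0275 v + 29.658}, established with an R-squared of 0.99.
#'
#' @return A [CalibrationModel-class].
#' @examples
#' voltageToDistance(0, defaultCalibration())  # 29.658 cm
#' @export
defaultCalibration <- function() new("CalibrationModel")

#' Construct a sensor configuration
#'
#' @param referenceDistance sensor height over weed-free ground in cm
#'   (default 80).
#' @param rangeMin,rangeMax configured sensing window in mm (defaults 350 and
#'   1000); echoes outside it are signalled as erroneous by the device.
#' @param errorSentinel voltage emitted for erroneous measurements (default
#'   10 V, the full-scale output).
#' @param fullScale upper end of the voltage output range (default 10 V).
#' @return A [SensorConfig-class].
#' @export
sensorConfig <- function(referenceDistance = 80, rangeMin = 350,
                         rangeMax = 1000, errorSentinel = 10, fullScale = 10) {
  new("SensorConfig", referenceDistance = referenceDistance,
      rangeMin = rangeMin, rangeMax = rangeMax,
      errorSentinel = errorSentinel, fullScale = fullScale)
}

#' Convert sensor voltages to distances
#'
#' Applies the linear calibration \code{d = slope * v + intercept}. Voltages
#' equal to the error sentinel (the device's flag for echoes outside the
#' sensing window) yield \code{NA}: they are invalid readings, not distances.
#'
#' @param v numeric vector of voltages in \code{[0, fullScale]}.
#' @param calib a [CalibrationModel-class] (default [defaultCalibration()]).
#' @param cfg a [SensorConfig-class] supplying the sentinel and full scale.
#' @return Numeric vector of distances in cm, \code{NA} where \code{v} is the
#'   sentinel.
#' @examples
#' voltageToDistance(c(0, 1), defaultCalibration())
#' @export
voltageToDistance <- function(v, calib = defaultCalibration(),
                              cfg = sensorConfig()) {
  stopifnot(is(calib, "CalibrationModel"), is(cfg, "SensorConfig"))
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("voltages must be finite numbers")
  if (any(v < 0 | v > cfg@fullScale))
    stop("voltages must lie in [0, ", cfg@fullScale, "] V")
  d <- calib@slope * v + calib@intercept
  d[v == cfg@errorSentinel] <- NA_real_
  d
}

#' Invert the calibration: distance to noiseless voltage
#'
#' Exact inverse of [voltageToDistance()] for in-window distances; used by the
#' synthetic trace generator and for round-trip checks.
#'
#' @param d numeric vector of distances in cm.
#' @inheritParams voltageToDistance
#' @return Voltages in volts.
#' @export
distanceToVoltage <- function(d, calib = defaultCalibration()) {
  stopifnot(is(calib, "CalibrationModel"))
  (d - calib@intercept) / calib@slope
}

#' Fit a voltage-to-distance calibration by ordinary least squares
#'
#' Regresses tape-measured distances on sensor voltages, as in a calibration
#' step where readings over the whole sensing range are compared with a tape
#' measure.
#'
#' @param volts sensor voltages.
#' @param distances tape-measured distances in cm, same length.
#' @return A [CalibrationModel-class] with the fitted slope, intercept and
#'   R-squared.
#' @examples
#' v <- seq(0, 10, by = 0.5)
#' fitCalibration(v, 7.0275 * v + 29.658)
#' @export
fitCalibration <- function(volts, distances) {
  stopifnot(length(volts) == length(distances))
  keep <- is.finite(volts) & is.finite(distances)
  volts <- volts[keep]; distances <- distances[keep]
  if (length(unique(volts)) < 2L)
    stop("calibration needs at least 2 distinct voltages")
  fit <- stats::lm(distances ~ volts)
  sl <- unname(stats::coef(fit)[2])
  if (!is.finite(sl) || sl <= 0)
    stop("fitted slope is not positive; check the calibration pairs")
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new("CalibrationModel", slope = sl,
      intercept = unname(stats::coef(fit)[1]),
      rSquared = min(max(r2, 0), 1))
}

#' Reference distance from an initial weed-free trace
#'
#' Averages calibrated distance readings over the first \code{window} seconds
#' of a trace taken over weed-free ground; the result is stored as the sensor
#' height over ground for later height-by-subtraction.
#'
#' @param trace data.frame with columns \code{t_seconds} and \code{volts}.
#' @param window averaging window in seconds (default 10).
#' @inheritParams voltageToDistance
#' @return Reference distance in cm.
#' @details Any sentinel (erroneous) or out-of-range reading inside the window
#'   is an error: the reference must come from clean in-range ground echoes.
#' @export
referenceDistance <- function(trace, window = 10,
                              calib = defaultCalibration(),
                              cfg = sensorConfig()) {
  stopifnot(is.data.frame(trace),
            all(c("t_seconds", "volts") %in% names(trace)))
  t0 <- trace$t_seconds[1]
  if (max(trace$t_seconds) - t0 < window)
    stop("trace is shorter than the averaging window (", window, " s)")
  inwin <- trace$t_seconds - t0 < window
  d <- voltageToDistance(trace$volts[inwin], calib, cfg)
  if (anyNA(d))
    stop("sentinel reading inside the reference window; ",
         "reference ground must be in range and weed-free")
  dmm <- d * 10
  if (any(dmm < cfg@rangeMin | dmm > cfg@rangeMax))
    stop("reference window contains out-of-range distances")
  mean(d)
}

#' Plant height by subtraction from the reference distance
#'
#' Height is the reference distance minus the measured distance; a reading is
#' valid only when the distance (in mm) lies inside the configured sensing
#' window.
#'
#' @param distance numeric vector of calibrated distances in cm (\code{NA} =
#'   sentinel reading).
#' @param cfg a [SensorConfig-class].
#' @return data.frame with columns \code{distance}, \code{height} (cm; \code{NA}
#'   when invalid) and \code{valid}.
#' @examples
#' estimateHeight(76.3)         # height 3.7 cm
#' estimateHeight(30)           # 300 mm < 350 mm: invalid
#' @export
estimateHeight <- function(distance, cfg = sensorConfig()) {
  stopifnot(is(cfg, "SensorConfig"))
  dmm <- distance * 10
  valid <- !is.na(distance) & dmm >= cfg@rangeMin & dmm <= cfg@rangeMax
  height <- ifelse(valid, cfg@referenceDistance - distance, NA_real_)
  data.frame(distance = distance, height = height, valid = valid)
}

#' Summarize a trace segment into one sample height
#'
#' Converts a segment of the continuous voltage measurements taken at a
#' sampling point into a mean plant height over the valid readings, reporting
#' how many readings were invalid (sentinel or out of range).
#'
#' @param trace data.frame with columns \code{t_seconds} and \code{volts}.
#' @inheritParams voltageToDistance
#' @param cfg a [SensorConfig-class].
#' @return list with \code{meanHeight} (cm), \code{nValid}, \code{nInvalid}.
#' @export
summarizeSample <- function(trace, calib = defaultCalibration(),
                            cfg = sensorConfig()) {
  stopifnot(is.data.frame(trace), "volts" %in% names(trace),
            nrow(trace) > 0)
  d <- voltageToDistance(trace$volts, calib, cfg)
  h <- estimateHeight(d, cfg)
  nv <- sum(h$valid)
  if (nv == 0L)
    stop("no valid readings in segment (all sentinel or out of range)")
  list(meanHeight = mean(h$height[h$valid]),
       nValid = nv, nInvalid = nrow(trace) - nv)
}

#' Read / write voltage trace CSV
#'
#' Traces are stored as CSV with columns \code{t_seconds} and \code{volts}.
#'
#' @param path file path.
#' @return \code{readTrace} returns the trace data.frame.
#' @export
readTrace <- function(path) {
  tr <- utils::read.csv(path)
  stopifnot(all(c("t_seconds", "volts") %in% names(tr)))
  tr
}

#' @rdname readTrace
#' @param trace trace data.frame.
#' @export
writeTrace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a calibration model as JSON
#'
#' @param path file path.
#' @return \code{readCalibration} returns a [CalibrationModel-class].
#' @export
readCalibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationModel", slope = x$slope, intercept = x$intercept,
      rSquared = x$r_squared)
}

#' @rdname readCalibration
#' @param calib a [CalibrationModel-class].
#' @export
writeCalibration <- function(calib, path) {
  jsonlite::write_json(list(slope = calib@slope, intercept = calib@intercept,
                            r_squared = calib@rSquared),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
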