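#' Construct a study configuration
#'
#' Collects the tunables of the whole-study pipeline; defaults equal the
#' printed parameters of the measurement protocol (HSV frame thresholds,
#' median size 10, ROI shrink 10 px, ExG fraction 0.08, elimination threshold
#' 0.10, equal priors).
#'
#' @param sensor a [SensorConfig-class].
#' @param calibration a [CalibrationModel-class].
#' @param thresholds an [HsvThresholds-class].
#' @param radii candidate Hough radii in pixels (default 105--145, matching
#'   the synthetic study's frame sizes; set from the expected frame size in
#'   real images).
#' @param medianSize,shrinkMargin,exgFraction,alphaDrop,priors see
#'   [StudyConfig-class].
#' @param cdaFeatures features for the discriminant analyses (default: the
#'   system's own measurements, ultrasonic height and weed coverage).
#' @param regressionPredictors candidate predictors of ultrasonic height.
#' @param seed integer seed.
#' @return A [StudyConfig-class].
#' @export
studyConfig <- function(sensor = sensorConfig(),
                        calibration = defaultCalibration(),
                        thresholds = hsvThresholds(),
                        radii = 105L:145L, medianSize = 10L,
                        shrinkMargin = 10L, exgFraction = 0.08,
                        alphaDrop = 0.10, priors = "equal",
                        cdaFeatures = c("ultrasonic_height", "weed_coverage"),
                        regressionPredictors = c(
                          "weed_coverage", "grass_height", "bl_height",
                          "crop_height", "grass_density", "bl_density",
                          "crop_density", "grass_biomass", "bl_biomass",
                          "crop_biomass"),
                        seed = 1L) {
  new("StudyConfig", sensor = sensor, calibration = calibration,
      thresholds = thresholds, radii = as.integer(radii),
      medianSize = as.integer(medianSize),
      shrinkMargin = as.integer(shrinkMargin), exgFraction = exgFraction,
      alphaDrop = alphaDrop, priors = priors, cdaFeatures = cdaFeatures,
      regressionPredictors = regressionPredictors, seed = as.integer(seed))
}

#' Process one sampling point: paired images plus a trace segment
#'
#' Runs the full imaging chain (frame segmentation, median filter, circular
#' Hough, ROI shrink, ExG, coverage) on the before-weeding and after-weeding
#' images and the sensor chain on the trace segment. Weed coverage is the
#' before-minus-after coverage difference, floored at 0 (registration or
#' segmentation noise can make the after-image coverage marginally larger).
#'
#' @param before,after RGB arrays or paths to the paired images.
#' @param trace trace segment data.frame (\code{t_seconds}, \code{volts}) or
#'   \code{NULL} if no trace is available.
#' @param config a [StudyConfig-class].
#' @return list with \code{ultrasonicHeight} (cm, \code{NA} if no valid
#'   readings), \code{heightValid}, \code{nInvalidReadings},
#'   \code{coverageBefore}, \code{coverageAfter}, \code{weedCoverage},
#'   \code{roiBefore}, \code{roiAfter} (shrunken [ROICircle-class]s).
#' @export
processSample <- function(before, after, trace = NULL,
                          config = studyConfig()) {
  stopifnot(is(config, "StudyConfig"))
  run <- function(img) measureCoverage(img, radii = config@radii,
                                       thr = config@thresholds,
                                       medianSize = config@medianSize,
                                       shrinkMargin = config@shrinkMargin,
                                       exgFraction = config@exgFraction)
  rb <- run(before)
  ra <- run(after)
  height <- NA_real_; valid <- FALSE; ninv <- NA_integer_
  if (!is.null(trace)) {
    s <- tryCatch(summarizeSample(trace, config@calibration, config@sensor),
                  error = function(e) NULL)
    if (!is.null(s)) {
      height <- s$meanHeight; valid <- TRUE; ninv <- s$nInvalid
    }
  }
  cb <- coverageFraction(rb$coverage)
  ca <- coverageFraction(ra$coverage)
  list(ultrasonicHeight = height, heightValid = valid,
       nInvalidReadings = ninv,
       coverageBefore = cb, coverageAfter = ca,
       weedCoverage = max(0, cb - ca),
       roiBefore = rb$roi, roiAfter = ra$roi)
}

.studySeed <- function(seed, i) (as.double(seed) * 7919 + i) %% 2147483647

#' Build a complete synthetic study directory
#'
#' Generates a field table, paired before/after plot images (before = crop
#' plus weed coverage, after = crop only) and per-sample voltage traces, all
#' with ground truth sidecars, laid out the way [runStudy()] expects:
#' \code{field_table.csv}, \code{before_NNN.png}, \code{after_NNN.png},
#' \code{trace_NNN.csv}, \code{truth_NNN.json}.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [fieldSimConfig()]; its seed drives all randomness.
#' @param imageSize image dimensions (default \code{c(360, 360)}).
#' @param radiusChoices candidate frame radii in pixels (default 115--135).
#' @param centerJitter maximal centre offset from the image centre (px).
#' @param cropCoverage \code{c(mean, sd)} of the crop coverage fraction.
#' @param traceLength readings per sample trace (default 20 at 0.1 s).
#' @param traceNoiseSd voltage noise sd of the traces (default 0.02 V).
#' @param sensor,calibration sensor configuration and calibration used to
#'   synthesize the traces.
#' @return Invisibly, the field table with the per-sample truth columns
#'   \code{coverage_before_true} and \code{coverage_after_true}.
#' @export
simulateStudy <- function(dir, cfg = fieldSimConfig(nPerGroup = 5L),
                          imageSize = c(360L, 360L),
                          radiusChoices = 115:135, centerJitter = 12,
                          cropCoverage = c(0.20, 0.05), traceLength = 20L,
                          traceNoiseSd = 0.02, sensor = sensorConfig(),
                          calibration = defaultCalibration()) {
  stopifnot(inherits(cfg, "FieldSimConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- genFieldTable(cfg)
  n <- nrow(tab)
  h <- imageSize[1]; w <- imageSize[2]
  cb <- numeric(n); ca <- numeric(n)
  withSeed(cfg$seed + 104729, {
    crop <- .rtrunc(n, cropCoverage[1], cropCoverage[2], 0.02, 0.6)
    rads <- sample(radiusChoices, n, replace = TRUE)
    jit <- -centerJitter:centerJitter   # frame placed on the pixel grid
    jx <- sample(jit, n, replace = TRUE)
    jy <- sample(jit, n, replace = TRUE)
    for (i in seq_len(n)) {
      id <- tab$sample_id[i]
      center <- c(floor((w - 1) / 2) + jx[i], floor((h - 1) / 2) + jy[i])
      cb[i] <- min(0.92, crop[i] + tab$weed_coverage[i])
      ca[i] <- crop[i]
      tb <- plotImageTruth(center, rads[i], trueCoverage = cb[i],
                           seed = .studySeed(cfg$seed, 2L * i))
      ta <- plotImageTruth(center, rads[i], trueCoverage = ca[i],
                           seed = .studySeed(cfg$seed, 2L * i + 1L))
      gb <- genPlotImage(tb, imageSize)
      ga <- genPlotImage(ta, imageSize)
      writePlotImage(gb$image, file.path(dir, sprintf("before_%03d.png", id)))
      writePlotImage(ga$image, file.path(dir, sprintf("after_%03d.png", id)))
      writeTruthJson(gb$truth, file.path(dir, sprintf("truth_%03d.json", id)))
      dist <- sensor@referenceDistance - tab$ultrasonic_height[i]
      tr <- genVoltageTrace(rep(dist, traceLength), noiseSd = traceNoiseSd,
                            seed = .studySeed(cfg$seed, 3L * i + 2L),
                            calib = calibration, cfg = sensor)
      writeTrace(tr, file.path(dir, sprintf("trace_%03d.csv", id)))
    }
  })
  out <- tab
  out$coverage_before_true <- cb
  out$coverage_after_true <- ca
  writeFieldTable(out, file.path(dir, "field_table.csv"))
  invisible(out)
}

.skip <- function(stage, reason) data.frame(stage = stage, reason = reason)

#' Run the whole-study analysis
#'
#' Processes every sample of a study directory (paired images plus trace),
#' merges the measured ultrasonic heights and weed coverages with the field
#' table, and emits the study statistics: a correlation table of every
#' covariate against ultrasonic height, the multiple-regression report with
#' backward elimination, and binary plus four-group canonical discriminant
#' confusion matrices. Per-sample failures never abort the run; each skipped
#' sample or analysis is recorded with a machine-readable reason code.
#'
#' @param studyDir directory as produced by [simulateStudy()] (or laid out
#'   the same way for real data).
#' @param config a [StudyConfig-class].
#' @param outDir where to write the report files (default
#'   \code{file.path(studyDir, "results")}).
#' @return list with \code{samples} (per-sample results data.frame),
#'   \code{correlations}, \code{regression} (a [RegressionResult-class] or
#'   \code{NULL}), \code{cdaBinary}, \code{cdaFourGroup} (each a list with
#'   \code{model} and \code{confusion}) and \code{skips}.
#' @export
runStudy <- function(studyDir, config = studyConfig(),
                     outDir = file.path(studyDir, "results")) {
  stopifnot(dir.exists(studyDir), is(config, "StudyConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tab <- readFieldTable(file.path(studyDir, "field_table.csv"))
  skips <- list()
  res <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    id <- tab$sample_id[i]
    bf <- file.path(studyDir, sprintf("before_%03d.png", id))
    af <- file.path(studyDir, sprintf("after_%03d.png", id))
    tf <- file.path(studyDir, sprintf("trace_%03d.csv", id))
    if (!file.exists(bf) || !file.exists(af)) {
      skips[[length(skips) + 1L]] <- .skip(sprintf("sample_%03d", id),
                                           "missing_image")
      next
    }
    trace <- if (file.exists(tf)) readTrace(tf) else NULL
    ps <- tryCatch(processSample(bf, af, trace, config),
                   error = function(e) NULL)
    if (is.null(ps)) {
      skips[[length(skips) + 1L]] <- .skip(sprintf("sample_%03d", id),
                                           "roi_not_found")
      next
    }
    if (!ps$heightValid)
      skips[[length(skips) + 1L]] <- .skip(sprintf("sample_%03d", id),
                                           "no_valid_height_readings")
    res[[i]] <- data.frame(
      sample_id = id,
      ultrasonic_height = ps$ultrasonicHeight,
      height_valid = ps$heightValid,
      coverage_before = ps$coverageBefore,
      coverage_after = ps$coverageAfter,
      weed_coverage = ps$weedCoverage,
      roi_x0 = ps$roiBefore@x0, roi_y0 = ps$roiBefore@y0,
      roi_r = ps$roiBefore@r)
  }
  samples <- do.call(rbind, res)
  if (is.null(samples) || nrow(samples) == 0L)
    stop("no sample could be processed; check the study directory")
  covars <- setdiff(names(tab),
                    c("sample_id", "ultrasonic_height", "weed_coverage",
                      "infestation", "weed_presence",
                      "coverage_before_true", "coverage_after_true"))
  analysis <- merge(samples[samples$height_valid, ],
                    tab[, c("sample_id", "infestation", "weed_presence",
                            covars)],
                    by = "sample_id")
  utils::write.csv(samples, file.path(outDir, "sample_results.csv"),
                   row.names = FALSE)

  # correlations of every covariate (and measured coverage) vs height
  corvars <- c("weed_coverage", covars)
  correlations <- do.call(rbind, lapply(corvars, function(v) {
    ct <- tryCatch(pearsonCor(analysis[[v]], analysis$ultrasonic_height),
                   error = function(e) list(r = NA_real_,
                                            rSquared = NA_real_))
    data.frame(variable = v, r = ct$r, r_squared = ct$rSquared)
  }))
  utils::write.csv(correlations, file.path(outDir, "correlations.csv"),
                   row.names = FALSE)

  # multiple regression with backward elimination
  regression <- NULL
  preds <- intersect(config@regressionPredictors, names(analysis))
  if (nrow(analysis) > length(preds) + 1L) {
    regression <- tryCatch(
      multipleRegression(analysis, "ultrasonic_height", preds,
                         alphaDrop = config@alphaDrop),
      error = function(e) NULL)
    if (is.null(regression))
      skips[[length(skips) + 1L]] <- .skip("regression", "singular_fit")
  } else {
    skips[[length(skips) + 1L]] <- .skip("regression",
                                         "insufficient_valid_samples")
  }
  if (!is.null(regression)) {
    utils::write.csv(coefficientTable(regression),
                     file.path(outDir, "regression_coefficients.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(excluded = excludedPredictors(regression),
           r_squared = rSquared(regression),
           adj_r_squared = adjRSquared(regression)),
      file.path(outDir, "regression_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }

  runCda <- function(label, tag) {
    g <- droplevels(factor(analysis[[label]]))
    if (nlevels(g) < 2L || any(table(g) < 2L) || nrow(analysis) < 3L) {
      skips[[length(skips) + 1L]] <<- .skip(paste0("cda_", tag),
                                            "insufficient_groups")
      return(NULL)
    }
    mod <- tryCatch(cdaFit(analysis, label, config@cdaFeatures,
                           priors = config@priors),
                    error = function(e) NULL)
    if (is.null(mod)) {
      skips[[length(skips) + 1L]] <<- .skip(paste0("cda_", tag),
                                            "singular_within_scatter")
      return(NULL)
    }
    pred <- cdaClassify(mod, analysis)
    cm <- confusionPercentages(analysis[[label]], pred)
    utils::write.csv(as.data.frame.matrix(confusionPercent(cm)),
                     file.path(outDir, sprintf("confusion_%s.csv", tag)))
    list(model = mod, confusion = cm)
  }
  cdaBinary <- runCda("weed_presence", "binary")
  cdaFour <- runCda("infestation", "four_group")

  skipdf <- if (length(skips)) do.call(rbind, skips)
            else data.frame(stage = character(0), reason = character(0))
  utils::write.csv(skipdf, file.path(outDir, "skips.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_samples = nrow(samples),
         n_analysed = nrow(analysis),
         binary_accuracy = if (!is.null(cdaBinary))
           classificationAccuracy(cdaBinary$confusion) else NULL,
         four_group_accuracy = if (!is.null(cdaFour))
           classificationAccuracy(cdaFour$confusion) else NULL),
    file.path(outDir, "study_report.json"), auto_unbox = TRUE, digits = NA)
  list(samples = samples, analysis = analysis, correlations = correlations,
       regression = regression, cdaBinary = cdaBinary,
       cdaFourGroup = cdaFour, skips = skipdf)
}
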