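# Synthetic plot images with known ground truth. Colour choices are
# constrained by the segmentation rules, not by realism:
#  - frame: desaturated blue-grey with R = G < B, whose 8-bit hue is exactly
#    170 and saturation <= 77, comfortably inside the frame HSV thresholds
#    (a pure grey has an unstable hue and would not segment reliably);
#  - soil: brown texture with R > B and 2G - R - B <= 16, always below the
#    ExG plant threshold and with hue < 116;
#  - plants: saturated green with ExG >= 120 and hue <= 102, always above
#    the ExG threshold and never inside the frame hue interval.

withSeed <- function(seed, code) {
  glob <- globalenv()
  if (exists(".Random.seed", envir = glob, inherits = FALSE)) {
    old <- get(".Random.seed", envir = glob)
    on.exit(assign(".Random.seed", old, envir = glob))
  } else {
    on.exit(if (exists(".Random.seed", envir = glob, inherits = FALSE))
      rm(".Random.seed", envir = glob))
  }
  set.seed(seed)
  force(code)
}

#' Ground truth for a synthetic plot image
#'
#' @param center 0-based pixel coordinates \code{c(x0, y0)} of the circular
#'   frame (x = column, y = row).
#' @param radius centreline radius of the ring, in pixels: the circle the
#'   Hough detection is expected to recover.
#' @param frameWidth radial width of the visible ring in pixels (default 12;
#'   the ring spans \code{(radius - frameWidth/2, radius + frameWidth/2]}).
#' @param segmentWidth radial width of the ring's bright central band
#'   (default 6). Only this band falls inside the frame HSV thresholds; the
#'   ring's borders are painted as shaded (value below the V threshold), the
#'   way a plastic frame photographed outdoors segments only partially.
#' @param trueCoverage target plant-pixel fraction of the ROI interior, in
#'   \code{[0, 1]}.
#' @param roiMargin shrink margin defining the ROI interior
#'   (\code{radius - roiMargin}; default 10, matching [shrinkRoi()]).
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return A list of class \code{PlotImageTruth}.
#' @export
plotImageTruth <- function(center, radius, frameWidth = 12,
                           segmentWidth = 6, trueCoverage = 0.3,
                           roiMargin = 10, seed = 1L) {
  stopifnot(length(center) == 2L, radius > frameWidth,
            segmentWidth >= 1, segmentWidth <= frameWidth,
            trueCoverage >= 0, trueCoverage <= 1,
            radius > roiMargin, frameWidth >= 1)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 frameWidth = as.numeric(frameWidth),
                 segmentWidth = as.numeric(segmentWidth),
                 trueCoverage = as.numeric(trueCoverage),
                 roiMargin = as.numeric(roiMargin), seed = as.integer(seed)),
            class = "PlotImageTruth")
}

# pixel-centre distance matrix from a 0-based centre
.distMatrix <- function(dim, x0, y0) {
  y <- (seq_len(dim[1]) - 1) - y0
  x <- (seq_len(dim[2]) - 1) - x0
  sqrt(outer(y^2, x^2, `+`))
}

.paintChannel <- function(img, ch, idx, values) {
  plane <- img[, , ch]
  plane[idx] <- values
  img[, , ch] <- plane
  img
}

#' Generate a synthetic plot image with a grey ring and painted plants
#'
#' Renders a textured soil background, a blue-grey ring centred on the truth
#' circle (bright in its central band, shaded towards its borders), and green
#' plant blobs whose pixel fraction inside the true ROI matches the requested
#' coverage exactly (random ellipses are painted until the target is
#' exceeded, then excess pixels are trimmed at random; shortfalls are padded
#' with random single pixels). Blobs are drawn over a disc slightly larger
#' than the true ROI so that a detected ROI a pixel or two off samples a
#' region with the same expected coverage. By construction every bright ring
#' pixel passes the frame HSV thresholds and every plant pixel exceeds the
#' ExG threshold, while soil and ring shadow never do.
#'
#' @param truth a [plotImageTruth()] object.
#' @param size image dimensions \code{c(height, width)} in pixels (default
#'   \code{c(400, 400)}).
#' @return list with \code{image} (an \code{(h, w, 3)} RGB array on 0--255),
#'   \code{truth} (the input truth augmented with \code{nRoiPixels} and the
#'   realized \code{paintedCoverage}), and the ground-truth masks
#'   \code{frameMask} (bright ring band) and \code{plantMask}.
#' @export
genPlotImage <- function(truth, size = c(400L, 400L)) {
  stopifnot(inherits(truth, "PlotImageTruth"), length(size) == 2L)
  h <- size[1]; w <- size[2]
  x0 <- truth$center[1]; y0 <- truth$center[2]; r <- truth$radius
  rOut <- r + truth$frameWidth / 2
  if (x0 - rOut < 0 || y0 - rOut < 0 || x0 + rOut > w - 1 ||
      y0 + rOut > h - 1)
    stop("circle (centre ", x0, ",", y0, ", outer radius ", rOut,
         ") does not fit inside a ", h, "x", w, " image")
  withSeed(truth$seed, {
    img <- array(0, dim = c(h, w, 3L))
    n <- h * w
    # soil: B <= G <= R keeps the hue in the red-yellow range (< 116);
    # G <= (R+B)/2 + 8 keeps ExG <= 16, below the plant threshold
    R <- sample(110:160, n, replace = TRUE)
    B <- sample(40:90, n, replace = TRUE)
    Ghi <- (R + B) %/% 2L + 8L
    G <- B + floor(stats::runif(n) * (Ghi - B + 1))
    img[, , 1] <- R; img[, , 2] <- G; img[, , 3] <- B

    dist <- .distMatrix(c(h, w), x0, y0)
    ring <- dist > r - truth$frameWidth / 2 & dist <= r + truth$frameWidth / 2
    bright <- ring & dist > r - truth$segmentWidth / 2 &
      dist <= r + truth$segmentWidth / 2
    shadow <- ring & !bright
    nb <- sum(bright)
    rg <- sample(105:125, nb, replace = TRUE)    # R = G: hue exactly 170
    bb <- rg + sample(25:45, nb, replace = TRUE)
    img <- .paintChannel(img, 1L, which(bright), rg)
    img <- .paintChannel(img, 2L, which(bright), rg)
    img <- .paintChannel(img, 3L, which(bright), bb)
    ns <- sum(shadow)
    rgs <- sample(8:16, ns, replace = TRUE)      # shaded border: V < 31
    bbs <- rgs + sample(6:9, ns, replace = TRUE)
    img <- .paintChannel(img, 1L, which(shadow), rgs)
    img <- .paintChannel(img, 2L, which(shadow), rgs)
    img <- .paintChannel(img, 3L, which(shadow), bbs)

    roi <- dist <= r - truth$roiMargin
    paintable <- dist <= min(r - truth$roiMargin + 3,
                             r - truth$frameWidth / 2 - 1)
    nroi <- sum(roi)
    target <- round(truth$trueCoverage * nroi)
    plant <- matrix(FALSE, h, w)
    if (target >= nroi) {
      plant[roi] <- TRUE
    } else if (target > 0) {
      paintR <- min(r - truth$roiMargin + 3, r - truth$frameWidth / 2 - 1)
      iter <- 0L
      while (sum(plant & roi) < target && iter < 5000L) {
        iter <- iter + 1L
        theta <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * paintR
        cx <- x0 + rad * cos(theta); cy <- y0 + rad * sin(theta)
        a <- stats::runif(1, 3, 9); b <- stats::runif(1, 3, 9)
        ang <- stats::runif(1, 0, pi)
        xs <- max(0, floor(cx - max(a, b))):min(w - 1, ceiling(cx + max(a, b)))
        ys <- max(0, floor(cy - max(a, b))):min(h - 1, ceiling(cy + max(a, b)))
        dx <- outer(rep(1, length(ys)), xs - cx)
        dy <- outer(ys - cy, rep(1, length(xs)))
        u <- (dx * cos(ang) + dy * sin(ang)) / a
        v <- (-dx * sin(ang) + dy * cos(ang)) / b
        hit <- u^2 + v^2 <= 1
        sub <- plant[ys + 1, xs + 1, drop = FALSE]
        plant[ys + 1, xs + 1] <- sub | hit
        plant <- plant & paintable
        # overshoot is trimmed below; stop as soon as the target is reached
      }
      painted <- which(plant & roi)
      excess <- length(painted) - target
      if (excess > 0) {
        plant[painted[sample.int(length(painted), excess)]] <- FALSE
      } else if (excess < 0) {
        bare <- which(roi & !plant)
        plant[bare[sample.int(length(bare), -excess)]] <- TRUE
      }
    }
    idx <- which(plant)
    if (length(idx)) {
      img <- .paintChannel(img, 1L, idx,
                           sample(40:80, length(idx), replace = TRUE))
      img <- .paintChannel(img, 2L, idx,
                           sample(140:200, length(idx), replace = TRUE))
      img <- .paintChannel(img, 3L, idx,
                           sample(40:80, length(idx), replace = TRUE))
    }
    truth$nRoiPixels <- nroi
    truth$paintedCoverage <- sum(plant & roi) / nroi
    list(image = img, truth = truth, frameMask = bright, plantMask = plant)
  })
}

#' Write / read the ground-truth sidecar of a synthetic image
#'
#' @param truth a [plotImageTruth()] object (possibly augmented by
#'   [genPlotImage()]).
#' @param path JSON file path.
#' @export
writeTruthJson <- function(truth, path) {
  stopifnot(inherits(truth, "PlotImageTruth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "PlotImageTruth")
}

#' Generate a synthetic ultrasonic voltage trace
#'
#' Inverts the calibration to produce the voltage corresponding to each true
#' distance, adds Gaussian noise, and replaces distances outside the sensing
#' window by the device's error sentinel (its full-scale voltage output).
#'
#' @param trueDistance numeric vector of true distances in cm.
#' @param noiseSd Gaussian noise standard deviation on the voltage, in volts
#'   (default 0).
#' @param seed integer seed (default \code{NULL}: use the current RNG state).
#' @param calib a [CalibrationModel-class].
#' @param cfg a [SensorConfig-class].
#' @param dt sampling interval in seconds (default 0.1).
#' @return data.frame with columns \code{t_seconds} and \code{volts}.
#' @export
genVoltageTrace <- function(trueDistance, noiseSd = 0, seed = NULL,
                            calib = defaultCalibration(), cfg = sensorConfig(),
                            dt = 0.1) {
  if (!is.numeric(trueDistance) || any(!is.finite(trueDistance)))
    stop("true distances must be finite numbers")
  stopifnot(noiseSd >= 0)
  gen <- function() {
    v <- distanceToVoltage(trueDistance, calib)
    if (noiseSd > 0) v <- v + stats::rnorm(length(v), 0, noiseSd)
    v <- pmin(pmax(v, 0), cfg@fullScale)
    # in-window readings must not collide with the sentinel flag
    v[v == cfg@errorSentinel] <- cfg@errorSentinel - 1e-9
    dmm <- trueDistance * 10
    v[dmm < cfg@rangeMin | dmm > cfg@rangeMax] <- cfg@errorSentinel
    data.frame(t_seconds = (seq_along(v) - 1) * dt, volts = v)
  }
  if (is.null(seed)) gen() else withSeed(seed, gen())
}
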