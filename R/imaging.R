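#' @useDynLib ultraweed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Image convention: numeric array dim (height, width, 3), channel order RGB,
# values on the 8-bit 0--255 scale. Masks are logical matrices (TRUE =
# object). Coordinates are 0-based with x = column, y = row; circle
# membership tests use pixel centres.

#' Construct HSV thresholds
#'
#' @param h,s,v inclusive \code{[lo, hi]} intervals on the 0--255 scale.
#'   Defaults are the frame-segmentation thresholds H [116, 255], S [0, 128],
#'   V [31, 255].
#' @return An [HsvThresholds-class].
#' @export
hsvThresholds <- function(h = c(116, 255), s = c(0, 128), v = c(31, 255)) {
  new("HsvThresholds", h = as.numeric(h), s = as.numeric(s), v = as.numeric(v))
}

#' Convert an RGB image to 8-bit HSV
#'
#' Standard hue/saturation/value transform with every channel rescaled to the
#' \code{[0, 255]} range (hue 360 degrees maps to 255). Achromatic pixels get
#' hue 0.
#'
#' @param img numeric array \code{(h, w, 3)} with 8-bit RGB values.
#' @return Array \code{(h, w, 3)} with H, S, V channels on \code{[0, 255]}.
#' @examples
#' px <- array(c(0, 0, 255), dim = c(1, 1, 3))
#' rgbToHsv8(px)[1, 1, ]  # H = 170
#' @export
rgbToHsv8 <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected a (height, width, 3) RGB array")
  d <- dim(img)
  m <- matrix(img, ncol = 3L)  # pixels x RGB, column-major within channel
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 255)
  out <- array(0, dim = d)
  out[, , 1] <- round(hsv["h", ] * 255)
  out[, , 2] <- round(hsv["s", ] * 255)
  out[, , 3] <- round(hsv["v", ] * 255)
  out
}

#' Segment the grey frame by HSV thresholding
#'
#' Thresholds each HSV channel with its inclusive interval and combines the
#' three binary images with a logical AND: a pixel is object iff all three
#' channel values fall inside their intervals. (Displays conventionally mark
#' object pixels black / value 0; the in-memory convention here is
#' \code{TRUE} = object.)
#'
#' @param hsv array \code{(h, w, 3)} from [rgbToHsv8()].
#' @param thr an [HsvThresholds-class].
#' @return Logical matrix, \code{TRUE} = frame pixel.
#' @export
segmentFrame <- function(hsv, thr = hsvThresholds()) {
  if (length(dim(hsv)) != 3L || dim(hsv)[3] != 3L)
    stop("expected a (height, width, 3) HSV array")
  stopifnot(is(thr, "HsvThresholds"))
  inside <- function(ch, iv) ch >= iv[1] & ch <= iv[2]
  matrix(inside(hsv[, , 1], thr@h) & inside(hsv[, , 2], thr@s) &
           inside(hsv[, , 3], thr@v), dim(hsv)[1], dim(hsv)[2])
}

#' Binary median (majority) filter
#'
#' The median of a binary window is a majority vote: the output pixel is
#' object iff more than half of the \code{size x size} window pixels are
#' object. Ties (exactly half, possible for even window sizes) resolve to
#' background; pixels outside the image count as background. For even
#' \code{size} the window spans offsets \code{-(size-1)\%/\%2 .. size\%/\%2}.
#' A size-10 filter removes small noise regions while preserving a frame
#' appearing as a linear structure of 10--20 pixel width.
#'
#' @param mask logical matrix.
#' @param size window edge length in pixels (default 10).
#' @return Filtered logical matrix of the same dimensions.
#' @export
medianMajority <- function(mask, size = 10L) {
  stopifnot(is.matrix(mask), is.logical(mask), size >= 1)
  size <- as.integer(size)
  nr <- nrow(mask); nc <- ncol(mask)
  lo <- -((size - 1L) %/% 2L)
  hi <- size %/% 2L
  # summed-area table, padded with a zero row/column
  P <- matrix(0, nr + 1L, nc + 1L)
  P[-1L, -1L] <- apply(apply(mask + 0, 2L, cumsum), 1L, cumsum) |> t()
  ra <- pmax(1L, seq_len(nr) + lo); rb <- pmin(nr, seq_len(nr) + hi)
  ca <- pmax(1L, seq_len(nc) + lo); cb <- pmin(nc, seq_len(nc) + hi)
  counts <- P[rb + 1L, cb + 1L, drop = FALSE] - P[ra, cb + 1L, drop = FALSE] -
    P[rb + 1L, ca, drop = FALSE] + P[ra, ca, drop = FALSE]
  counts * 2 > size * size
}

#' Detect a circle with the circular Hough transform
#'
#' For every candidate radius, each object pixel votes for all grid positions
#' at that (rounded) distance from it, on an accumulator grid of the same
#' size as the image; the circle centre is the accumulator cell with the
#' maximum count, i.e. the position supported by most object pixels. The
#' estimate is robust to noise and to missing parts of the ring. Ties are
#' broken towards the smallest radius, then row-major pixel order.
#'
#' @param mask logical matrix with at least one object (\code{TRUE}) pixel.
#' @param radii candidate radii in pixels (integer vector or range).
#' @return An [ROICircle-class] with 0-based centre coordinates, the winning
#'   radius, and the accumulator support score.
#' @details A pixel at Euclidean distance \code{d} from a grid position
#'   supports radius \code{r} iff \code{d} rounds to \code{r}
#'   (\code{d} in \code{[r - 0.5, r + 0.5)}), evaluated in exact integer
#'   arithmetic.
#' @export
houghCircle <- function(mask, radii) {
  stopifnot(is.matrix(mask), is.logical(mask))
  radii <- as.integer(radii)
  if (length(radii) == 0L || any(is.na(radii)) || any(radii < 1L))
    stop("radii must be a non-empty set of positive integers")
  if (!any(mask)) stop("mask contains no object pixels")
  res <- cpp_hough_circle(mask, radii)
  new("ROICircle", x0 = as.numeric(res$x0), y0 = as.numeric(res$y0),
      r = as.numeric(res$r), score = as.numeric(res$score))
}

#' Shrink an ROI circle by a margin
#'
#' Reduces the detected radius (by default 10 pixels) so that no part of the
#' frame itself remains inside the region of interest.
#'
#' @param c an [ROICircle-class].
#' @param margin pixels to subtract from the radius (default 10).
#' @return An [ROICircle-class] with the same centre and \code{r - margin}.
#' @export
shrinkRoi <- function(c, margin = 10) {
  stopifnot(is(c, "ROICircle"))
  if (c@r <= margin)
    stop("radius (", c@r, ") must exceed the shrink margin (", margin, ")")
  new("ROICircle", x0 = c@x0, y0 = c@y0, r = c@r - margin, score = c@score)
}

#' Logical membership mask of an ROI circle
#'
#' @param c an [ROICircle-class].
#' @param dim image dimensions \code{c(height, width)}.
#' @return Logical matrix: \code{TRUE} where the pixel centre satisfies
#'   \code{(x - x0)^2 + (y - y0)^2 <= r^2}.
#' @export
roiMask <- function(c, dim) {
  stopifnot(is(c, "ROICircle"), length(dim) >= 2L)
  y <- (seq_len(dim[1]) - 1) - c@y0
  x <- (seq_len(dim[2]) - 1) - c@x0
  outer(y^2, x^2, `+`) <= c@r^2
}

#' Mask an image with a circular ROI in the alpha channel
#'
#' Adds an opacity (alpha) channel: pixels inside the circle are opaque
#' (255), pixels outside are transparent (0). RGB values are untouched.
#'
#' @param img numeric array \code{(h, w, 3)}.
#' @param c an [ROICircle-class].
#' @return Array \code{(h, w, 4)}; the fourth channel is the ROI opacity.
#' @export
applyRoi <- function(img, c) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected a (height, width, 3) RGB array")
  m <- roiMask(c, dim(img))
  out <- array(0, dim = c(dim(img)[1:2], 4L))
  out[, , 1:3] <- img
  out[, , 4] <- m * 255
  out
}

#' Excess green index image
#'
#' Computes \code{ExG = 2G - R - B} per pixel in signed arithmetic and clips
#' the result to \code{[0, 255]}; green vegetation appears bright, soil and
#' other backgrounds dark.
#'
#' @param img numeric array \code{(h, w, 3)} with 8-bit RGB values.
#' @return Numeric matrix of clipped ExG values.
#' @export
exgImage <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected a (height, width, 3) RGB array")
  exg <- 2 * img[, , 2] - img[, , 1] - img[, , 3]
  matrix(pmin(pmax(exg, 0), 255), dim(img)[1], dim(img)[2])
}

#' Threshold the ExG image into a plant mask
#'
#' The threshold fraction maps to a grey level by truncation
#' (\code{0.08 -> trunc(255 * 0.08) = 20}); a pixel is plant iff its ExG
#' value strictly exceeds that level.
#'
#' @param exg matrix from [exgImage()].
#' @param fraction threshold as a fraction of the 8-bit range (default 0.08).
#' @return Logical matrix, \code{TRUE} = plant.
#' @export
segmentPlants <- function(exg, fraction = 0.08) {
  stopifnot(is.matrix(exg), fraction > 0, fraction < 1)
  exg > trunc(255 * fraction)
}

#' ExG threshold grey level for a fraction
#'
#' @param fraction threshold fraction in (0, 1).
#' @return Integer grey level \code{trunc(255 * fraction)}.
#' @export
exgThresholdLevel <- function(fraction = 0.08) {
  stopifnot(fraction > 0, fraction < 1)
  trunc(255 * fraction)
}

#' Plant coverage within an ROI
#'
#' Counts plant (\code{pf}) and background (\code{pb}) pixels among the ROI
#' pixels only, and reports the coverage ratio \code{C = pf / (pb + pf)}.
#'
#' @param plant logical plant mask (from [segmentPlants()]).
#' @param roi logical ROI mask of the same dimensions (from [roiMask()] or the
#'   alpha channel of [applyRoi()] interpreted as \code{> 0}).
#' @return A [CoverageResult-class].
#' @export
plantCoverage <- function(plant, roi) {
  stopifnot(is.matrix(plant), is.logical(plant), is.logical(roi),
            all(dim(plant) == dim(roi)))
  n <- sum(roi)
  if (n == 0L) stop("ROI is empty; coverage is undefined")
  pf <- sum(plant & roi)
  new("CoverageResult", pf = pf, pb = n - pf, coverage = pf / n)
}

#' Full frame-to-coverage processing chain for one image
#'
#' Runs HSV conversion, frame thresholding, binary median filtering, circular
#' Hough detection, ROI shrinkage, ExG computation, plant thresholding and
#' coverage measurement.
#'
#' @param img RGB array or path to a PNG/JPEG file.
#' @param radii candidate Hough radii (pixels).
#' @param thr an [HsvThresholds-class].
#' @param medianSize binary median window size (default 10).
#' @param shrinkMargin ROI shrink margin in pixels (default 10).
#' @param exgFraction ExG threshold fraction (default 0.08).
#' @return list with elements \code{frameCircle} (detected [ROICircle-class]),
#'   \code{roi} (shrunken circle), \code{coverage} (a [CoverageResult-class]),
#'   and \code{plantMask}.
#' @export
measureCoverage <- function(img, radii, thr = hsvThresholds(),
                            medianSize = 10L, shrinkMargin = 10,
                            exgFraction = 0.08) {
  if (is.character(img)) img <- readPlotImage(img)
  hsv <- rgbToHsv8(img)
  frame <- medianMajority(segmentFrame(hsv, thr), medianSize)
  circ <- houghCircle(frame, radii)
  roi <- shrinkRoi(circ, shrinkMargin)
  plant <- segmentPlants(exgImage(img), exgFraction)
  list(frameCircle = circ, roi = roi,
       coverage = plantCoverage(plant, roiMask(roi, dim(img))),
       plantMask = plant)
}

#' Read / write plot images
#'
#' Images are stored as PNG (JPEG also readable); in memory they are 8-bit
#' RGB arrays on the 0--255 scale.
#'
#' @param path file path (.png, .jpg/.jpeg).
#' @return \code{readPlotImage} returns a \code{(h, w, 3)} array.
#' @export
readPlotImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (PNG or JPEG expected)"))
  if (length(dim(raw)) == 2L)
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  round(raw[, , 1:3, drop = FALSE] * 255)
}

#' @rdname readPlotImage
#' @param img image array, values 0--255; a fourth (alpha) channel is kept.
#' @export
writePlotImage <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Serialize an ROI circle or coverage result to JSON
#'
#' @param x an [ROICircle-class] or [CoverageResult-class].
#' @param path output file.
#' @export
writeRoiJson <- function(x, path) {
  stopifnot(is(x, "ROICircle"))
  jsonlite::write_json(list(x0 = x@x0, y0 = x@y0, r = x@r, score = x@score),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRoiJson
#' @export
writeCoverageJson <- function(x, path) {
  stopifnot(is(x, "CoverageResult"))
  jsonlite::write_json(list(pf = x@pf, pb = x@pb, coverage = x@coverage),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
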