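test_that("RGB to 8-bit HSV matches closed-form conversions", {
  expect_equal(rgbToHsv8(flatImage(c(1, 1), c(255, 0, 0)))[1, 1, ],
               c(0, 255, 255))
  expect_equal(rgbToHsv8(flatImage(c(1, 1), c(128, 128, 128)))[1, 1, ],
               c(0, 0, 128))
  expect_equal(rgbToHsv8(flatImage(c(1, 1), c(0, 0, 255)))[1, 1, ],
               c(170, 255, 255))  # 240 degrees scaled by 255/360
  expect_error(rgbToHsv8(matrix(0, 2, 2)), "RGB")
})

test_that("frame segmentation is the AND of the three channel thresholds", {
  hsv <- array(0, dim = c(2, 2, 3))
  hsv[1, 1, ] <- c(150, 100, 200)   # inside all intervals
  hsv[1, 2, ] <- c(100, 100, 200)   # hue below 116
  hsv[2, 1, ] <- c(150, 200, 200)   # saturation above 128
  hsv[2, 2, ] <- c(150, 100, 10)    # value below 31
  m <- segmentFrame(hsv)
  expect_identical(m, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  # bit-exact decomposition into per-channel masks
  set.seed(3)
  hsv2 <- array(sample(0:255, 3 * 30 * 30, TRUE), dim = c(30, 30, 3))
  thr <- hsvThresholds()
  per <- (hsv2[, , 1] >= 116 & hsv2[, , 1] <= 255) &
    (hsv2[, , 2] >= 0 & hsv2[, , 2] <= 128) &
    (hsv2[, , 3] >= 31 & hsv2[, , 3] <= 255)
  expect_identical(segmentFrame(hsv2, thr), per)
  # an image with no in-range pixel gives an empty mask
  expect_false(any(segmentFrame(array(0, dim = c(4, 4, 3)))))
})

test_that("binary median majority filters as specified", {
  # uniform object mask: interior unchanged
  m <- matrix(TRUE, 40, 40)
  f <- medianMajority(m, 10)
  expect_true(all(f[15:25, 15:25]))
  # a single isolated object pixel is removed (1 < 50 of 100 votes)
  m2 <- matrix(FALSE, 30, 30)
  m2[15, 15] <- TRUE
  expect_false(any(medianMajority(m2, 10)))
  # a solid 20-pixel band survives away from its ends
  m3 <- matrix(FALSE, 60, 60)
  m3[21:40, ] <- TRUE
  f3 <- medianMajority(m3, 10)
  expect_true(all(f3[25:35, 20:40]))
  expect_false(any(f3[1:10, ]))
  # ties (exactly half) resolve to background: a 5-wide band under a
  # size-10 window peaks at 50 votes
  m4 <- matrix(FALSE, 40, 40)
  m4[18:22, ] <- TRUE
  expect_false(any(medianMajority(m4, 10)[, 15:25]))
})

test_that("hough detection finds full and partial circles", {
  mask <- circleMask(c(280, 280), 120, 140, 80)
  hc <- houghCircle(mask, 80)
  expect_lte(abs(roiCenter(hc)["x0"] - 120), 1)
  expect_lte(abs(roiCenter(hc)["y0"] - 140), 1)
  expect_equal(roiRadius(hc), 80)
  expect_equal(houghScore(hc), sum(mask))  # every object pixel supports it
  # half arc: centre still recovered within 2 px
  idx <- which(mask, arr.ind = TRUE)
  keep <- idx[, 2] - 1 >= 120   # right half
  half <- matrix(FALSE, 280, 280)
  half[idx[keep, , drop = FALSE]] <- TRUE
  hh <- houghCircle(half, 80)
  expect_lte(abs(hh@x0 - 120), 2)
  expect_lte(abs(hh@y0 - 140), 2)
  expect_error(houghCircle(matrix(FALSE, 5, 5), 2), "object")
})

test_that("three points on a circle vote for their common centre", {
  m <- matrix(FALSE, 40, 40)
  # P1, P2, P3 at distance 5 from (20, 20), 0-based (x, y)
  pts <- rbind(c(25, 20), c(20, 25), c(15, 20))
  m[pts[, 2] + 1 + nrow(m) * pts[, 1]] <- TRUE
  expect_equal(sum(m), 3L)
  hc <- houghCircle(m, 5)
  expect_equal(unname(roiCenter(hc)), c(20, 20))
  expect_equal(houghScore(hc), 3)
})

test_that("accumulator equals the brute-force support count", {
  # property over several small masks with <= 200 object pixels
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(FALSE, 50, 50)
    m[sample.int(2500, 150)] <- TRUE
    r <- sample(5:15, 1)
    acc <- ultraweed:::cpp_hough_accumulator(m, r)
    expect_identical(acc, bruteHoughSupport(m, r))
  }
})

test_that("ROI shrink subtracts the margin and rejects degenerate radii", {
  c0 <- new("ROICircle", x0 = 10, y0 = 10, r = 150, score = 10)
  expect_equal(roiRadius(shrinkRoi(c0)), 140)
  expect_equal(roiRadius(shrinkRoi(c0, margin = 0)), 150)
  c1 <- new("ROICircle", x0 = 10, y0 = 10, r = 10, score = 10)
  expect_error(shrinkRoi(c1, 10), "margin")
})

test_that("ROI masking fills the alpha channel with the disc", {
  img <- flatImage(c(50, 50), c(10, 20, 30))
  big <- new("ROICircle", x0 = 25, y0 = 25, r = 100, score = 1)
  rgba <- applyRoi(img, big)
  expect_true(all(rgba[, , 4] == 255))          # ROI covers the whole image
  out <- new("ROICircle", x0 = 500, y0 = 500, r = 10, score = 1)
  expect_true(all(applyRoi(img, out)[, , 4] == 0))
  # disc area close to pi r^2
  disc <- new("ROICircle", x0 = 150, y0 = 150, r = 100, score = 1)
  n <- sum(roiMask(disc, c(301, 301)))
  expect_lt(abs(n - pi * 100^2) / (pi * 100^2), 0.005)
})

test_that("ExG is 2G - R - B clipped to [0, 255]", {
  expect_equal(exgImage(flatImage(c(1, 1), c(0, 255, 0)))[1, 1], 255)
  expect_equal(exgImage(flatImage(c(1, 1), c(128, 128, 128)))[1, 1], 0)
  expect_equal(exgImage(flatImage(c(1, 1), c(255, 0, 0)))[1, 1], 0)
  expect_equal(exgImage(flatImage(c(1, 1), c(10, 50, 20)))[1, 1], 70)
})

test_that("plant threshold truncates the fraction and compares strictly", {
  expect_equal(exgThresholdLevel(0.08), 20)
  exg <- matrix(c(20, 21, 0, 255), 2, 2)
  expect_identical(segmentPlants(exg, 0.08),
                   matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  expect_false(any(segmentPlants(matrix(0, 3, 3))))
})

test_that("coverage counts are restricted to the ROI", {
  roi <- matrix(FALSE, 10, 10); roi[3:8, 3:8] <- TRUE
  plant <- matrix(FALSE, 10, 10)
  plant[3:8, 3:5] <- TRUE       # half of the ROI
  plant[1, 1] <- TRUE           # outside the ROI, must not count
  cov <- plantCoverage(plant, roi)
  expect_equal(plantPixels(cov), 18)
  expect_equal(backgroundPixels(cov), 18)
  expect_equal(coverageFraction(cov), 0.5)
  expect_equal(plantPixels(cov) + backgroundPixels(cov), sum(roi))
  # all-plant ROI
  expect_equal(coverageFraction(plantCoverage(roi, roi)), 1)
  expect_error(plantCoverage(plant, matrix(FALSE, 10, 10)), "empty")
})

test_that("coverage is permutation-invariant and monotone in plant pixels", {
  set.seed(9)
  roi <- matrix(TRUE, 12, 12)
  plant <- matrix(runif(144) < 0.3, 12, 12)
  c1 <- coverageFraction(plantCoverage(plant, roi))
  perm <- matrix(sample(plant), 12, 12)   # permute pixels within the ROI
  expect_equal(coverageFraction(plantCoverage(perm, roi)), c1)
  more <- plant
  more[which(!plant)[1:10]] <- TRUE
  expect_gte(coverageFraction(plantCoverage(more, roi)), c1)
})

test_that("plot images survive a PNG round-trip unchanged", {
  set.seed(5)
  img <- array(sample(0:255, 3 * 20 * 20, TRUE), dim = c(20, 20, 3))
  path <- withr::local_tempfile(fileext = ".png")
  writePlotImage(img, path)
  expect_equal(readPlotImage(path), img)
})
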