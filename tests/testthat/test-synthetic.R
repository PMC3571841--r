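test_that("painted plant coverage matches the requested fraction exactly", {
  for (cov in c(0, 0.3, 1)) {
    t0 <- plotImageTruth(c(200, 200), 150, trueCoverage = cov, seed = 11)
    g <- genPlotImage(t0, c(400, 400))
    expect_lte(abs(g$truth$paintedCoverage - cov), 0.005)
    roi <- roiMask(new("ROICircle", x0 = 200, y0 = 200, r = 140, score = 1),
                   c(400, 400))
    if (cov == 0) expect_false(any(g$plantMask & roi))
    if (cov == 1) expect_true(all(g$plantMask[roi]))
  }
})

test_that("painted colours respect the segmentation rules by construction", {
  t0 <- plotImageTruth(c(180, 220), 140, trueCoverage = 0.3, seed = 7)
  g <- genPlotImage(t0, c(400, 400))
  hsv <- rgbToHsv8(g$image)
  frame <- segmentFrame(hsv)
  # every bright ring pixel passes the frame thresholds
  expect_true(all(frame[g$frameMask]))
  # no plant or soil pixel does
  expect_false(any(frame & !g$frameMask))
  # every plant pixel exceeds the ExG threshold, no soil pixel does
  exg <- exgImage(g$image)
  expect_true(all(exg[g$plantMask] > 20))
  soil <- !g$plantMask & !g$frameMask
  expect_false(any(exg[soil] > 20))
})

test_that("the imaging chain recovers generator ground truth", {
  t0 <- plotImageTruth(c(180, 220), 140, trueCoverage = 0.30, seed = 7)
  g <- genPlotImage(t0, c(420, 420))
  mc <- measureCoverage(g$image, radii = 120:160)
  expect_lte(abs(mc$frameCircle@x0 - 180), 2)
  expect_lte(abs(mc$frameCircle@y0 - 220), 2)
  expect_lte(abs(mc$frameCircle@r - 140), 2)
  expect_lte(abs(coverageFraction(mc$coverage) - 0.30), 0.01)
})

test_that("image generation is deterministic in the seed", {
  t0 <- plotImageTruth(c(150, 150), 100, trueCoverage = 0.2, seed = 3)
  g1 <- genPlotImage(t0, c(320, 320))
  g2 <- genPlotImage(t0, c(320, 320))
  expect_identical(g1$image, g2$image)
  t1 <- t0; t1$seed <- 4L
  expect_false(identical(genPlotImage(t1, c(320, 320))$image, g1$image))
})

test_that("out-of-bounds circles and bad coverages are rejected", {
  expect_error(genPlotImage(plotImageTruth(c(50, 50), 100, trueCoverage = 0.1),
                            c(200, 200)), "fit")
  expect_error(plotImageTruth(c(100, 100), 50, trueCoverage = 1.2))
  expect_error(plotImageTruth(c(100, 100), 50, trueCoverage = -0.1))
})

test_that("voltage traces invert the calibration and flag out-of-window", {
  # the inverse mapping returns 0 V at the intercept distance; as a trace
  # reading that distance (296.58 mm) sits below the 350 mm window and is
  # therefore emitted as the sentinel
  expect_equal(distanceToVoltage(29.658), 0)
  expect_equal(genVoltageTrace(29.658)$volts, 10)
  # noiseless round trip over the sensing window, < 1e-9 cm
  d <- seq(36, 99, by = 0.5)
  tr2 <- genVoltageTrace(d)
  expect_lt(max(abs(voltageToDistance(tr2$volts) - d)), 1e-9)
  # 120 cm is outside the 350-1000 mm window: sentinel, flagged invalid
  tr3 <- genVoltageTrace(120)
  expect_equal(tr3$volts, 10)
  expect_true(is.na(voltageToDistance(tr3$volts)))
  expect_error(genVoltageTrace(Inf), "finite")
  # determinism under seed, difference across seeds
  a <- genVoltageTrace(rep(76, 20), noiseSd = 0.05, seed = 1)
  b <- genVoltageTrace(rep(76, 20), noiseSd = 0.05, seed = 1)
  c <- genVoltageTrace(rep(76, 20), noiseSd = 0.05, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("field tables honour the group structure", {
  tab <- genFieldTable(fieldSimConfig(nPerGroup = 10L, seed = 2L))
  expect_equal(nrow(tab), 40L)
  ni <- tab[tab$infestation == "non-infested", ]
  weedcols <- c("weed_coverage", "grass_height", "bl_height", "grass_density",
                "bl_density", "grass_biomass", "bl_biomass")
  expect_true(all(as.matrix(ni[, weedcols]) == 0))
  gr <- tab[tab$infestation == "grass", ]
  expect_true(all(gr$grass_density > 0))
  expect_true(all(gr$bl_density == 0))
  mx <- tab[tab$infestation == "mixture", ]
  expect_true(all(mx$grass_density > 0 & mx$bl_density > 0))
  # non-negativity of truncated draws
  num <- vapply(tab, is.numeric, logical(1))
  expect_true(all(as.matrix(tab[, num]) >= 0))
  expect_true(all(tab$weed_presence[tab$infestation != "non-infested"] ==
                    "infested"))
})

test_that("field-table moments match the configured world", {
  tab <- genFieldTable(fieldSimConfig(nPerGroup = 20L, seed = 1L))
  # crop height: mean 6.6, sd 0.5, n = 80 -> 3 standard errors
  expect_lt(abs(mean(tab$crop_height) - 6.6), 3 * 0.5 / sqrt(80))
  # ultrasonic height near its configured mean (sd 1.0)
  expect_lt(abs(mean(tab$ultrasonic_height) - 3.7), 3 * 1.0 / sqrt(80))
})

test_that("field tables are reproducible under a fixed seed", {
  cfg <- fieldSimConfig(nPerGroup = 5L, seed = 9L)
  expect_identical(genFieldTable(cfg), genFieldTable(cfg))
  cfg2 <- fieldSimConfig(nPerGroup = 5L, seed = 10L)
  expect_false(identical(genFieldTable(cfg), genFieldTable(cfg2)))
})
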