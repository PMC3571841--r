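test_that("pearson correlation handles exact and sampled relationships", {
  x <- 1:20
  expect_equal(pearsonCor(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCor(x, -x)$r, -1)
  expect_error(pearsonCor(x, rep(3, 20)), "variance")
  set.seed(14)
  z <- matrix(rnorm(1000), ncol = 2)
  x2 <- z[, 1]; y2 <- 0.8 * z[, 1] + sqrt(1 - 0.64) * z[, 2]
  expect_lt(abs(pearsonCor(x2, y2)$r - 0.8), 0.05)
})

test_that("simple regression matches closed forms", {
  x <- c(1, 2, 4, 7, 9)
  # exact line through the origin
  r0 <- simpleRegression(x, 3 * x, throughOrigin = TRUE)
  expect_equal(r0$slope, 3, tolerance = 1e-12)
  expect_equal(r0$rSquared, 1)
  # exact affine data
  ra <- simpleRegression(x, 2 * x + 5)
  expect_equal(ra$slope, 2, tolerance = 1e-12)
  expect_equal(ra$intercept, 5, tolerance = 1e-12)
  # through-origin slope equals sum(xy)/sum(x^2)
  set.seed(8)
  y <- 3 * x + rnorm(5)
  rt <- simpleRegression(x, y, throughOrigin = TRUE)
  expect_equal(rt$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
  # fixed known intercept
  rf <- simpleRegression(x, 2 * x + 5, fixedIntercept = 5)
  expect_equal(rf$slope, 2, tolerance = 1e-12)
  expect_error(simpleRegression(rep(2, 5), y), "distinct")
})

test_that("multiple regression recovers a noiseless model exactly", {
  set.seed(21)
  d <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
  d$y <- 0.3 * d$x1 + 0.4 * d$x2
  rr <- multipleRegression(d, "y", c("x1", "x2"))
  tab <- coefficientTable(rr)
  expect_equal(tab$estimate[tab$term == "x1"], 0.3, tolerance = 1e-9)
  expect_equal(tab$estimate[tab$term == "x2"], 0.4, tolerance = 1e-9)
  expect_length(excludedPredictors(rr), 0)
  expect_equal(adjRSquared(rr), 1, tolerance = 1e-9)
  expect_lte(adjRSquared(rr), rSquared(rr) + 1e-12)
})

test_that("standardized coefficients equal raw times sd(x)/sd(y)", {
  set.seed(22)
  d <- data.frame(x1 = rnorm(80, sd = 3), x2 = runif(80, 0, 10))
  d$y <- 1.5 * d$x1 - 0.2 * d$x2 + rnorm(80)
  rr <- multipleRegression(d, "y", c("x1", "x2"), alphaDrop = NULL)
  tab <- coefficientTable(rr)
  for (v in c("x1", "x2")) {
    raw <- tab$estimate[tab$term == v]
    expect_equal(tab$std_estimate[tab$term == v],
                 raw * sd(d[[v]]) / sd(d$y), tolerance = 1e-12)
  }
})

test_that("backward elimination drops a pure-noise predictor", {
  dropped <- 0L
  for (s in 1:100) {
    set.seed(300 + s)
    d <- data.frame(x1 = rnorm(300), x2 = rnorm(300), x3 = rnorm(300))
    d$y <- 0.5 * d$x1 + 0.3 * d$x2 + rnorm(300)
    rr <- multipleRegression(d, "y", c("x1", "x2", "x3"), alphaDrop = 0.10)
    if ("x3" %in% excludedPredictors(rr)) dropped <- dropped + 1L
  }
  expect_gte(dropped, 90L)
})

test_that("regression residuals are orthogonal to retained predictors", {
  set.seed(23)
  d <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
  d$y <- d$x1 - d$x2 + rnorm(60)
  rr <- multipleRegression(d, "y", c("x1", "x2"), alphaDrop = NULL)
  tab <- coefficientTable(rr)
  fitted <- tab$estimate[1] + as.matrix(d[, c("x1", "x2")]) %*%
    tab$estimate[-1]
  res <- d$y - drop(fitted)
  expect_lt(abs(sum(res * d$x1)), 1e-8)
  expect_lt(abs(sum(res * d$x2)), 1e-8)
})

test_that("collinear designs are rejected with the offending predictor", {
  d <- data.frame(x1 = rnorm(30))
  d$x2 <- 2 * d$x1
  d$y <- d$x1 + rnorm(30)
  expect_error(multipleRegression(d, "y", c("x1", "x2")), "x2")
})

test_that("two-group CDA matches the Fisher closed form", {
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 40
    d <- data.frame(
      f1 = c(rnorm(n), rnorm(n, 2)),
      f2 = c(rnorm(n, sd = 2), rnorm(n, 1, sd = 2)),
      f3 = c(rnorm(n), rnorm(n, -1)),
      g = rep(c("a", "b"), each = n))
    mod <- cdaFit(d, "g", c("f1", "f2", "f3"))
    # independent oracle: Sw^-1 (m1 - m2)
    X <- as.matrix(d[, 1:3])
    m1 <- colMeans(X[d$g == "a", ]); m2 <- colMeans(X[d$g == "b", ])
    Sw <- crossprod(sweep(X[d$g == "a", ], 2, m1)) +
      crossprod(sweep(X[d$g == "b", ], 2, m2))
    fisher <- solve(Sw, m1 - m2)
    a <- canonicalCoefficients(mod)[, 1]
    expect_equal(a / sqrt(sum(a^2)),
                 sign(sum(fisher * a)) * fisher / sqrt(sum(fisher^2)),
                 tolerance = 1e-8)
  }
})

test_that("CDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(77)
  d <- data.frame(f1 = rnorm(90), f2 = rnorm(90), f3 = rnorm(90),
                  g = rep(c("a", "b", "c"), each = 30))
  d$f1 <- d$f1 + rep(c(0, 1.5, 3), each = 30)
  d$f2 <- d$f2 + rep(c(0, 1, -1), each = 30)
  mod <- cdaFit(d, "g", c("f1", "f2", "f3"))
  ld <- MASS::lda(g ~ f1 + f2 + f3, data = d)
  A <- canonicalCoefficients(mod)
  for (j in 1:2) {
    a <- A[, j] / sqrt(sum(A[, j]^2))
    b <- ld$scaling[, j] / sqrt(sum(ld$scaling[, j]^2))
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-6)
  }
  # identical predictions on the training data
  expect_equal(as.character(cdaClassify(mod, d)),
               as.character(predict(ld)$class))
})

test_that("CDA degenerate cases behave as specified", {
  set.seed(31)
  # identical group means: no separation, eigenvalues ~ 0
  d <- data.frame(f1 = rnorm(60), f2 = rnorm(60),
                  g = rep(c("a", "b"), each = 30))
  mod <- cdaFit(d, "g", c("f1", "f2"))
  expect_lt(max(canonicalEigenvalues(mod)), 0.2)
  # 4 groups in 2 features: at most 2 axes
  d4 <- data.frame(f1 = rnorm(80), f2 = rnorm(80),
                   g = rep(letters[1:4], each = 20))
  d4$f1 <- d4$f1 + rep(1:4, each = 20)
  expect_lte(ncol(canonicalCoefficients(cdaFit(d4, "g", c("f1", "f2")))), 2)
  # singular within-group scatter
  ds <- data.frame(f1 = rnorm(20), g = rep(c("a", "b"), each = 10))
  ds$f2 <- ds$f1
  expect_error(cdaFit(ds, "g", c("f1", "f2")), "singular")
  expect_error(cdaFit(d[1:30, ], "g", c("f1", "f2")), "2 groups")
})

test_that("canonical projections are invariant to affine feature rescaling", {
  set.seed(32)
  d <- data.frame(f1 = rnorm(60), f2 = runif(60),
                  g = rep(c("a", "b", "c"), each = 20))
  d$f1 <- d$f1 + rep(c(0, 2, 4), each = 20)
  m1 <- cdaFit(d, "g", c("f1", "f2"))
  d2 <- d
  d2$f1 <- 100 * d$f1 - 7
  d2$f2 <- 0.01 * d$f2 + 3
  m2 <- cdaFit(d2, "g", c("f1", "f2"))
  expect_equal(canonicalEigenvalues(m1), canonicalEigenvalues(m2),
               tolerance = 1e-8)
  z1 <- sweep(as.matrix(d[, 1:2]), 2, m1@featureMeans) %*%
    canonicalCoefficients(m1)
  z2 <- sweep(as.matrix(d2[, 1:2]), 2, m2@featureMeans) %*%
    canonicalCoefficients(m2)
  for (j in 1:2)
    expect_equal(abs(cor(z1[, j], z2[, j])), 1, tolerance = 1e-8)
})

test_that("classification is by nearest centroid with deterministic ties", {
  set.seed(33)
  d <- data.frame(f1 = c(rnorm(100), rnorm(100, 10)),
                  g = rep(c("a", "b"), each = 100))
  mod <- cdaFit(d, "g", "f1")
  # records at the centroids classify to their group
  cents <- groupCentroids(mod)
  at <- data.frame(f1 = mod@featureMeans[1] +
                     cents[, 1] / canonicalCoefficients(mod)[1, 1])
  expect_equal(as.character(cdaClassify(mod, at)), c("a", "b"))
  # 10-sd separation: perfect resubstitution
  expect_equal(as.character(cdaClassify(mod, d)), as.character(d$g))
  # an exactly equidistant record ties to the first group in label order
  sym <- new("CDAModel", coefficients = matrix(1, 1, 1,
                                               dimnames = list("f1", "CAN1")),
             eigenvalues = 0.5, centroids = matrix(c(-1, 1), 2, 1),
             groupLabels = c("a", "b"), priors = c(a = 0.5, b = 0.5),
             featureMeans = c(f1 = 0))
  expect_equal(as.character(cdaClassify(sym, data.frame(f1 = 0))), "a")
})

test_that("binary CDA accuracy sits in the expected envelope when the Bayes
           accuracy is about 0.93", {
  # two Gaussian groups separated so that Phi(delta/2) = 0.93
  delta <- 2 * qnorm(0.93)
  set.seed(55)
  d <- data.frame(f1 = c(rnorm(100), rnorm(100, delta)),
                  f2 = rnorm(200),   # uninformative second feature
                  g = rep(c("a", "b"), each = 100))
  mod <- cdaFit(d, "g", c("f1", "f2"))
  cm <- confusionPercentages(d$g, cdaClassify(mod, d))
  acc <- classificationAccuracy(cm)
  expect_gte(acc, 0.88)
  expect_lte(acc, 0.98)
})

test_that("confusion matrices are row-normalized percentages", {
  truth <- rep(c("a", "b"), c(14, 10))
  pred <- truth
  pred[14] <- "b"              # 13 of 14 correct in class a
  cm <- confusionPercentages(truth, pred)
  expect_equal(confusionPercent(cm)["a", ], c(a = 92.9, b = 7.1),
               tolerance = 0.05)
  expect_equal(unname(rowSums(confusionPercent(cm))), c(100, 100))
  # perfect prediction: identity pattern
  cmp <- confusionPercentages(truth, truth)
  expect_equal(unname(diag(confusionPercent(cmp))), c(100, 100))
  # everything predicted as one class
  cm1 <- confusionPercentages(truth, rep("a", 24))
  expect_equal(unname(confusionPercent(cm1)[, "a"]), c(100, 100))
  expect_error(confusionPercentages(character(0), character(0)), "empty")
})
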