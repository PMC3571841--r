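#' Pearson correlation between two series
#'
#' @param x,y numeric vectors of equal length; at least 3 finite pairs with
#'   nonzero variance in each.
#' @return list with \code{r} (product-moment correlation) and
#'   \code{rSquared}.
#' @export
pearsonCor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  r <- stats::cor(x, y)
  list(r = r, rSquared = r^2)
}

#' Simple linear regression, optionally with a fixed intercept
#'
#' Ordinary least squares of \code{y} on \code{x}. With
#' \code{throughOrigin = TRUE} the intercept is omitted (regression through
#' the origin); with a numeric \code{fixedIntercept} the line is constrained
#' to pass through \code{(0, fixedIntercept)}. R-squared is reported as
#' \code{stats::lm} defines it (uncentred total sum of squares when the
#' intercept is absent).
#'
#' @param x,y numeric vectors.
#' @param throughOrigin logical; omit the intercept.
#' @param fixedIntercept optional known intercept value.
#' @return list with \code{slope}, \code{intercept} and \code{rSquared}.
#' @export
simpleRegression <- function(x, y, throughOrigin = FALSE,
                             fixedIntercept = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (!is.null(fixedIntercept)) {
    if (all(x == 0)) stop("singular design: all x are zero")
    fit <- stats::lm(I(y - fixedIntercept) ~ 0 + x)
    return(list(slope = unname(stats::coef(fit)[1]),
                intercept = fixedIntercept,
                rSquared = suppressWarnings(summary(fit)$r.squared)))
  }
  if (throughOrigin) {
    if (all(x == 0)) stop("singular design: all x are zero")
    fit <- stats::lm(y ~ 0 + x)
    return(list(slope = unname(stats::coef(fit)[1]), intercept = 0,
                rSquared = suppressWarnings(summary(fit)$r.squared)))
  }
  if (length(unique(x)) < 2L) stop("singular design: need 2 distinct x")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = suppressWarnings(summary(fit)$r.squared))
}

#' Multiple regression with backward elimination
#'
#' Fits an ordinary-least-squares model of the response on the candidate
#' predictors, then repeatedly removes the least significant predictor while
#' its p-value exceeds \code{alphaDrop} (ties broken by removing the first of
#' the equally largest p-values). The final model is reported with raw and
#' standardized coefficients (\code{raw * sd(x) / sd(y)}), standard errors,
#' p-values and (adjusted) R-squared.
#'
#' @param data data.frame of samples.
#' @param response response column name.
#' @param predictors character vector of candidate predictor columns.
#' @param alphaDrop elimination threshold on the p-value (default 0.10;
#'   \code{NULL} or \code{>= 1} disables elimination, keeping all predictors).
#' @return A [RegressionResult-class].
#' @export
multipleRegression <- function(data, response, predictors, alphaDrop = 0.10) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)), length(predictors) >= 1L)
  if (nrow(data) <= length(predictors) + 1L)
    stop("need more samples than predictors + 1")
  form <- function(preds) {
    if (length(preds) == 0L)
      stats::reformulate("1", response = as.name(response))
    else
      stats::reformulate(sprintf("`%s`", preds), response = as.name(response))
  }
  fit <- stats::lm(form(predictors), data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- predictors[is.na(stats::coef(fit))[-1]]
    stop("exactly collinear predictors: ", paste(bad, collapse = ", "))
  }
  keep <- predictors
  doDrop <- !is.null(alphaDrop) && alphaDrop < 1
  repeat {
    fit <- stats::lm(form(keep), data = data)
    if (!doDrop || length(keep) == 0L) break
    ct <- suppressWarnings(summary(fit))$coefficients
    p <- ct[-1, 4]  # drop the intercept row
    worst <- which.max(p)
    if (p[worst] > alphaDrop) {
      keep <- keep[-worst]
      if (length(keep) == 0L) {
        fit <- stats::lm(form(keep), data = data)
        break
      }
    } else break
  }
  sm <- suppressWarnings(summary(fit))
  ct <- sm$coefficients
  sdy <- stats::sd(data[[response]])
  std <- c(NA_real_, vapply(keep, function(v)
    stats::sd(data[[v]]) / sdy, numeric(1))) * ct[, 1]
  std[1] <- NA_real_
  tab <- data.frame(term = c("(Intercept)", keep),
                    estimate = unname(ct[, 1]),
                    std_estimate = unname(std),
                    std_error = unname(ct[, 2]),
                    p_value = unname(ct[, 4]),
                    stringsAsFactors = FALSE)
  new("RegressionResult", coefficients = tab,
      excluded = setdiff(predictors, keep),
      rSquared = sm$r.squared, adjRSquared = sm$adj.r.squared,
      response = response)
}

#' Fit a canonical discriminant model
#'
#' Finds the linear combinations of features that maximize between-group
#' relative to pooled within-group scatter: the canonical directions are the
#' eigenvectors of \code{W^-1 B}, where \code{W} is the pooled within-group
#' covariance and \code{B} the between-group scatter, computed via a
#' Cholesky whitening of \code{W} so the problem stays symmetric. Axes are
#' scaled to unit pooled within-group variance (\code{a' W a = 1}) and signed
#' so each axis's largest-magnitude coefficient is positive. At most
#' \code{min(groups - 1, features)} axes are returned.
#'
#' @param data data.frame of samples.
#' @param labelField name of the grouping column (factor or character).
#' @param features character vector of feature columns.
#' @param priors \code{"equal"} (default), \code{"proportional"} to group
#'   sizes, or a numeric vector (one prior per group, in group-label order).
#' @return A [CDAModel-class].
#' @export
cdaFit <- function(data, labelField, features, priors = "equal") {
  stopifnot(is.data.frame(data), labelField %in% names(data),
            all(features %in% names(data)), length(features) >= 1L)
  g <- droplevels(factor(data[[labelField]]))
  labs <- levels(g)
  if (length(labs) < 2L) stop("need at least 2 groups")
  ns <- table(g)
  if (any(ns < 2L)) stop("every group needs at least 2 members")
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X); k <- length(labs)
  grand <- colMeans(X)
  M <- do.call(rbind, lapply(labs, function(l)
    colMeans(X[g == l, , drop = FALSE])))
  rownames(M) <- labs
  Sw <- matrix(0, p, p)
  for (l in labs) {
    xc <- sweep(X[g == l, , drop = FALSE], 2L, M[l, ])
    Sw <- Sw + crossprod(xc)
  }
  W <- Sw / (n - k)
  Mc <- sweep(M, 2L, grand)
  B <- crossprod(Mc * sqrt(as.numeric(ns)))  # sum_g n_g (m_g - m)(m_g - m)'
  U <- tryCatch(chol(W), error = function(e)
    stop("pooled within-group scatter is singular; ",
         "reduce or decorrelate the features"))
  Ui <- backsolve(U, diag(p))
  K <- crossprod(t(crossprod(Ui, B)), Ui)  # t(Ui) %*% B %*% Ui
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE)
  naxes <- min(k - 1L, p)
  # canonical eigenvalues on the conventional scatter scale (Sw^-1 Sb)
  vals <- pmax(ev$values[seq_len(naxes)], 0) / (n - k)
  A <- Ui %*% ev$vectors[, seq_len(naxes), drop = FALSE]
  for (j in seq_len(ncol(A))) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  dimnames(A) <- list(features, paste0("CAN", seq_len(naxes)))
  pri <- if (identical(priors, "equal")) rep(1 / k, k)
    else if (identical(priors, "proportional")) as.numeric(ns) / n
    else {
      stopifnot(is.numeric(priors), length(priors) == k)
      priors / sum(priors)
    }
  names(pri) <- labs
  cent <- Mc %*% A
  rownames(cent) <- labs
  new("CDAModel", coefficients = A, eigenvalues = vals, centroids = cent,
      groupLabels = labs, priors = pri, featureMeans = grand)
}

#' Classify samples with a canonical discriminant model
#'
#' Projects samples into canonical space and assigns each to the group whose
#' centroid minimizes the squared Euclidean distance adjusted by
#' \code{-2 log(prior)}. Exact ties go to the first group in label order.
#' Resubstitution (classifying the training samples) is supported.
#'
#' @param model a [CDAModel-class].
#' @param data data.frame containing the model's feature columns.
#' @return factor of predicted group labels.
#' @export
cdaClassify <- function(model, data) {
  stopifnot(is(model, "CDAModel"))
  feats <- rownames(model@coefficients)
  miss <- setdiff(feats, names(data))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(data[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  Z <- sweep(X, 2L, model@featureMeans) %*% model@coefficients
  scores <- vapply(seq_along(model@groupLabels), function(i) {
    d2 <- rowSums(sweep(Z, 2L, model@centroids[i, ])^2)
    d2 - 2 * log(model@priors[i])
  }, numeric(nrow(Z)))
  if (nrow(Z) == 1L) scores <- matrix(scores, nrow = 1L)
  idx <- apply(scores, 1L, which.min)
  factor(model@groupLabels[idx], levels = model@groupLabels)
}

#' Row-normalized confusion matrix
#'
#' Cross-tabulates true against predicted labels and normalizes each row to
#' percentages (rows = true group, columns = predicted group).
#'
#' @param truth,predicted equal-length label vectors.
#' @return A [ConfusionMatrix-class].
#' @export
confusionPercentages <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  if (length(truth) == 0L) stop("empty label vectors")
  truth <- droplevels(factor(truth))
  lev <- union(levels(truth), levels(droplevels(factor(predicted))))
  truth <- factor(truth, levels = lev)
  predicted <- factor(predicted, levels = lev)
  counts <- unclass(table(truth, predicted))
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  pct <- counts / rowSums(counts) * 100
  new("ConfusionMatrix", percent = pct, counts = counts)
}

#' Overall classification accuracy from a confusion matrix
#'
#' @param cm a [ConfusionMatrix-class].
#' @return Fraction of correctly classified samples (diagonal of the count
#'   matrix over its total).
#' @export
classificationAccuracy <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  counts <- cm@counts
  common <- intersect(rownames(counts), colnames(counts))
  sum(counts[cbind(common, common)]) / sum(counts)
}
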