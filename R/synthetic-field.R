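#' Configuration for the synthetic field-sample generator
#'
#' Describes the stated world of a first-date winter-wheat sampling: four
#' infestation groups (non-infested, grass, broad-leaved, mixture), per-group
#' covariate moments, and a linear model generating the ultrasonic height
#' from the covariates.
#'
#' Default moments follow the descriptive field statistics: grass weeds
#' height 3.6 (sd 0.6) cm, density 4.8 (2.9), biomass 0.7 (0.4) g;
#' broad-leaved weeds height 2.0 (1.1) cm, density 3.5 (2.9), biomass
#' 0.3 (0.3) g; crop height 6.6 (0.5) cm, density 9.7 (1.7), biomass
#' 1.6 (0.5) g; weed coverage 0.167 (0.103) as a fraction. Grass variables
#' are drawn only in the grass and mixture groups, broad-leaved variables
#' only in the broad-leaved and mixture groups; elsewhere they are exactly 0.
#' All draws are truncated normals (at 0; coverage also at 1).
#'
#' The ultrasonic height is \code{b0 + sum_j raw_j x_j + noise}. Raw
#' coefficients are derived from standardized ones via
#' \code{raw_j = beta_j * sdU / sd_j}; defaults are the significant
#' standardized coefficients of the first-date regression (coverage 0.029,
#' grass height 0.301, broad-leaved height 0.227, grass density 0.392, crop
#' density 0.225, grass biomass 0.174, broad-leaved biomass 0.177; crop
#' height, broad-leaved density and crop biomass 0, i.e. not significant),
#' with \code{sdU = 1.0} (the ultrasonic-height sd). The intercept is chosen
#' so that the expected mean ultrasonic height over an equal group mix is
#' \code{meanU} (default 3.7 cm), and the noise sd defaults to
#' \code{sqrt(1 - 0.667)} so the model R-squared is about 0.667.
#'
#' @param nPerGroup samples per group (default 20, i.e. 80 in total).
#' @param groups group labels, in order.
#' @param moments named list of \code{c(mean, sd)} per covariate.
#' @param stdCoefficients named numeric: standardized coefficients of the
#'   height model.
#' @param sdU,meanU standard deviation / mean of the ultrasonic height used
#'   to convert standardized to raw coefficients and set the intercept.
#' @param noiseSd residual sd of the height model in cm (must be > 0).
#' @param seed integer seed.
#' @return list of class \code{FieldSimConfig}.
#' @export
fieldSimConfig <- function(nPerGroup = 20L,
                           groups = c("non-infested", "grass",
                                      "broad-leaved", "mixture"),
                           moments = list(
                             weed_coverage = c(0.167, 0.103),
                             grass_height = c(3.6, 0.6),
                             bl_height = c(2.0, 1.1),
                             crop_height = c(6.6, 0.5),
                             grass_density = c(4.8, 2.9),
                             bl_density = c(3.5, 2.9),
                             crop_density = c(9.7, 1.7),
                             grass_biomass = c(0.7, 0.4),
                             bl_biomass = c(0.3, 0.3),
                             crop_biomass = c(1.6, 0.5)),
                           stdCoefficients = c(
                             weed_coverage = 0.029,
                             grass_height = 0.301,
                             bl_height = 0.227,
                             crop_height = 0,
                             grass_density = 0.392,
                             bl_density = 0,
                             crop_density = 0.225,
                             grass_biomass = 0.174,
                             bl_biomass = 0.177,
                             crop_biomass = 0),
                           sdU = 1.0, meanU = 3.7, noiseSd = sqrt(1 - 0.667),
                           seed = 1L) {
  stopifnot(nPerGroup >= 2L, noiseSd > 0, sdU > 0)
  sds <- vapply(moments, `[`, numeric(1), 2L)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  miss <- setdiff(names(stdCoefficients), names(moments))
  if (length(miss))
    stop("coefficients without moments: ", paste(miss, collapse = ", "))
  raw <- vapply(names(stdCoefficients), function(v) {
    s <- moments[[v]][2]
    if (stdCoefficients[[v]] == 0) 0 else stdCoefficients[[v]] * sdU / s
  }, numeric(1))
  # expected covariate mean over an equal group mix (weed variables are zero
  # in the groups where the weed type is absent)
  present <- function(v) {
    if (startsWith(v, "grass_")) 0.5
    else if (startsWith(v, "bl_")) 0.5
    else if (v == "weed_coverage") 0.75
    else 1
  }
  emeans <- vapply(names(raw),
                   function(v) moments[[v]][1] * present(v), numeric(1))
  b0 <- meanU - sum(raw * emeans)
  structure(list(nPerGroup = as.integer(nPerGroup), groups = groups,
                 moments = moments, stdCoefficients = stdCoefficients,
                 rawCoefficients = raw, intercept = b0, sdU = sdU,
                 meanU = meanU, noiseSd = noiseSd, seed = as.integer(seed)),
            class = "FieldSimConfig")
}

.rtrunc <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  truncnorm::rtruncnorm(n, a = lower, b = upper, mean = mean, sd = sd)
}

#' Generate a synthetic field-sample table
#'
#' Draws one row per sampling point with the group structure of a weed
#' infestation survey: per-group covariates from truncated normals at the
#' configured moments, the ultrasonic height from the configured linear model
#' plus Gaussian noise, and categorical labels (4-level infestation and
#' binary weed presence).
#'
#' @param cfg a [fieldSimConfig()].
#' @return data.frame with columns \code{sample_id}, \code{infestation},
#'   \code{weed_presence}, \code{ultrasonic_height} and the ten covariates.
#'   Reproducible: a fixed seed gives an identical table.
#' @export
genFieldTable <- function(cfg = fieldSimConfig()) {
  stopifnot(inherits(cfg, "FieldSimConfig"))
  withSeed(cfg$seed, {
    rows <- lapply(cfg$groups, function(g) {
      n <- cfg$nPerGroup
      draw <- function(v, lower = 0, upper = Inf) {
        m <- cfg$moments[[v]]
        .rtrunc(n, m[1], m[2], lower, upper)
      }
      hasGrass <- g %in% c("grass", "mixture")
      hasBl <- g %in% c("broad-leaved", "mixture")
      infested <- g != "non-infested"
      data.frame(
        infestation = g,
        weed_presence = if (infested) "infested" else "non-infested",
        weed_coverage = if (infested) draw("weed_coverage", 0, 1) else 0,
        grass_height = if (hasGrass) draw("grass_height") else 0,
        bl_height = if (hasBl) draw("bl_height") else 0,
        crop_height = draw("crop_height"),
        grass_density = if (hasGrass) draw("grass_density") else 0,
        bl_density = if (hasBl) draw("bl_density") else 0,
        crop_density = draw("crop_density"),
        grass_biomass = if (hasGrass) draw("grass_biomass") else 0,
        bl_biomass = if (hasBl) draw("bl_biomass") else 0,
        crop_biomass = draw("crop_biomass"))
    })
    tab <- do.call(rbind, rows)
    X <- as.matrix(tab[, names(cfg$rawCoefficients)])
    u <- cfg$intercept + drop(X %*% cfg$rawCoefficients) +
      stats::rnorm(nrow(tab), 0, cfg$noiseSd)
    out <- cbind(data.frame(sample_id = seq_len(nrow(tab)),
                            ultrasonic_height = u), tab)
    out$infestation <- factor(out$infestation, levels = cfg$groups)
    out$weed_presence <- factor(out$weed_presence,
                                levels = c("non-infested", "infested"))
    out
  })
}

#' Read / write a field-sample table as CSV
#'
#' @param path file path.
#' @return \code{readFieldTable} returns the table with label columns
#'   restored as factors.
#' @export
readFieldTable <- function(path) {
  tab <- utils::read.csv(path)
  if ("infestation" %in% names(tab)) {
    lev <- c("non-infested", "grass", "broad-leaved", "mixture")
    tab$infestation <- factor(tab$infestation,
                              levels = intersect(lev, unique(tab$infestation)))
  }
  if ("weed_presence" %in% names(tab))
    tab$weed_presence <- factor(tab$weed_presence,
                                levels = intersect(c("non-infested", "infested"),
                                                   unique(tab$weed_presence)))
  tab
}

#' @rdname readFieldTable
#' @param tab field table data.frame.
#' @export
writeFieldTable <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
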