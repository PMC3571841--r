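# Independent oracles and small fixture builders used across tests.

# Brute-force circular Hough support: for every grid cell, count object
# pixels whose rounded Euclidean distance to the cell equals r
# (d in [r - 1/2, r + 1/2), exact integer arithmetic). Independent of the
# accumulator implementation: it loops over centres, not over voters.
bruteHoughSupport <- function(mask, r) {
  idx <- which(mask, arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      d2 <- (px - (j - 1))^2 + (py - (i - 1))^2
      out[i, j] <- sum(4 * d2 >= (2 * r - 1)^2 & 4 * d2 < (2 * r + 1)^2)
    }
  }
  out
}

# rasterized circle mask: pixels at rounded distance r from (x0, y0), 0-based
circleMask <- function(dim, x0, y0, r) {
  y <- (seq_len(dim[1]) - 1) - y0
  x <- (seq_len(dim[2]) - 1) - x0
  d2 <- outer(y^2, x^2, `+`)
  4 * d2 >= (2 * r - 1)^2 & 4 * d2 < (2 * r + 1)^2
}

# single-colour RGB image
flatImage <- function(dim, rgb) {
  img <- array(0, dim = c(dim, 3L))
  for (k in 1:3) img[, , k] <- rgb[k]
  img
}

# constant-distance voltage trace
constantTrace <- function(d_cm, n = 101L, dt = 0.1) {
  data.frame(t_seconds = (seq_len(n) - 1) * dt,
             volts = rep(distanceToVoltage(d_cm), n))
}
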