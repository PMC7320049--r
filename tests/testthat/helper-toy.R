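# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; no data files are read.

# the standard toy calibration system (4 components, 423-point grid)
toy <- makeToyLibrary(seed = 1L)

# a coarse grid whose points land exactly on 0.01-ppm positions
gridCoarse <- SpectralGrid(5.6, 9.0, 341L)

# a fine grid for quadrature comparisons
gridFine <- SpectralGrid(5.6, 9.0, 20001L)

# brute-force mixture evaluation: every peak of every component
# evaluated independently through the public single-peak interface
bruteMixture <- function(mixture, grid, params) {
  y <- numeric(grid@nPoints)
  for (k in seq_along(components(mixture))) {
    m <- components(mixture)[[k]]
    p <- peaks(m)
    for (i in seq_len(nrow(p))) {
      om <- p$omega[i] + params@peakJitter[[k]][i] +
        params@groupShift[[k]][p$group[i] + 1L] + params@componentShift[k]
      y <- y + params@weights[k] *
        evalPeak(om, p$alpha[i], p$gamma[i] * params@peakBroadening[k],
                 p$beta[i], grid)
    }
  }
  y
}

# brute-force steady-state classification: refit every centred window
# with lm() on true timestamps
bruteSteadyMask <- function(series, window = 11L, slopeMax = 0.1,
                            stdMax = 0.01) {
  n <- length(series@time)
  half <- (window - 1L) %/% 2L
  mask <- rep(FALSE, n)
  if (n < window) return(mask)
  for (c0 in seq.int(half + 1L, n - half)) {
    rows <- (c0 - half):(c0 + half)
    ok <- TRUE
    for (j in seq_len(ncol(series@values))) {
      d <- data.frame(t = series@time[rows], y = series@values[rows, j])
      ft <- stats::lm(y ~ t, data = d)
      sig <- sqrt(stats::deviance(ft) / stats::df.residual(ft))
      if (!(abs(stats::coef(ft)[2]) < slopeMax && sig < stdMax)) {
        ok <- FALSE; break
      }
    }
    mask[c0] <- ok
  }
  mask
}

# brute-force Kennard-Stone: recompute the max-min criterion over all
# remaining candidates from scratch at every step
bruteKennardStone <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  best <- c(1L, 2L)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    if (D[i, j] > D[best[1], best[2]]) best <- c(i, j)
  sel <- sort(best)
  while (length(sel) < k) {
    rest <- setdiff(seq_len(n), sel)
    crit <- vapply(rest, function(r) min(D[r, sel]), numeric(1))
    sel <- c(sel, rest[which.max(crit)])
  }
  sel[seq_len(k)]
}
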