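#' @include spectral-model.R
NULL

#' Apply a line-broadening factor to a spectrum
#'
#' Convolves the spectrum with a unit-area Lorentzian kernel of full
#' width at half maximum \code{lb} Hz (converted to ppm through the
#' grid's spectrometer frequency). This is the frequency-domain
#' equivalent of exponential apodization of the underlying FID, the
#' standard way a Hz-scale broadening factor acts on an NMR spectrum.
#' The discrete kernel is normalised to unit sum, so the integral of
#' the spectrum is preserved (up to the Lorentzian tail mass beyond
#' the truncated kernel support, < 0.2\%).
#'
#' @param spectrum a \linkS4class{Spectrum}
#' @param lb line-broadening factor in Hz (>= 0); 0 is the identity
#' @return the broadened \linkS4class{Spectrum}
#' @export
broadenSpectrum <- function(spectrum, lb) {
  if (lb < 0) stop("lb must be >= 0 (Hz)")
  if (lb == 0) return(spectrum)
  grid <- spectrum@grid
  hwhm <- (lb / grid@spectrometerFreq) / 2    # Hz -> ppm, FWHM -> HWHM
  dppm <- deltaPpm(grid)
  # The kernel is truncated at +/- 60 HWHM and renormalised to unit
  # sum: the discrete convolution then redistributes each point's
  # mass exactly, so the integral over the window is conserved for
  # peaks further than the kernel support from the edges (the far
  # Lorentzian tails, ~1% of kernel mass, are folded back by the
  # renormalisation instead of leaking out of the window).
  M <- max(25L, ceiling(60 * hwhm / dppm))
  x <- seq(-M, M) * dppm
  kern <- hwhm / (x^2 + hwhm^2)               # Lorentzian, unnormalised
  kern <- kern / sum(kern)
  y <- spectrum@intensity
  ypad <- c(numeric(M), y, numeric(M))
  out <- stats::convolve(ypad, rev(kern), type = "open")
  y2 <- out[(2 * M + 1):(2 * M + length(y))]
  Spectrum(grid, y2, meta = c(spectrum@meta, list(lb_hz = lb)))
}

#' Translate a spectrum along the ppm axis
#'
#' Shifts the intensity by \code{delta} ppm (positive = towards higher
#' ppm) using linear interpolation on the grid; points vacated at the
#' edges are filled with zero. Interior peak areas are preserved by
#' the interpolation up to edge truncation.
#'
#' @param spectrum a \linkS4class{Spectrum}
#' @param delta shift in ppm, |delta| at most the grid span
#' @return the shifted \linkS4class{Spectrum}
#' @export
shiftSpectrum <- function(spectrum, delta) {
  if (delta == 0) return(spectrum)
  grid <- spectrum@grid
  span <- grid@ppmEnd - grid@ppmStart
  delta <- max(-span, min(span, delta))
  nu <- ppmAxis(grid)
  y2 <- stats::approx(nu, spectrum@intensity, xout = nu - delta,
                      method = "linear", yleft = 0, yright = 0)$y
  Spectrum(grid, y2, meta = c(spectrum@meta, list(shift_ppm = delta)))
}

#' Harvest an empirical noise pool from baseline regions
#'
#' Collects the intensity values of a measured, baseline-corrected
#' spectrum inside signal-free ppm intervals. Synthetic spectra later
#' resample this pool (with replacement) so their noise carries the
#' real instrument's statistics.
#'
#' @param spectrum a \linkS4class{Spectrum}, baseline-corrected
#' @param baselineRegions 2-column matrix (or list of length-2
#'   vectors) of ppm intervals known to contain no signal
#' @return a \linkS4class{NoisePool}
#' @export
extractNoisePool <- function(spectrum, baselineRegions) {
  if (is.list(baselineRegions))
    baselineRegions <- do.call(rbind, baselineRegions)
  baselineRegions <- matrix(as.numeric(baselineRegions), ncol = 2)
  if (nrow(baselineRegions) == 0L) stop("no baseline regions given")
  nu <- ppmAxis(spectrum)
  keep <- rep(FALSE, length(nu))
  for (i in seq_len(nrow(baselineRegions))) {
    r <- sort(baselineRegions[i, ])
    if (r[1] < spectrum@grid@ppmStart - 1e-12 ||
        r[2] > spectrum@grid@ppmEnd + 1e-12)
      stop("baseline region outside the grid")
    keep <- keep | (nu >= r[1] & nu <= r[2])
  }
  if (sum(keep) < 100L)
    stop("baseline regions must contain at least 100 grid points")
  new("NoisePool", samples = spectrum@intensity[keep],
      sourceRegions = baselineRegions)
}

#' Generate the pure-spectrum synthetic dataset
#'
#' Builds labelled mixture spectra as linear combinations of altered
#' measured pure-component spectra. Per output spectrum and per
#' component, three parameters are drawn (in this fixed order:
#' line broadening, component shift, target area; components in
#' mixture order): a line-broadening factor uniform over the discrete
#' Hz set, a component shift uniform over the symmetric ppm range, and
#' a target area uniform over the area interval. The altered pure
#' spectrum is rescaled by a scalar so its trapezoidal area equals the
#' target; the label is that integrated area. The mixture is the sum
#' of the K altered, scaled components. A single seeded RNG drives the
#' whole build, so the same config reproduces the dataset bit for bit.
#'
#' Because measured pure spectra carry measurement noise that is
#' scaled together with the signal, label conservation (sum of labels
#' vs integral of the mixture) holds only up to that noise.
#'
#' @param pureSpectra list of K measured \linkS4class{Spectrum}s on a
#'   common grid, one per component (names become component names)
#' @param config an \linkS4class{XiConfig}
#' @return a \linkS4class{LabeledDataset}
#' @export
makeDatasetXi <- function(pureSpectra, config = XiConfig()) {
  K <- length(pureSpectra)
  if (K < 1L) stop("need at least one pure spectrum")
  grid <- pureSpectra[[1]]@grid
  for (s in pureSpectra)
    if (!isTRUE(all.equal(ppmAxis(s@grid), ppmAxis(grid))))
      stop("all pure spectra must share one grid")
  nm <- names(pureSpectra)
  if (is.null(nm)) nm <- paste0("comp", seq_len(K))
  dppm <- deltaPpm(grid)
  for (k in seq_len(K))
    if (.trapz(pureSpectra[[k]]@intensity, dppm) <= 0)
      stop(sprintf("pure spectrum '%s' has non-positive total area", nm[k]))

  lbSet <- config@lineBroadeningSet
  # all (component, lb) combinations are precomputed; draws then only
  # pick indices, shift and rescale
  broadened <- lapply(pureSpectra, function(s)
    lapply(lbSet, function(lb) broadenSpectrum(s, lb)@intensity))

  n <- config@nSpectra
  nu <- ppmAxis(grid)
  X <- matrix(0, nrow = n, ncol = grid@nPoints)
  A <- matrix(0, nrow = n, ncol = K, dimnames = list(NULL, nm))
  P <- matrix(0, nrow = n, ncol = 3L * K)
  colnames(P) <- as.vector(t(outer(nm, c("lb", "shift", "area"), paste, sep = "_")))

  set.seed(config@seed)
  sr <- config@componentShiftRange
  ar <- config@areaRange
  for (i in seq_len(n)) {
    acc <- numeric(grid@nPoints)
    for (k in seq_len(K)) {
      j <- sample.int(length(lbSet), 1L)
      sh <- stats::runif(1, -sr, sr)
      target <- stats::runif(1, ar[1], ar[2])
      y <- broadened[[k]][[j]]
      if (sh != 0)
        y <- stats::approx(nu, y, xout = nu - sh, yleft = 0, yright = 0)$y
      a0 <- .trapz(y, dppm)
      y <- y * (target / a0)
      acc <- acc + y
      A[i, k] <- .trapz(y, dppm)
      P[i, (k - 1L) * 3L + 1:3] <- c(lbSet[j], sh, target)
    }
    X[i, ] <- acc
  }
  new("LabeledDataset", spectra = X, labels = A,
      paramsLog = as.data.frame(P), grid = grid, seed = config@seed)
}

#' Generate the spectral-model synthetic dataset
#'
#' Builds labelled mixture spectra from the parametric pseudo-Voigt
#' mixture model. Per output spectrum the sampled parameters are, in
#' this fixed order for each component k: component shift, width
#' multiplier, target area, the per-group shifts, the per-peak
#' position jitters; after all components, the noise amplitude factor
#' and the per-point noise resampling indices. All signed ranges are
#' symmetric uniform. The component weight \eqn{w_k} is chosen so that
#' the noise-free trapezoidal area of component k equals its sampled
#' target; the label IS that noise-free area, computed before any
#' noise is added. Noise is drawn from the empirical pool with
#' replacement, independently per grid point, and scaled by
#' \eqn{1 + u} with \eqn{u \sim U(-r, +r)} per spectrum.
#'
#' @param mixture a \linkS4class{MixtureModel} with grouped peaks
#' @param grid a \linkS4class{SpectralGrid}
#' @param noisePool a \linkS4class{NoisePool}, or NULL when
#'   \code{config@noiseOff} is TRUE
#' @param config an \linkS4class{XiiConfig}
#' @return a \linkS4class{LabeledDataset}
#' @export
makeDatasetXii <- function(mixture, grid, noisePool = NULL,
                           config = XiiConfig()) {
  comps <- mixture@components
  K <- length(comps)
  nm <- componentNames(mixture)
  if (!config@noiseOff && is.null(noisePool))
    stop("noisePool required unless config@noiseOff is TRUE")
  nGr <- vapply(comps, nGroups, integer(1))
  nPk <- vapply(comps, function(m) nrow(m@peaks), integer(1))
  dppm <- deltaPpm(grid)

  n <- config@nSpectra
  X <- matrix(0, nrow = n, ncol = grid@nPoints)
  A <- matrix(0, nrow = n, ncol = K, dimnames = list(NULL, nm))
  P <- vector("list", n)

  set.seed(config@seed)
  jr <- config@peakJitterRange; sr <- config@componentShiftRange
  gr <- config@groupShiftRange; br <- config@broadeningRange
  ar <- config@areaRange; nr <- config@noiseFactorRange
  for (i in seq_len(n)) {
    acc <- numeric(grid@nPoints)
    row <- numeric(0)
    for (k in seq_len(K)) {
      thS <- stats::runif(1, -sr, sr)
      thPB <- 1 + stats::runif(1, -br, br)
      target <- stats::runif(1, ar[1], ar[2])
      thGS <- stats::runif(nGr[k], -gr, gr)
      jit <- stats::runif(nPk[k], -jr, jr)
      y <- evalComponent(comps[[k]], grid, componentShift = thS,
                         groupShift = thGS, broadening = thPB,
                         peakJitter = jit, warnTruncation = FALSE)
      a1 <- .trapz(y, dppm)
      w <- if (target == 0 || a1 <= 0) 0 else target / a1
      acc <- acc + w * y
      A[i, k] <- w * a1
      row <- c(row, thS, thPB, target, thGS, jit)
    }
    if (!is.null(noisePool)) {
      # noise draws are consumed even when noiseOff, so the labels and
      # noise-free signal of a build are invariant to the noise toggle
      u <- stats::runif(1, -nr, nr)
      idx <- sample.int(length(noisePool@samples), grid@nPoints,
                        replace = TRUE)
      if (!config@noiseOff) acc <- acc + noisePool@samples[idx] * (1 + u)
      row <- c(row, u)
    }
    X[i, ] <- acc
    P[[i]] <- row
  }
  cn <- character(0)
  for (k in seq_len(K))
    cn <- c(cn, paste0(nm[k], "_", c("shift", "broadening", "area",
                                     paste0("gshift", seq_len(nGr[k])),
                                     paste0("jitter", seq_len(nPk[k])))))
  if (!is.null(noisePool)) cn <- c(cn, "noise_factor")
  P <- do.call(rbind, P)
  colnames(P) <- cn
  new("LabeledDataset", spectra = X, labels = A,
      paramsLog = as.data.frame(P), grid = grid, seed = config@seed)
}
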