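#' @include augment.R
NULL

# Fixed peak tables of the toy 4-component system. Positions sit well
# inside the 5.6..9.0 ppm window (>= 10 gamma from the edges, so
# truncated Lorentzian tail mass stays far below 1%), linewidths are
# benchtop-typical (HWHM 0.012..0.02 ppm at 43.3 MHz), and three
# regions (6.5-6.7, 7.2-7.4, 7.9-8.1 ppm) are shared by two
# components to force the overlapping multiplets a low-field
# spectrometer cannot resolve by direct integration.
.toyPeakTables <- function() list(
  oFNB = data.frame(
    omega = c(7.95, 8.03, 8.22, 8.30),
    alpha = c(0.90, 1.00, 0.55, 0.60),
    gamma = c(0.018, 0.016, 0.015, 0.017),
    beta  = c(0.90, 1.00, 0.85, 1.00)),
  LiMNDPA = data.frame(
    omega = c(6.55, 6.63, 6.72, 7.18, 7.27, 7.38, 8.05),
    alpha = c(0.45, 0.60, 0.40, 0.85, 1.00, 0.50, 0.35),
    gamma = c(0.016, 0.018, 0.015, 0.020, 0.018, 0.016, 0.014),
    beta  = c(1.00, 0.90, 0.95, 1.00, 0.85, 0.90, 1.00)),
  LiToluidine = data.frame(
    omega = c(6.45, 6.52, 7.20, 7.30, 7.95),
    alpha = c(0.70, 0.80, 0.50, 0.45, 0.30),
    gamma = c(0.017, 0.015, 0.019, 0.016, 0.018),
    beta  = c(0.95, 1.00, 0.90, 1.00, 0.80)),
  Toluidine = data.frame(
    omega = c(6.60, 6.68, 7.50),
    alpha = c(0.95, 0.90, 0.65),
    gamma = c(0.016, 0.018, 0.020),
    beta  = c(1.00, 0.95, 0.90)))

# plateau levels (rows) per component (cols), mol/L
.toyLevels <- matrix(c(
  0.60, 0.05, 0.10, 0.70,
  0.40, 0.25, 0.30, 0.45,
  0.15, 0.50, 0.45, 0.20,
  0.30, 0.35, 0.25, 0.35), nrow = 4, byrow = TRUE)

# piecewise plateau/ramp truth: plateaus [0,2], [3,5], [6,8], [8.5,10] h
.toyTruth <- function(t) {
  lev <- .toyLevels
  seg <- function(ti) {
    if (ti <= 2) return(lev[1, ])
    if (ti <= 3) return(lev[1, ] + (ti - 2) * (lev[2, ] - lev[1, ]))
    if (ti <= 5) return(lev[2, ])
    if (ti <= 6) return(lev[2, ] + (ti - 5) * (lev[3, ] - lev[2, ]))
    if (ti <= 8) return(lev[3, ])
    if (ti <= 8.5) return(lev[3, ] + (ti - 8) / 0.5 * (lev[4, ] - lev[3, ]))
    lev[4, ]
  }
  t(vapply(t, seg, numeric(4)))
}

#' Build the self-contained toy calibration system
#'
#' Generates everything the pipeline needs without any measured data:
#' a 4-component pseudo-Voigt mixture model whose components play the
#' roles of the reaction species (reagent, lithiated intermediate,
#' free amine, lithiated product), rendered pure-component spectra
#' with 0.5\% white measurement noise, an empirical baseline noise
#' pool, and a 200-point process trajectory with four concentration
#' plateaus joined by ramps, observed by a noisy "online" analyzer
#' (with a few reference-side outliers injected at known rows) and a
#' near-exact "reference" analyzer on its own time base.
#'
#' The peak tables are fixed; the seed drives only the stochastic
#' parts (measurement noise, baseline pool, trajectory noise), so the
#' whole library is bit-identical for a given seed.
#'
#' @param seed integer seed
#' @param grid the \linkS4class{SpectralGrid} to render on (default a
#'   423-point 5.6..9.0 ppm axis, compact enough for fast experiments)
#' @return a named list: \code{mixture} (\linkS4class{MixtureModel}),
#'   \code{pureSpectra} (named list of noisy \linkS4class{Spectrum}s),
#'   \code{noisePool} (\linkS4class{NoisePool}), \code{lfSeries} and
#'   \code{hfSeries} (\linkS4class{TimeSeriesTable}s), \code{truthLf}
#'   (noise-free concentrations at the lf timestamps),
#'   \code{outlierRows} (hf rows carrying injected outliers),
#'   \code{grid}, \code{seed}
#' @export
makeToyLibrary <- function(seed = 1L, grid = SpectralGrid(5.6, 9.0, 423L)) {
  set.seed(seed)
  tabs <- .toyPeakTables()
  comps <- lapply(names(tabs), function(nm)
    PureComponentModel(nm, tabs[[nm]], deltaNu = 0.12))
  mixture <- MixtureModel(comps)

  clean <- lapply(comps, function(m)
    evalComponent(m, grid, warnTruncation = FALSE))
  maxI <- max(vapply(clean, max, numeric(1)))
  noiseSd <- 0.005 * maxI
  pureSpectra <- lapply(seq_along(comps), function(k)
    Spectrum(grid, clean[[k]] + stats::rnorm(grid@nPoints, 0, noiseSd),
             meta = list(component = comps[[k]]@name)))
  names(pureSpectra) <- names(tabs)

  baseline <- Spectrum(grid, stats::rnorm(grid@nPoints, 0, noiseSd),
                       meta = list(source = "toy blank"))
  noisePool <- extractNoisePool(baseline,
                                rbind(c(grid@ppmStart, grid@ppmEnd)))

  compNames <- names(tabs)
  tLf <- seq(0, 10, length.out = 200)
  truthLf <- .toyTruth(tLf)
  colnames(truthLf) <- compNames
  lfVals <- truthLf + matrix(stats::rnorm(length(truthLf), 0, 0.003),
                             nrow(truthLf))
  lfSeries <- TimeSeriesTable(tLf, lfVals, source = "toy online")

  tHf <- seq(0.015, 10, length.out = 190)
  truthHf <- .toyTruth(tHf)
  colnames(truthHf) <- compNames
  hfVals <- truthHf + matrix(stats::rnorm(length(truthHf), 0, 0.001),
                             nrow(truthHf))
  # reference-side glitches on plateau rows: large enough (0.08 mol/L)
  # that the analyzer-disagreement filter must drop them
  outlierRows <- c(20L, 75L, 130L, 180L)
  for (r in outlierRows)
    hfVals[r, 1 + (r %% 4L)] <- hfVals[r, 1 + (r %% 4L)] + 0.08
  hfSeries <- TimeSeriesTable(tHf, hfVals, source = "toy reference")

  list(mixture = mixture, pureSpectra = pureSpectra,
       noisePool = noisePool, lfSeries = lfSeries, hfSeries = hfSeries,
       truthLf = truthLf, outlierRows = outlierRows, grid = grid,
       seed = as.integer(seed))
}
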