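#' @include AllClasses.R
NULL

# ---- generics ---------------------------------------------------------------

#' @export
setGeneric("ppmAxis", function(x) standardGeneric("ppmAxis"))
#' @export
setGeneric("deltaPpm", function(x) standardGeneric("deltaPpm"))
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))
#' @export
setGeneric("areaLabels", function(x) standardGeneric("areaLabels"))
#' @export
setGeneric("paramsLog", function(x) standardGeneric("paramsLog"))
#' @export
setGeneric("history", function(x) standardGeneric("history"))
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))

# ---- accessors --------------------------------------------------------------

#' Chemical-shift axis of a grid or spectrum
#'
#' @param x a \linkS4class{SpectralGrid} or \linkS4class{Spectrum}
#' @return numeric vector of ppm values, ascending
#' @export
setMethod("ppmAxis", "SpectralGrid", function(x)
  seq(x@ppmStart, x@ppmEnd, length.out = x@nPoints))

#' @rdname ppmAxis
#' @export
setMethod("ppmAxis", "Spectrum", function(x) ppmAxis(x@grid))

#' Grid spacing in ppm
#' @param x a \linkS4class{SpectralGrid} or \linkS4class{Spectrum}
#' @return single numeric, the uniform point spacing
#' @export
setMethod("deltaPpm", "SpectralGrid", function(x)
  (x@ppmEnd - x@ppmStart) / (x@nPoints - 1L))

#' @rdname deltaPpm
#' @export
setMethod("deltaPpm", "Spectrum", function(x) deltaPpm(x@grid))

#' Intensity vector of a spectrum
#' @param x a \linkS4class{Spectrum}
#' @return numeric vector (a.u.)
#' @export
setMethod("intensity", "Spectrum", function(x) x@intensity)

#' Peak table of a pure-component model
#' @param x a \linkS4class{PureComponentModel}
#' @return data.frame with columns omega, alpha, gamma, beta, group
#' @export
setMethod("peaks", "PureComponentModel", function(x) x@peaks)

#' Component models of a mixture
#' @param x a \linkS4class{MixtureModel}
#' @return list of \linkS4class{PureComponentModel}
#' @export
setMethod("components", "MixtureModel", function(x) x@components)

#' Component names of a mixture
#' @param x a \linkS4class{MixtureModel}
#' @return character vector
#' @export
setMethod("componentNames", "MixtureModel", function(x)
  vapply(x@components, function(m) m@name, character(1)))

#' Number of peak groups
#' @param x a \linkS4class{PureComponentModel}
#' @return integer count of groups
#' @export
setMethod("nGroups", "PureComponentModel", function(x)
  length(unique(x@peaks$group)))

#' Spectra matrix of a labelled dataset
#' @param x a \linkS4class{LabeledDataset}
#' @return n x nPoints matrix
#' @export
setMethod("spectra", "LabeledDataset", function(x) x@spectra)

#' Area labels of a labelled dataset
#' @param x a \linkS4class{LabeledDataset}
#' @return n x K matrix of areas (a.u.)
#' @export
setMethod("areaLabels", "LabeledDataset", function(x) x@labels)

#' Sampled-parameter log of a labelled dataset
#' @param x a \linkS4class{LabeledDataset}
#' @return data.frame, one row per spectrum
#' @export
setMethod("paramsLog", "LabeledDataset", function(x) x@paramsLog)

#' Per-epoch training record
#' @param x a \linkS4class{TrainedModel}
#' @return data.frame with one row per completed epoch
#' @export
setMethod("history", "TrainedModel", function(x) x@history)

#' Fitted object inside a fit result
#' @param x a \linkS4class{FitResult}
#' @return the fitted \linkS4class{PureComponentModel} or
#'   \linkS4class{MixtureParams}
#' @export
setMethod("fittedModel", "FitResult", function(x) x@model)

# ---- constructors -----------------------------------------------------------

#' Construct a uniform spectral grid
#'
#' @param ppmStart,ppmEnd axis limits in ppm (ascending)
#' @param nPoints number of points
#' @param spectrometerFreq proton frequency in MHz (fixes ppm-to-Hz)
#' @return a \linkS4class{SpectralGrid}
#' @examples
#' SpectralGrid()                # 5.6..9.0 ppm, 1692 points, 43.3 MHz
#' SpectralGrid(0, 10, 2048, 500)
#' @export
SpectralGrid <- function(ppmStart = 5.6, ppmEnd = 9.0, nPoints = 1692L,
                         spectrometerFreq = 43.3) {
  new("SpectralGrid", ppmStart = as.numeric(ppmStart),
      ppmEnd = as.numeric(ppmEnd), nPoints = as.integer(nPoints),
      spectrometerFreq = as.numeric(spectrometerFreq))
}

#' Construct a spectrum
#'
#' @param grid a \linkS4class{SpectralGrid}
#' @param intensity numeric vector of length \code{nPoints}
#' @param meta named list of provenance
#' @return a \linkS4class{Spectrum}
#' @export
Spectrum <- function(grid, intensity, meta = list()) {
  new("Spectrum", grid = grid, intensity = as.numeric(intensity), meta = meta)
}

#' Construct a pure-component peak model
#'
#' Peaks are sorted by position; if \code{group} is missing, groups are
#' assigned by chaining peaks whose positions lie within \code{deltaNu}
#' ppm of their neighbour (see \code{\link{assignGroups}}).
#'
#' @param name component label
#' @param peaks data.frame with columns omega (ppm), alpha (a.u.),
#'   gamma (HWHM, ppm), beta (Lorentzian weight in [0,1]) and
#'   optionally group
#' @param deltaNu grouping threshold in ppm
#' @return a \linkS4class{PureComponentModel}
#' @export
PureComponentModel <- function(name, peaks, deltaNu = 0.12) {
  peaks <- as.data.frame(peaks)
  peaks <- peaks[order(peaks$omega), , drop = FALSE]
  rownames(peaks) <- NULL
  if (is.null(peaks$group))
    peaks$group <- assignGroups(peaks$omega, deltaNu)
  peaks$group <- as.integer(peaks$group)
  new("PureComponentModel", name = name, peaks = peaks,
      deltaNu = as.numeric(deltaNu))
}

#' Construct a mixture model
#'
#' @param ... \linkS4class{PureComponentModel}s, or a single list of them
#' @return a \linkS4class{MixtureModel}
#' @export
MixtureModel <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1]]) &&
      !is(comps[[1]], "PureComponentModel"))
    comps <- comps[[1]]
  new("MixtureModel", components = comps)
}

#' Construct mixture perturbation parameters
#'
#' Missing arguments default to the identity transformation (weight 1,
#' zero shifts, unit broadening, zero jitter) for the given mixture.
#'
#' @param mixture the \linkS4class{MixtureModel} the parameters belong to
#' @param weights per-component weights (>= 0)
#' @param componentShift per-component shift, ppm
#' @param groupShift list of per-group shift vectors, ppm
#' @param peakBroadening per-component width multipliers (> 0)
#' @param peakJitter list of per-peak position perturbations, ppm
#' @return a \linkS4class{MixtureParams}
#' @export
MixtureParams <- function(mixture, weights = NULL, componentShift = NULL,
                          groupShift = NULL, peakBroadening = NULL,
                          peakJitter = NULL) {
  K <- length(mixture@components)
  if (is.null(weights)) weights <- rep(1, K)
  if (is.null(componentShift)) componentShift <- rep(0, K)
  if (is.null(peakBroadening)) peakBroadening <- rep(1, K)
  if (is.null(groupShift))
    groupShift <- lapply(mixture@components,
                         function(m) rep(0, nGroups(m)))
  if (is.null(peakJitter))
    peakJitter <- lapply(mixture@components,
                         function(m) rep(0, nrow(m@peaks)))
  new("MixtureParams", weights = as.numeric(weights),
      componentShift = as.numeric(componentShift),
      groupShift = lapply(groupShift, as.numeric),
      peakBroadening = as.numeric(peakBroadening),
      peakJitter = lapply(peakJitter, as.numeric))
}

#' Construct a generator configuration for the pure-spectrum dataset
#'
#' @param nSpectra number of spectra to generate
#' @param areaRange target-area interval, a.u.
#' @param lineBroadeningSet discrete line-broadening values, Hz
#' @param componentShiftRange half-width of the symmetric shift range, ppm
#' @param seed integer RNG seed
#' @return an \linkS4class{XiConfig}
#' @export
XiConfig <- function(nSpectra = 300000L, areaRange = c(0, 180),
                     lineBroadeningSet = c(0.2, 0.5, 0.8, 1.0, 1.5),
                     componentShiftRange = 0.015, seed = 1L) {
  new("XiConfig", areaRange = as.numeric(areaRange),
      lineBroadeningSet = as.numeric(lineBroadeningSet),
      componentShiftRange = as.numeric(componentShiftRange),
      nSpectra = as.integer(nSpectra), seed = as.integer(seed))
}

#' Construct a generator configuration for the spectral-model dataset
#'
#' @param nSpectra number of spectra to generate
#' @param peakJitterRange half-width of per-peak position jitter, ppm
#' @param componentShiftRange half-width of the component shift, ppm
#' @param groupShiftRange half-width of the group shift, ppm
#' @param broadeningRange half-width of the width multiplier as a
#'   fraction (0.15 means multipliers in [0.85, 1.15])
#' @param areaRange target-area interval, a.u.
#' @param noiseFactorRange half-width of the noise amplitude scale
#'   as a fraction
#' @param noiseOff TRUE builds noise-free spectra (labels are always
#'   computed noise-free either way)
#' @param seed integer RNG seed
#' @return an \linkS4class{XiiConfig}
#' @export
XiiConfig <- function(nSpectra = 300000L, peakJitterRange = 0.005,
                      componentShiftRange = 0.015, groupShiftRange = 0.01,
                      broadeningRange = 0.15, areaRange = c(0, 180),
                      noiseFactorRange = 0.15, noiseOff = FALSE, seed = 1L) {
  new("XiiConfig", peakJitterRange = as.numeric(peakJitterRange),
      componentShiftRange = as.numeric(componentShiftRange),
      groupShiftRange = as.numeric(groupShiftRange),
      broadeningRange = as.numeric(broadeningRange),
      areaRange = as.numeric(areaRange),
      noiseFactorRange = as.numeric(noiseFactorRange),
      noiseOff = isTRUE(noiseOff), nSpectra = as.integer(nSpectra),
      seed = as.integer(seed))
}

#' Construct a network configuration
#'
#' Defaults are the production architecture and training recipe; see
#' \linkS4class{AnnConfig}. Any field can be overridden for scaled-down
#' experiments.
#'
#' @param inputLength spectrum length in points
#' @param outputNodes number of predicted component areas (K)
#' @param kernelSize,strides,nFilters convolution geometry
#' @param convType "locally_connected" or "shared"
#' @param batchSize minibatch size
#' @param awgnStd train-time input noise sd (normalised units)
#' @param lrInitial initial learning rate
#' @param lrSchedule named numeric vector, new rate keyed by epoch
#' @param epochs training epochs
#' @param adamBeta1,adamBeta2 Adam moment decays
#' @param splitRatio training fraction of the train/validation split
#' @param seed integer seed controlling split, init, shuffles and AWGN
#' @return an \linkS4class{AnnConfig}
#' @export
AnnConfig <- function(inputLength = 1692L, outputNodes = 4L,
                      kernelSize = 9L, strides = 9L, nFilters = 4L,
                      convType = "locally_connected", batchSize = 1024L,
                      awgnStd = 0.04, lrInitial = 1e-4,
                      lrSchedule = c("170" = 3e-5, "240" = 1e-5),
                      epochs = 400L, adamBeta1 = 0.9, adamBeta2 = 0.999,
                      splitRatio = 0.95, seed = 1L) {
  new("AnnConfig", inputLength = as.integer(inputLength),
      kernelSize = as.integer(kernelSize), strides = as.integer(strides),
      nFilters = as.integer(nFilters), convType = convType,
      outputNodes = as.integer(outputNodes),
      batchSize = as.integer(batchSize), awgnStd = as.numeric(awgnStd),
      lrInitial = as.numeric(lrInitial), lrSchedule = lrSchedule,
      epochs = as.integer(epochs), adamBeta1 = as.numeric(adamBeta1),
      adamBeta2 = as.numeric(adamBeta2), splitRatio = as.numeric(splitRatio),
      seed = as.integer(seed))
}

#' Construct a time-series table
#'
#' @param time timestamps in hours, strictly increasing
#' @param values matrix or data.frame, one column per component
#' @param source label of the producing analyzer
#' @return a \linkS4class{TimeSeriesTable}
#' @export
TimeSeriesTable <- function(time, values, source = "") {
  values <- as.matrix(values)
  new("TimeSeriesTable", time = as.numeric(time), values = values,
      source = source)
}
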