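#' @import methods
NULL

#' Uniform chemical-shift axis
#'
#' A uniform grid of chemical shifts (ppm) together with the proton
#' frequency of the spectrometer, which fixes the ppm-to-Hz conversion
#' (1 ppm = \code{spectrometerFreq} Hz at \code{spectrometerFreq} MHz).
#' The default window, 5.6 to 9.0 ppm at 43.3 MHz, is the aromatic
#' region a benchtop spectrometer resolves well enough for quantitative
#' work.
#'
#' @slot ppmStart lower end of the axis (ppm)
#' @slot ppmEnd upper end of the axis (ppm)
#' @slot nPoints number of grid points (>= 2)
#' @slot spectrometerFreq proton frequency in MHz
#' @exportClass SpectralGrid
setClass("SpectralGrid",
  representation(ppmStart = "numeric", ppmEnd = "numeric",
                 nPoints = "integer", spectrometerFreq = "numeric"),
  prototype(ppmStart = 5.6, ppmEnd = 9.0, nPoints = 1692L,
            spectrometerFreq = 43.3))

setValidity("SpectralGrid", function(object) {
  msg <- character()
  if (length(object@nPoints) != 1L || object@nPoints < 2L)
    msg <- c(msg, "nPoints must be a single integer >= 2")
  if (!(object@ppmStart < object@ppmEnd))
    msg <- c(msg, "ppmStart must be < ppmEnd")
  if (object@spectrometerFreq <= 0)
    msg <- c(msg, "spectrometerFreq must be positive (MHz)")
  if (length(msg)) msg else TRUE
})

#' Intensity vector on a spectral grid
#'
#' A frequency-domain 1-D spectrum: finite intensities (a.u.) on a
#' \linkS4class{SpectralGrid}, plus free-form provenance metadata.
#' The axis is stored ascending in ppm; readers flip descending input.
#'
#' @slot grid a \linkS4class{SpectralGrid}
#' @slot intensity numeric vector, length \code{nPoints(grid)}
#' @slot meta named list of provenance
#' @exportClass Spectrum
setClass("Spectrum",
  representation(grid = "SpectralGrid", intensity = "numeric",
                 meta = "list"),
  prototype(meta = list()))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@intensity) != object@grid@nPoints)
    msg <- c(msg, "intensity length must equal grid nPoints")
  if (anyNA(object@intensity) || any(!is.finite(object@intensity)))
    msg <- c(msg, "intensity must be finite")
  if (length(msg)) msg else TRUE
})

#' Pure-component peak model
#'
#' A named set of pseudo-Voigt peaks describing one chemical species.
#' Peaks are stored as a data.frame with columns \code{omega} (position,
#' ppm), \code{alpha} (height, a.u.), \code{gamma} (half width at half
#' maximum, ppm), \code{beta} (Lorentzian weight in [0,1]) and
#' \code{group} (integer id). Neighbouring peaks share a group when
#' their positions chain within \code{deltaNu} ppm; every peak of a
#' group feels one common group-shift parameter during simulation.
#'
#' @slot name component label
#' @slot peaks data.frame of peak parameters, sorted by omega
#' @slot deltaNu grouping threshold in ppm (default 0.12)
#' @exportClass PureComponentModel
setClass("PureComponentModel",
  representation(name = "character", peaks = "data.frame",
                 deltaNu = "numeric"),
  prototype(deltaNu = 0.12))

.peakCols <- c("omega", "alpha", "gamma", "beta", "group")

setValidity("PureComponentModel", function(object) {
  p <- object@peaks
  msg <- character()
  if (!all(.peakCols %in% names(p)))
    return(paste("peaks must have columns", paste(.peakCols, collapse = ", ")))
  if (nrow(p) == 0L) msg <- c(msg, "at least one peak required")
  if (is.unsorted(p$omega)) msg <- c(msg, "peaks must be sorted by omega")
  if (any(p$alpha < 0)) msg <- c(msg, "alpha must be >= 0")
  if (any(p$gamma <= 0)) msg <- c(msg, "gamma must be > 0")
  if (any(p$beta < 0 | p$beta > 1)) msg <- c(msg, "beta must lie in [0,1]")
  g <- sort(unique(p$group))
  if (nrow(p) && !identical(as.integer(g), seq(0L, length(g) - 1L)))
    msg <- c(msg, "group ids must be contiguous 0..nGroups-1")
  if (length(msg)) msg else TRUE
})

#' Parametric mixture model
#'
#' An ordered list of \linkS4class{PureComponentModel}s with unique
#' names; the spectrum of a mixture is the weighted sum of the
#' component models after their shift/broadening perturbations.
#'
#' @slot components list of \linkS4class{PureComponentModel}
#' @exportClass MixtureModel
setClass("MixtureModel", representation(components = "list"))

setValidity("MixtureModel", function(object) {
  msg <- character()
  if (length(object@components) < 1L)
    msg <- c(msg, "at least one component required")
  ok <- vapply(object@components, is, logical(1), "PureComponentModel")
  if (!all(ok)) msg <- c(msg, "all components must be PureComponentModel")
  nm <- vapply(object@components, function(x) x@name, character(1))
  if (anyDuplicated(nm)) msg <- c(msg, "component names must be unique")
  if (length(msg)) msg else TRUE
})

#' Perturbation parameters of one mixture realisation
#'
#' Holds, per component, the weight w_k, the component shift (ppm) and
#' the width multiplier; per group, a group shift (ppm); and per peak,
#' an independent position jitter (ppm). The effective position of a
#' peak is omega + jitter + groupShift[group] + componentShift; the
#' effective width is gamma * peakBroadening.
#'
#' @slot weights non-negative per-component scale factors
#' @slot componentShift per-component shift (ppm)
#' @slot groupShift list of per-group shift vectors (ppm), one per component
#' @slot peakBroadening per-component width multiplier (> 0)
#' @slot peakJitter list of per-peak position perturbations (ppm)
#' @exportClass MixtureParams
setClass("MixtureParams",
  representation(weights = "numeric", componentShift = "numeric",
                 groupShift = "list", peakBroadening = "numeric",
                 peakJitter = "list"))

setValidity("MixtureParams", function(object) {
  K <- length(object@weights)
  msg <- character()
  if (length(object@componentShift) != K ||
      length(object@groupShift) != K ||
      length(object@peakBroadening) != K ||
      length(object@peakJitter) != K)
    msg <- c(msg, "all parameter slots must have one entry per component")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
  if (any(object@peakBroadening <= 0))
    msg <- c(msg, "peakBroadening must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of a nonlinear least-squares fit
#'
#' @slot model the fitted object (a \linkS4class{PureComponentModel} or
#'   \linkS4class{MixtureParams})
#' @slot residualNorm L2 norm of the final residual (a.u.)
#' @slot converged logical; FALSE flags non-convergence, never an error
#' @slot nIterations optimizer iterations used
#' @slot diagnostics free-form list (optimizer message, objective trace)
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "ANY", residualNorm = "numeric",
                 converged = "logical", nIterations = "integer",
                 diagnostics = "list"),
  prototype(diagnostics = list()))

setValidity("FitResult", function(object) {
  if (length(object@residualNorm) != 1L || object@residualNorm < 0)
    "residualNorm must be a single non-negative number" else TRUE
})

#' Labelled synthetic training set
#'
#' Row i of \code{spectra} is one synthetic mixture spectrum; row i of
#' \code{labels} holds the per-component areas that generated it (the
#' regression targets, proportional to concentration). \code{paramsLog}
#' records every sampled parameter so a build is auditable, and
#' regeneration from the same config and seed is bit-identical.
#'
#' @slot spectra n x nPoints matrix (a.u.)
#' @slot labels n x K matrix of areas (a.u.)
#' @slot paramsLog data.frame of the sampled parameters per spectrum
#' @slot grid the shared \linkS4class{SpectralGrid}
#' @slot seed integer seed the build used
#' @exportClass LabeledDataset
setClass("LabeledDataset",
  representation(spectra = "matrix", labels = "matrix",
                 paramsLog = "data.frame", grid = "SpectralGrid",
                 seed = "integer"))

setValidity("LabeledDataset", function(object) {
  msg <- character()
  if (nrow(object@spectra) != nrow(object@labels))
    msg <- c(msg, "spectra and labels must have equal row counts")
  if (ncol(object@spectra) != object@grid@nPoints)
    msg <- c(msg, "spectra columns must match grid nPoints")
  if (any(object@labels < 0)) msg <- c(msg, "labels must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Empirical baseline-noise pool
#'
#' Intensity values harvested from signal-free baseline regions of a
#' measured, baseline-corrected spectrum. Synthetic spectra draw their
#' noise from this pool (resampling with replacement), so the noise
#' statistics are those of the real instrument rather than an assumed
#' distribution.
#'
#' @slot samples numeric vector of baseline intensities (a.u.)
#' @slot sourceRegions 2-column matrix of ppm intervals the samples came from
#' @exportClass NoisePool
setClass("NoisePool",
  representation(samples = "numeric", sourceRegions = "matrix"))

setValidity("NoisePool", function(object) {
  msg <- character()
  if (length(object@samples) == 0L) msg <- c(msg, "pool must be non-empty")
  s <- stats::sd(object@samples)
  if (length(object@samples) > 1L && is.finite(s) && s > 0 &&
      abs(mean(object@samples)) >= 0.1 * s)
    msg <- c(msg, "pool mean must be ~0 (|mean| < 0.1 sd); baseline-correct first")
  if (length(msg)) msg else TRUE
})

#' Configuration for the pure-spectrum dataset generator
#'
#' Ranges for the dataset built from altered measured pure-component
#' spectra: per component a target area (uniform), a line-broadening
#' factor (uniform over a discrete Hz set) and a component shift
#' (uniform, symmetric). Defaults: area 0-180 a.u., broadening
#' {0.2, 0.5, 0.8, 1.0, 1.5} Hz, shift +/-0.015 ppm, 300,000 spectra.
#'
#' @slot areaRange length-2 numeric, a.u.
#' @slot lineBroadeningSet discrete Hz values
#' @slot componentShiftRange half-width of the symmetric shift range (ppm)
#' @slot nSpectra number of spectra to generate
#' @slot seed integer RNG seed
#' @exportClass XiConfig
setClass("XiConfig",
  representation(areaRange = "numeric", lineBroadeningSet = "numeric",
                 componentShiftRange = "numeric", nSpectra = "integer",
                 seed = "integer"),
  prototype(areaRange = c(0, 180),
            lineBroadeningSet = c(0.2, 0.5, 0.8, 1.0, 1.5),
            componentShiftRange = 0.015, nSpectra = 300000L, seed = 1L))

#' Configuration for the spectral-model dataset generator
#'
#' Ranges for the dataset built from the parametric mixture model.
#' All signed ranges are symmetric uniform U(-r, +r). Defaults:
#' peak jitter +/-0.005 ppm, component shift +/-0.015 ppm, group shift
#' +/-0.01 ppm, peak broadening +/-15%, area 0-180 a.u., noise factor
#' +/-15%, 300,000 spectra.
#'
#' @slot peakJitterRange half-width, ppm
#' @slot componentShiftRange half-width, ppm
#' @slot groupShiftRange half-width, ppm
#' @slot broadeningRange half-width as a fraction (0.15 = +/-15\%)
#' @slot areaRange length-2 numeric, a.u.
#' @slot noiseFactorRange half-width as a fraction of noise amplitude
#' @slot noiseOff logical; TRUE builds noise-free spectra
#' @slot nSpectra number of spectra to generate
#' @slot seed integer RNG seed
#' @exportClass XiiConfig
setClass("XiiConfig",
  representation(peakJitterRange = "numeric", componentShiftRange = "numeric",
                 groupShiftRange = "numeric", broadeningRange = "numeric",
                 areaRange = "numeric", noiseFactorRange = "numeric",
                 noiseOff = "logical", nSpectra = "integer", seed = "integer"),
  prototype(peakJitterRange = 0.005, componentShiftRange = 0.015,
            groupShiftRange = 0.01, broadeningRange = 0.15,
            areaRange = c(0, 180), noiseFactorRange = 0.15,
            noiseOff = FALSE, nSpectra = 300000L, seed = 1L))

#' Architecture and training configuration of the area-regression CNN
#'
#' The production network is a single locally-connected 1-D
#' convolutional layer (kernel 9, stride 9, 4 filters, no weight
#' sharing across positions, ELU activation) flattened into a K-node
#' ReLU output; on a 1692-point input with K = 4 this has 10,532
#' trainable parameters. Training uses MSE loss, Adam
#' (beta1 = 0.9, beta2 = 0.999), batch size 1024, additive white
#' Gaussian noise of sd 0.04 on the normalised inputs (train time
#' only), and a step learning-rate schedule 1e-4 -> 3e-5 (epoch 170)
#' -> 1e-5 (epoch 240) over 400 epochs.
#'
#' @slot inputLength spectrum length in points
#' @slot kernelSize convolution kernel size
#' @slot strides convolution stride
#' @slot nFilters number of filters per position
#' @slot convType "locally_connected" (default) or "shared" (ordinary conv)
#' @slot outputNodes K, number of predicted component areas
#' @slot batchSize minibatch size
#' @slot awgnStd sd of train-time additive white Gaussian noise
#'   (normalised units)
#' @slot lrInitial initial Adam learning rate
#' @slot lrSchedule named numeric: new learning rate keyed by epoch
#' @slot epochs training epochs
#' @slot adamBeta1,adamBeta2 Adam moment decay rates
#' @slot splitRatio training fraction of the train/validation split
#' @slot seed integer seed for split, init, shuffling and AWGN
#' @exportClass AnnConfig
setClass("AnnConfig",
  representation(inputLength = "integer", kernelSize = "integer",
                 strides = "integer", nFilters = "integer",
                 convType = "character", outputNodes = "integer",
                 batchSize = "integer", awgnStd = "numeric",
                 lrInitial = "numeric", lrSchedule = "numeric",
                 epochs = "integer", adamBeta1 = "numeric",
                 adamBeta2 = "numeric", splitRatio = "numeric",
                 seed = "integer"),
  prototype(inputLength = 1692L, kernelSize = 9L, strides = 9L,
            nFilters = 4L, convType = "locally_connected",
            outputNodes = 4L, batchSize = 1024L, awgnStd = 0.04,
            lrInitial = 1e-4, lrSchedule = c("170" = 3e-5, "240" = 1e-5),
            epochs = 400L, adamBeta1 = 0.9, adamBeta2 = 0.999,
            splitRatio = 0.95, seed = 1L))

setValidity("AnnConfig", function(object) {
  msg <- character()
  if (object@kernelSize > object@inputLength)
    msg <- c(msg, "kernelSize must be <= inputLength")
  if (object@strides < 1L) msg <- c(msg, "strides must be >= 1")
  if (!object@convType %in% c("locally_connected", "shared"))
    msg <- c(msg, "convType must be 'locally_connected' or 'shared'")
  if (object@lrInitial <= 0 || any(object@lrSchedule <= 0))
    msg <- c(msg, "learning rates must be > 0")
  if (object@splitRatio <= 0 || object@splitRatio >= 1)
    msg <- c(msg, "splitRatio must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' A trained area-regression network
#'
#' Weights plus the two normalisation scalars recorded at training
#' time: inputs are divided by \code{xScale} = max of the training
#' spectra and predictions are multiplied back by \code{yScale} = max
#' of the training areas, so the network operates entirely in [0,1]
#' while the user sees areas in a.u. \code{history} holds one row per
#' completed epoch (train loss, validation loss, learning rate, and
#' the MSE against an external reference set when one was supplied).
#'
#' @slot config the \linkS4class{AnnConfig} used
#' @slot weights list of weight arrays
#' @slot xScale,yScale normalisation scalars (a.u.)
#' @slot history per-epoch training record (data.frame)
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(config = "AnnConfig", weights = "list",
                 xScale = "numeric", yScale = "numeric",
                 history = "data.frame"),
  prototype(xScale = 1, yScale = 1, history = data.frame()))

#' Time-stamped multi-component concentration (or area) series
#'
#' @slot time numeric, strictly increasing timestamps in hours
#' @slot values matrix, one column per component (mol/L or a.u.)
#' @slot source label of the producing analyzer
#' @exportClass TimeSeriesTable
setClass("TimeSeriesTable",
  representation(time = "numeric", values = "matrix", source = "character"),
  prototype(source = ""))

setValidity("TimeSeriesTable", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@time))
    msg <- c(msg, "values must have one row per timestamp")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (anyNA(object@values)) msg <- c(msg, "values must be complete")
  if (length(msg)) msg else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "SpectralGrid", function(object) {
  cat(sprintf("SpectralGrid: %.4g..%.4g ppm, %d points (d = %.5g ppm), %.4g MHz\n",
              object@ppmStart, object@ppmEnd, object@nPoints,
              (object@ppmEnd - object@ppmStart) / (object@nPoints - 1L),
              object@spectrometerFreq))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.4g..%.4g ppm, max %.4g a.u.\n",
              object@grid@nPoints, object@grid@ppmStart, object@grid@ppmEnd,
              max(object@intensity)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "PureComponentModel", function(object) {
  cat(sprintf("PureComponentModel '%s': %d peaks in %d groups (deltaNu = %g ppm)\n",
              object@name, nrow(object@peaks),
              length(unique(object@peaks$group)), object@deltaNu))
})

setMethod("show", "MixtureModel", function(object) {
  nm <- vapply(object@components, function(x) x@name, character(1))
  cat(sprintf("MixtureModel: %d components (%s)\n",
              length(nm), paste(nm, collapse = ", ")))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: residualNorm = %.4g, %s after %d iterations\n",
              object@residualNorm,
              if (object@converged) "converged" else "NOT converged",
              object@nIterations))
})

setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf("LabeledDataset: %d spectra x %d points, %d components, seed %d\n",
              nrow(object@spectra), ncol(object@spectra),
              ncol(object@labels), object@seed))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s conv, input %d, %d outputs, %d parameters\n",
              object@config@convType, object@config@inputLength,
              object@config@outputNodes, countParams(object@config)))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, final train loss %.4g\n",
                nrow(object@history),
                object@history$train_loss[nrow(object@history)]))
})

setMethod("show", "TimeSeriesTable", function(object) {
  cat(sprintf("TimeSeriesTable '%s': %d rows x %d components, %.3g..%.3g h\n",
              object@source, length(object@time), ncol(object@values),
              if (length(object@time)) min(object@time) else NA,
              if (length(object@time)) max(object@time) else NA))
})
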