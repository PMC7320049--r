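#' @include AllGenerics.R
NULL

# FNV-1a hash of a character string, returned as 8 hex digits; used to
# stamp bundles with a config fingerprint. Arithmetic is kept inside
# the exact-double range by splitting the 32-bit state into 16-bit
# halves for the modular multiply, and the byte xor touches only the
# low byte (the input bytes are < 256).
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.configHash <- function(obj) {
  sl <- lapply(slotNames(class(obj)), function(s) slot(obj, s))
  names(sl) <- slotNames(class(obj))
  .fnv1a(jsonlite::toJSON(sl, auto_unbox = TRUE, digits = NA))
}

#' Read a spectrum from two-column text
#'
#' Expects whitespace- or comma-separated lines of (ppm, intensity);
#' lines starting with \code{#} are comments. A descending ppm axis
#' (the common display order) is accepted and flipped to the internal
#' ascending representation. The axis must be uniform.
#'
#' @param path file path
#' @param spectrometerFreq proton frequency in MHz to attach to the grid
#' @return a \linkS4class{Spectrum}
#' @export
readSpectrum <- function(path, spectrometerFreq = 43.3) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("malformed spectrum file (fewer than 2 data lines): ", path)
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop(sprintf("malformed spectrum file %s at data line %d", path, bad[1]))
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric value in spectrum file: ", path)
  if (m[1, 1] > m[nrow(m), 1]) m <- m[nrow(m):1, , drop = FALSE]
  d <- diff(m[, 1])
  if (any(d <= 0) || diff(range(d)) > 1e-6 * mean(d))
    stop("ppm axis must be uniform and strictly monotonic: ", path)
  grid <- SpectralGrid(m[1, 1], m[nrow(m), 1], nrow(m), spectrometerFreq)
  Spectrum(grid, m[, 2], meta = list(path = path))
}

#' Write a spectrum as two-column text
#'
#' @param spectrum a \linkS4class{Spectrum}
#' @param path output file path
#' @param descending write in display order (high to low ppm)
#' @return \code{path}, invisibly
#' @export
writeSpectrum <- function(spectrum, path, descending = FALSE) {
  nu <- ppmAxis(spectrum)
  y <- spectrum@intensity
  if (descending) { nu <- rev(nu); y <- rev(y) }
  utils::write.table(
    data.frame(ppm = sprintf("%.17g", nu), intensity = sprintf("%.17g", y)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pure-component peak model from JSON
#'
#' Schema: \code{{name, delta_nu, peaks: [{omega, alpha, gamma, beta,
#' group}, ...]}}. Round-trips losslessly with
#' \code{\link{writePeakModel}}.
#'
#' @param path JSON file path
#' @return a \linkS4class{PureComponentModel}
#' @export
readPeakModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$name) || is.null(doc$peaks))
    stop("peak-model JSON must have 'name' and 'peaks': ", path)
  PureComponentModel(doc$name, as.data.frame(doc$peaks),
                     deltaNu = if (is.null(doc$delta_nu)) 0.12 else doc$delta_nu)
}

#' Write a pure-component peak model as JSON
#'
#' @param model a \linkS4class{PureComponentModel}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writePeakModel <- function(model, path) {
  doc <- list(name = model@name, delta_nu = model@deltaNu,
              peaks = model@peaks)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a labelled dataset bundle
#'
#' A bundle is a directory of plain-text files: \code{spectra.tsv}
#' and \code{labels.tsv} (tab-separated matrices), \code{params.tsv}
#' (the sampled-parameter log with a header), \code{grid.json} and
#' \code{meta.json} (seed and a hash of the grid for integrity).
#'
#' @param dataset a \linkS4class{LabeledDataset}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeBundle <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset@spectra, file.path(dir, "spectra.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset@labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset@paramsLog, file.path(dir, "params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g <- dataset@grid
  jsonlite::write_json(
    list(ppm_start = g@ppmStart, ppm_end = g@ppmEnd,
         n_points = g@nPoints, spectrometer_freq = g@spectrometerFreq),
    file.path(dir, "grid.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = dataset@seed, grid_hash = .configHash(g),
         n_spectra = nrow(dataset@spectra)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a labelled dataset bundle
#'
#' @param dir bundle directory written by \code{\link{writeBundle}}
#' @return a \linkS4class{LabeledDataset}
#' @export
readBundle <- function(dir) {
  need <- c("spectra.tsv", "labels.tsv", "params.tsv", "grid.json",
            "meta.json")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop("bundle incomplete, missing: ",
                         paste(miss, collapse = ", "))
  g <- jsonlite::fromJSON(file.path(dir, "grid.json"))
  grid <- SpectralGrid(g$ppm_start, g$ppm_end, g$n_points,
                       g$spectrometer_freq)
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  X <- as.matrix(utils::read.table(file.path(dir, "spectra.tsv"),
                                   sep = "\t", header = FALSE))
  dimnames(X) <- NULL
  A <- as.matrix(utils::read.table(file.path(dir, "labels.tsv"),
                                   sep = "\t", header = TRUE))
  P <- utils::read.table(file.path(dir, "params.tsv"), sep = "\t",
                         header = TRUE)
  new("LabeledDataset", spectra = X, labels = A, paramsLog = P,
      grid = grid, seed = as.integer(meta$seed))
}

#' Save / load a trained model as plain text
#'
#' The model directory holds the weights (one TSV per array), the
#' configuration and the normalisation scalars (JSON), and the
#' training history (CSV).
#'
#' @param model a \linkS4class{TrainedModel}
#' @param dir output directory
#' @return \code{dir}, invisibly
#' @export
writeModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- model@weights
  utils::write.table(matrix(as.vector(w$Wc), ncol = 1),
                     file.path(dir, "Wc.tsv"), row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(matrix(as.vector(w$bc), ncol = 1),
                     file.path(dir, "bc.tsv"), row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(w$Wd, file.path(dir, "Wd.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(matrix(w$bd, ncol = 1), file.path(dir, "bd.tsv"),
                     row.names = FALSE, col.names = FALSE)
  cfg <- model@config
  sl <- lapply(slotNames("AnnConfig"), function(s) slot(cfg, s))
  names(sl) <- slotNames("AnnConfig")
  jsonlite::write_json(c(sl, list(x_scale = model@xScale,
                                  y_scale = model@yScale)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(model@history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname writeModel
#' @param dir model directory written by \code{writeModel}
#' @return \code{readModel}: the reconstructed \linkS4class{TrainedModel}
#' @export
readModel <- function(dir) {
  cj <- jsonlite::fromJSON(file.path(dir, "config.json"))
  sched <- unlist(cj$lrSchedule)
  if (is.null(sched)) sched <- stats::setNames(numeric(0), character(0))
  config <- AnnConfig(inputLength = cj$inputLength,
                      outputNodes = cj$outputNodes,
                      kernelSize = cj$kernelSize, strides = cj$strides,
                      nFilters = cj$nFilters, convType = cj$convType,
                      batchSize = cj$batchSize, awgnStd = cj$awgnStd,
                      lrInitial = cj$lrInitial, lrSchedule = sched,
                      epochs = cj$epochs, adamBeta1 = cj$adamBeta1,
                      adamBeta2 = cj$adamBeta2,
                      splitRatio = cj$splitRatio, seed = cj$seed)
  P <- .nPositions(config)
  k <- config@kernelSize; F <- config@nFilters; K <- config@outputNodes
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f),
                                                sep = "\t", header = FALSE))
  Wc <- if (config@convType == "locally_connected")
    array(rd("Wc.tsv")[, 1], dim = c(k, F, P)) else
    matrix(rd("Wc.tsv")[, 1], k, F)
  bc <- if (config@convType == "locally_connected")
    matrix(rd("bc.tsv")[, 1], P, F) else rd("bc.tsv")[, 1]
  Wd <- rd("Wd.tsv"); dimnames(Wd) <- NULL
  bd <- rd("bd.tsv")[, 1]
  hist <- utils::read.csv(file.path(dir, "history.csv"))
  new("TrainedModel", config = config,
      weights = list(Wc = Wc, bc = bc, Wd = Wd, bd = bd),
      xScale = cj$x_scale, yScale = cj$y_scale, history = hist)
}

#' Read / write a time-series table as CSV
#'
#' CSV schema: first column \code{time_h}, remaining columns one per
#' component.
#'
#' @param path CSV file path
#' @param source label for the table
#' @return a \linkS4class{TimeSeriesTable}
#' @export
readTimeSeries <- function(path, source = basename(path)) {
  d <- utils::read.csv(path)
  if (names(d)[1] != "time_h")
    stop("first column must be 'time_h': ", path)
  TimeSeriesTable(d$time_h, as.matrix(d[, -1, drop = FALSE]),
                  source = source)
}

#' @rdname readTimeSeries
#' @param table a \linkS4class{TimeSeriesTable}
#' @export
writeTimeSeries <- function(table, path) {
  d <- data.frame(time_h = table@time)
  d <- cbind(d, as.data.frame(table@values))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
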