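#' @include AllGenerics.R
NULL

#' Pair two analyzer time series by nearest timestamp
#'
#' Two spectrometers monitoring the same stream never sample at the
#' same instants; each row of the target series is paired with the
#' reference row of minimal absolute time difference. An exact
#' midpoint tie goes to the earlier reference row.
#'
#' @param target a \linkS4class{TimeSeriesTable} (e.g. the low-field
#'   series whose timestamps are kept)
#' @param reference a \linkS4class{TimeSeriesTable} to draw matches from
#' @return data.frame with the target time, target values (prefixed
#'   \code{lf_}), matched reference values (prefixed \code{hf_}) and
#'   the matched reference row index \code{ref_idx}
#' @export
matchNearest <- function(target, reference) {
  if (length(reference@time) == 0L) stop("reference series is empty")
  if (length(target@time) == 0L) stop("target series is empty")
  idx <- vapply(target@time, function(t) {
    d <- abs(reference@time - t)
    which(d == min(d))[1L]        # tie -> earlier row
  }, integer(1))
  lf <- as.data.frame(target@values)
  names(lf) <- paste0("lf_", colnames(target@values))
  hf <- as.data.frame(reference@values[idx, , drop = FALSE])
  names(hf) <- paste0("hf_", colnames(reference@values))
  rownames(hf) <- NULL
  cbind(data.frame(time = target@time), lf, hf,
        data.frame(ref_idx = idx))
}

#' Flag steady-state points of a concentration series
#'
#' Slides a centred window of \code{window} consecutive points over
#' the series; in each window and for each component an ordinary
#' least-squares line against the true timestamps is fitted. The
#' window is steady iff, for every component, the absolute slope is
#' below \code{slopeMax} (mol/h) and the spread of the points around
#' the fitted line is below \code{stdMax} (mol/L). The mask marks the
#' centre point of every steady window (set \code{markAll} to flag
#' all its points instead). Spread is the residual standard deviation
#' about the fitted line by default; \code{rawStd} switches to the
#' plain standard deviation of the points.
#'
#' @param series a \linkS4class{TimeSeriesTable} with time in hours
#' @param window odd window length (default 11)
#' @param slopeMax slope threshold, mol/h
#' @param stdMax spread threshold, mol/L
#' @param markAll mark every point of a steady window, not just the centre
#' @param rawStd use the raw sd of the window instead of residual sd
#' @return logical vector, one entry per series row
#' @export
steadyStateMask <- function(series, window = 11L, slopeMax = 0.1,
                            stdMax = 0.01, markAll = FALSE,
                            rawStd = FALSE) {
  n <- length(series@time)
  if (window %% 2L != 1L) stop("window must be odd")
  if (n < window) {
    warning("series shorter than the window; returning all-FALSE mask")
    return(rep(FALSE, n))
  }
  half <- (window - 1L) %/% 2L
  mask <- rep(FALSE, n)
  for (c0 in seq.int(half + 1L, n - half)) {
    rows <- (c0 - half):(c0 + half)
    t <- series@time[rows]
    ok <- TRUE
    for (j in seq_len(ncol(series@values))) {
      y <- series@values[rows, j]
      ft <- stats::lm.fit(cbind(1, t), y)
      slope <- ft$coefficients[2]
      spread <- if (rawStd) stats::sd(y)
                else sqrt(sum(ft$residuals^2) / (window - 2L))
      if (!(abs(slope) < slopeMax && spread < stdMax)) { ok <- FALSE; break }
    }
    if (ok) {
      if (markAll) mask[rows] <- TRUE else mask[c0] <- TRUE
    }
  }
  mask
}

#' Drop pairs where the two analyzers disagree
#'
#' Removes rows of a paired table in which any component's absolute
#' difference between the reference (\code{hf_}) and target
#' (\code{lf_}) reading exceeds \code{maxDev}. The comparison is
#' strict: a deviation of exactly \code{maxDev} is kept.
#'
#' @param pairs data.frame from \code{\link{matchNearest}}
#' @param maxDev deviation threshold, mol/L (default 0.04)
#' @return the filtered data.frame
#' @export
removeOutliers <- function(pairs, maxDev = 0.04) {
  lf <- as.matrix(pairs[, grep("^lf_", names(pairs)), drop = FALSE])
  hf <- as.matrix(pairs[, grep("^hf_", names(pairs)), drop = FALSE])
  if (ncol(lf) != ncol(hf)) stop("paired table has mismatched lf_/hf_ columns")
  keep <- apply(abs(hf - lf) <= maxDev, 1L, all)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kennard-Stone uniform subset selection
#'
#' The classic deterministic design algorithm: start with the two
#' points at maximal Euclidean distance, then repeatedly add the
#' candidate whose minimal distance to the already-selected set is
#' largest, until \code{k} points are chosen. The result covers the
#' point cloud uniformly and is a prefix chain: the first \code{k}
#' picks of a \code{k+1} selection equal the \code{k}-selection.
#' Distance ties break to the lowest row index.
#'
#' @param points n x d numeric matrix (rows are samples)
#' @param k number of samples to select (2 <= k <= n; k = 1 returns
#'   the first point of the maximal pair)
#' @param scale min-max scale each column to [0,1] before computing
#'   distances
#' @return integer vector of selected row indices, in selection order
#' @export
kennardStoneSelect <- function(points, k, scale = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k must be <= the number of points")
  if (k < 1L) stop("k must be >= 1")
  if (scale) {
    rng <- apply(points, 2, range)
    den <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
    points <- sweep(sweep(points, 2, rng[1, ]), 2, den, "/")
  }
  D <- as.matrix(stats::dist(points))
  # farthest pair, ties to lowest (i, j)
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[order(pmin(far[, 1], far[, 2]), pmax(far[, 1], far[, 2])), ,
             drop = FALSE]
  sel <- sort(c(far[1, 1], far[1, 2]))[seq_len(min(k, 2L))]
  if (k <= 2L) return(sel)
  rest <- setdiff(seq_len(n), sel)
  minD <- apply(D[rest, sel, drop = FALSE], 1L, min)
  while (length(sel) < k) {
    pick <- which(minD == max(minD))[1L]   # tie -> lowest index in rest
    sel <- c(sel, rest[pick])
    newD <- D[rest, rest[pick]]
    rest <- rest[-pick]
    minD <- pmin(minD, newD)[-pick]
  }
  sel
}

#' Run the full reference-curation pipeline
#'
#' Convenience wrapper chaining the four curation steps: nearest-
#' timestamp pairing, steady-state filtering on the target series,
#' analyzer-disagreement outlier removal, and Kennard-Stone selection
#' of \code{select} uniformly covering samples (on the reference
#' component vectors).
#'
#' @param target,reference \linkS4class{TimeSeriesTable}s (target
#'   timestamps are kept)
#' @param window,slopeMax,stdMax steady-state parameters, see
#'   \code{\link{steadyStateMask}}
#' @param maxDev outlier threshold, see \code{\link{removeOutliers}}
#' @param select number of samples to keep; NULL (or more than
#'   available) keeps all
#' @return the curated data.frame of paired rows
#' @export
curateReference <- function(target, reference, window = 11L,
                            slopeMax = 0.1, stdMax = 0.01,
                            maxDev = 0.04, select = 300L) {
  pairs <- matchNearest(target, reference)
  mask <- steadyStateMask(target, window = window,
                          slopeMax = slopeMax, stdMax = stdMax)
  pairs <- pairs[mask, , drop = FALSE]
  pairs <- removeOutliers(pairs, maxDev = maxDev)
  if (!is.null(select) && nrow(pairs) > select) {
    hf <- as.matrix(pairs[, grep("^hf_", names(pairs)), drop = FALSE])
    pairs <- pairs[sort(kennardStoneSelect(hf, select)), , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}
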