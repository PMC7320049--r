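#' @include AllGenerics.R
NULL

# number of convolution output positions
.nPositions <- function(config)
  (config@inputLength - config@kernelSize) %/% config@strides + 1L

# column indices of the input window feeding each output position
.patchIndex <- function(config) {
  P <- .nPositions(config)
  vapply(seq_len(P), function(p)
    (p - 1L) * config@strides + seq_len(config@kernelSize),
    integer(config@kernelSize))            # kernelSize x P
}

#' Closed-form trainable-parameter count
#'
#' For the locally-connected variant every output position owns its
#' kernel and bias, giving \eqn{P F (k+1)} convolution parameters plus
#' \eqn{P F K + K} for the dense output, with
#' \eqn{P = \lfloor (L-k)/s \rfloor + 1}. The shared-weight variant
#' needs only \eqn{F(k+1)} for the convolution. The production
#' geometry (L = 1692, k = s = 9, F = 4, K = 4) gives P = 188 and
#' 10,532 parameters.
#'
#' @param config an \linkS4class{AnnConfig}
#' @return integer parameter count
#' @examples
#' countParams(AnnConfig())   # 10532
#' @export
countParams <- function(config) {
  P <- .nPositions(config)
  F <- config@nFilters; k <- config@kernelSize; K <- config@outputNodes
  conv <- if (config@convType == "locally_connected")
    P * F * (k + 1L) else F * (k + 1L)
  as.integer(conv + P * F * K + K)
}

# Glorot-uniform draw
.glorot <- function(nr, nc, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained area-regression network
#'
#' Architecture: one 1-D convolutional layer (locally connected by
#' default: every output position has its own kernel and bias, no
#' weight sharing along the axis) with ELU activation, flattened and
#' fully connected to a K-node output with ReLU activation, so
#' predicted areas are never negative. Weights are Glorot-uniform
#' initialised from the seeded RNG state.
#'
#' @param config an \linkS4class{AnnConfig}
#' @param seedInit set the RNG to \code{config@seed} before
#'   initialising (FALSE inside the training pipeline, which manages
#'   one RNG stream itself)
#' @return an untrained \linkS4class{TrainedModel}
#' @export
buildAnn <- function(config, seedInit = TRUE) {
  validObject(config)
  if (seedInit) set.seed(config@seed)
  P <- .nPositions(config)
  k <- config@kernelSize; F <- config@nFilters; K <- config@outputNodes
  if (config@convType == "locally_connected") {
    Wc <- array(0, dim = c(k, F, P))
    for (p in seq_len(P)) Wc[, , p] <- .glorot(k, F, k, F)
    bc <- matrix(0, P, F)
  } else {
    Wc <- .glorot(k, F, k, F)
    bc <- numeric(F)
  }
  Wd <- .glorot(P * F, K, P * F, K)
  bd <- numeric(K)
  new("TrainedModel", config = config,
      weights = list(Wc = Wc, bc = bc, Wd = Wd, bd = bd),
      xScale = 1, yScale = 1, history = data.frame())
}

# forward pass; returns activations needed by the backward pass
.annForward <- function(weights, config, X, idx = .patchIndex(config)) {
  n <- nrow(X); P <- ncol(idx); F <- config@nFilters
  local <- config@convType == "locally_connected"
  Z <- matrix(0, n, P * F)
  for (p in seq_len(P)) {
    W <- if (local) weights$Wc[, , p] else weights$Wc
    b <- if (local) weights$bc[p, ] else weights$bc
    Z[, (p - 1L) * F + seq_len(F)] <-
      X[, idx[, p], drop = FALSE] %*% W +
      matrix(b, n, F, byrow = TRUE)
  }
  Apos <- Z > 0
  A <- ifelse(Apos, Z, exp(Z) - 1)         # ELU
  Ylin <- A %*% weights$Wd + matrix(weights$bd, n, length(weights$bd),
                                    byrow = TRUE)
  Y <- pmax(Ylin, 0)                        # ReLU output
  list(Z = Z, A = A, Apos = Apos, Ylin = Ylin, Y = Y)
}

# backward pass for MSE loss; returns gradients matching weights' shapes
.annBackward <- function(weights, config, X, fwd, Yref, idx) {
  n <- nrow(X); F <- config@nFilters
  P <- ncol(idx)
  local <- config@convType == "locally_connected"
  dY <- 2 * (fwd$Y - Yref) / length(Yref)
  dYlin <- dY * (fwd$Ylin > 0)
  dWd <- crossprod(fwd$A, dYlin)
  dbd <- colSums(dYlin)
  dA <- tcrossprod(dYlin, weights$Wd)
  dZ <- dA * ifelse(fwd$Apos, 1, fwd$A + 1)  # ELU' = exp(Z) = A + 1 for Z <= 0
  if (local) {
    dWc <- array(0, dim = dim(weights$Wc))
    dbc <- matrix(0, P, F)
    for (p in seq_len(P)) {
      dZp <- dZ[, (p - 1L) * F + seq_len(F), drop = FALSE]
      dWc[, , p] <- crossprod(X[, idx[, p], drop = FALSE], dZp)
      dbc[p, ] <- colSums(dZp)
    }
  } else {
    dWc <- matrix(0, nrow(weights$Wc), F)
    dbc <- numeric(F)
    for (p in seq_len(P)) {
      dZp <- dZ[, (p - 1L) * F + seq_len(F), drop = FALSE]
      dWc <- dWc + crossprod(X[, idx[, p], drop = FALSE], dZp)
      dbc <- dbc + colSums(dZp)
    }
  }
  list(Wc = dWc, bc = dbc, Wd = dWd, bd = dbd)
}

#' Normalise a labelled dataset to [0,1]
#'
#' Divides the spectra by their global maximum and the area labels by
#' theirs, recording both scalars: measured spectra presented to a
#' trained model are divided by the same \code{xScale}, and
#' predictions are multiplied back by \code{yScale}.
#'
#' @param dataset a \linkS4class{LabeledDataset}
#' @return list with elements \code{x}, \code{y} (normalised
#'   matrices), \code{xScale}, \code{yScale}
#' @export
normalizeDataset <- function(dataset) {
  xs <- max(dataset@spectra)
  ys <- max(dataset@labels)
  if (xs <= 0 || ys <= 0) stop("dataset has no positive signal to normalise by")
  list(x = dataset@spectra / xs, y = dataset@labels / ys,
       xScale = xs, yScale = ys)
}

#' Split row indices into train and validation sets
#'
#' Seeded random split into disjoint covering index sets whose sizes
#' are within one row of the exact ratio (default 95:5).
#'
#' @param n number of rows, or a \linkS4class{LabeledDataset}
#' @param ratio training fraction in (0,1)
#' @param seed integer seed
#' @return list with integer vectors \code{train} and \code{val}
#' @export
splitDataset <- function(n, ratio = 0.95, seed = 1L) {
  if (is(n, "LabeledDataset")) n <- nrow(n@spectra)
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0,1)")
  set.seed(seed)
  perm <- sample.int(n)
  nTrain <- min(max(round(n * ratio), 1L), n - 1L)
  list(train = sort(perm[seq_len(nTrain)]),
       val = sort(perm[seq.int(nTrain + 1L, n)]))
}

# learning rate in force at a given (1-based) epoch
.lrAt <- function(config, epoch) {
  lr <- config@lrInitial
  ks <- as.numeric(names(config@lrSchedule))
  for (i in order(ks)) if (epoch >= ks[i]) lr <- config@lrSchedule[[i]]
  lr
}

.adamStep <- function(w, g, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(g)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

#' Train the area-regression network on a synthetic dataset
#'
#' Runs the full pipeline: normalise to [0,1], split train/validation
#' at \code{config@splitRatio}, initialise the network, then minimise
#' the MSE loss with Adam under the step learning-rate schedule.
#' Additive white Gaussian noise of sd \code{config@awgnStd} is drawn
#' freshly for every minibatch and added to the (normalised) training
#' inputs only — evaluation always sees clean spectra, so repeated
#' prediction is deterministic. One RNG stream, seeded from
#' \code{config@seed}, drives split, weight initialisation, epoch
#' shuffles and AWGN, making a rerun with the same inputs
#' reproducible.
#'
#' When a \code{reference} is supplied (a list with a spectra matrix
#' and an \code{areas} matrix from an independent, more accurate
#' analyzer), the model is additionally evaluated against it after
#' every epoch in back-transformed units; this second validation
#' curve tracks performance on real measurements while the loss
#' tracks the synthetic data.
#'
#' @param dataset a \linkS4class{LabeledDataset}
#' @param config an \linkS4class{AnnConfig}
#' @param reference optional list(spectra = matrix in a.u.,
#'   areas = matrix in a.u.)
#' @param verbose print a line every 10 epochs
#' @return a \linkS4class{TrainedModel} with its per-epoch
#'   \code{history} (train_loss, val_loss, lr, ref_mse)
#' @export
trainAnn <- function(dataset, config, reference = NULL, verbose = FALSE) {
  validObject(config)
  if (ncol(dataset@spectra) != config@inputLength)
    stop("config inputLength does not match the dataset grid")
  if (ncol(dataset@labels) != config@outputNodes)
    stop("config outputNodes does not match the label count")
  norm <- normalizeDataset(dataset)

  set.seed(config@seed)
  n <- nrow(norm$x)
  perm <- sample.int(n)
  nTrain <- min(max(round(n * config@splitRatio), 1L), n - 1L)
  iTrain <- perm[seq_len(nTrain)]
  iVal <- perm[seq.int(nTrain + 1L, n)]
  Xtr <- norm$x[iTrain, , drop = FALSE]; Ytr <- norm$y[iTrain, , drop = FALSE]
  Xva <- norm$x[iVal, , drop = FALSE];   Yva <- norm$y[iVal, , drop = FALSE]

  model <- buildAnn(config, seedInit = FALSE)
  w <- model@weights
  idx <- .patchIndex(config)
  zero <- lapply(w, function(a) a * 0)
  state <- list(t = 0L, m = zero, v = zero)

  hist <- vector("list", config@epochs)
  for (epoch in seq_len(config@epochs)) {
    lr <- .lrAt(config, epoch)
    ord <- sample.int(nrow(Xtr))
    starts <- seq(1L, nrow(Xtr), by = config@batchSize)
    bl <- numeric(length(starts))
    for (b in seq_along(starts)) {
      rows <- ord[starts[b]:min(starts[b] + config@batchSize - 1L, nrow(Xtr))]
      Xb <- Xtr[rows, , drop = FALSE]
      if (config@awgnStd > 0)
        Xb <- Xb + matrix(stats::rnorm(length(Xb), 0, config@awgnStd),
                          nrow(Xb), ncol(Xb))
      Yb <- Ytr[rows, , drop = FALSE]
      fwd <- .annForward(w, config, Xb, idx)
      loss <- mean((fwd$Y - Yb)^2)
      if (!is.finite(loss))
        stop(sprintf("NaN/Inf loss at epoch %d batch %d; lower the learning rate",
                     epoch, b))
      g <- .annBackward(w, config, Xb, fwd, Yb, idx)
      upd <- .adamStep(w, g, state, lr, config@adamBeta1, config@adamBeta2)
      w <- upd$w; state <- upd$state
      bl[b] <- loss
    }
    valLoss <- mean((.annForward(w, config, Xva, idx)$Y - Yva)^2)
    refMse <- NA_real_
    if (!is.null(reference)) {
      pred <- .annForward(w, config, reference$spectra / norm$xScale,
                          idx)$Y * norm$yScale
      refMse <- mean((pred - reference$areas)^2)
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(bl),
                                val_loss = valLoss, lr = lr,
                                ref_mse = refMse)
    if (verbose && epoch %% 10L == 0L)
      message(sprintf("epoch %3d  loss %.3e  val %.3e  lr %.1e",
                      epoch, mean(bl), valLoss, lr))
  }
  # gradients can pick up label dimnames via crossprod; store clean arrays
  w <- lapply(w, function(a) { dimnames(a) <- NULL; names(a) <- NULL; a })
  new("TrainedModel", config = config, weights = w,
      xScale = norm$xScale, yScale = norm$yScale,
      history = do.call(rbind, hist))
}

#' Predict component areas from spectra
#'
#' Applies the trained network to one or more spectra given in a.u.
#' on the training grid: inputs are divided by the training
#' \code{xScale}, passed through the network, and the outputs
#' multiplied by \code{yScale}, giving areas in a.u. The ReLU output
#' guarantees non-negative predictions. Batch and single-spectrum
#' calls agree elementwise.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param x a \linkS4class{Spectrum}, a numeric vector, or a matrix
#'   with one spectrum per row
#' @return matrix of predicted areas (a.u.), one row per input spectrum
#' @export
predictAreas <- function(model, x) {
  if (is(x, "Spectrum")) x <- x@intensity
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model@config@inputLength)
    stop(sprintf("input has %d points but the model was trained on %d",
                 ncol(x), model@config@inputLength))
  fwd <- .annForward(model@weights, model@config, x / model@xScale)
  fwd$Y * model@yScale
}

#' Mean squared error between predicted and reference areas
#'
#' @param pred,ref matrices of equal shape (samples x components)
#' @return list with \code{overall} (mean over everything) and
#'   \code{perComponent} (named numeric vector)
#' @export
mseEval <- function(pred, ref) {
  pred <- as.matrix(pred); ref <- as.matrix(ref)
  if (!all(dim(pred) == dim(ref))) stop("pred and ref shapes differ")
  d2 <- (pred - ref)^2
  list(overall = mean(d2), perComponent = colMeans(d2))
}
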