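#' @include spectral-model.R
NULL

# pack/unpack helpers for the peak-table parameter vector
.packPeaks <- function(p) as.vector(rbind(p$omega, p$alpha, p$gamma, p$beta))
.unpackPeaks <- function(v) {
  m <- matrix(v, nrow = 4L)
  data.frame(omega = m[1, ], alpha = m[2, ], gamma = m[3, ], beta = m[4, ])
}

# simple peak picking: local maxima above a height fraction of the
# global maximum, strongest first
.pickPeaks <- function(nu, y, frac = 0.05) {
  n <- length(y)
  loc <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  loc <- loc[y[loc] > frac * max(y)]
  loc[order(y[loc], decreasing = TRUE)]
}

#' Fit a pseudo-Voigt peak set to a measured pure-component spectrum
#'
#' Estimates position, height, half width and Lorentz weight of each
#' peak by bounded nonlinear least squares (Levenberg-Marquardt with
#' box constraints: alpha >= 0, gamma > 0, beta in [0,1], omega inside
#' the grid). Starting values come either from a user-supplied peak
#' table or from picking local maxima above 5\% of the spectrum
#' maximum. Peak groups are assigned afterwards by the position
#' chaining rule. Non-convergence is reported in the result, never
#' thrown.
#'
#' @param spectrum a baseline-corrected \linkS4class{Spectrum}
#' @param nPeaks number of peaks to pick automatically (ignored when
#'   \code{initPeaks} is given)
#' @param initPeaks optional data.frame of starting values with
#'   columns omega, alpha, gamma, beta
#' @param name label for the fitted component model
#' @param deltaNu grouping threshold in ppm
#' @param maxIter optimizer iteration cap
#' @return a \linkS4class{FitResult} whose model is the fitted
#'   \linkS4class{PureComponentModel}
#' @export
fitPureComponent <- function(spectrum, nPeaks = NULL, initPeaks = NULL,
                             name = "component", deltaNu = 0.12,
                             maxIter = 500L) {
  grid <- spectrum@grid
  nu <- ppmAxis(grid)
  y <- spectrum@intensity
  dppm <- deltaPpm(grid)
  if (is.null(initPeaks)) {
    if (is.null(nPeaks) || nPeaks < 1L)
      stop("give nPeaks >= 1 or an initPeaks table")
    loc <- .pickPeaks(nu, y)
    if (length(loc) == 0L) stop("no peaks found above the picking threshold")
    loc <- sort(loc[seq_len(min(nPeaks, length(loc)))])
    initPeaks <- data.frame(omega = nu[loc], alpha = y[loc],
                            gamma = 5 * dppm, beta = 0.5)
  }
  initPeaks <- as.data.frame(initPeaks)[, c("omega", "alpha", "gamma", "beta")]
  np <- nrow(initPeaks)
  par0 <- .packPeaks(initPeaks)
  lower <- rep(c(grid@ppmStart, 0, dppm / 100, 0), np)
  upper <- rep(c(grid@ppmEnd, Inf, grid@ppmEnd - grid@ppmStart, 1), np)
  par0 <- pmin(pmax(par0, lower), upper)
  resid <- function(v) .evalPeakTable(.unpackPeaks(v), nu) - y
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = as.integer(maxIter),
                              ftol = 1e-10, ptol = 1e-10))
  pk <- .unpackPeaks(fit$par)
  model <- PureComponentModel(name, pk, deltaNu = deltaNu)
  new("FitResult", model = model,
      residualNorm = sqrt(fit$deviance),
      converged = fit$info %in% 1:4,
      nIterations = as.integer(fit$niter),
      diagnostics = list(message = fit$message, info = fit$info,
                         rsstrace = fit$rsstrace))
}

#' Quantify a mixture spectrum against pure-component models
#'
#' The indirect-hard-modeling style baseline: fits the parametric
#' mixture model to a measured spectrum by bounded nonlinear least
#' squares over the component weights and, optionally, the component
#' shifts, group shifts and width multipliers. The released
#' perturbations make the hard model flexible enough to absorb the
#' peak drift and broadening a benchtop instrument shows, while the
#' weights carry the quantitative information. Weights start from a
#' non-negative linear least-squares solution with all perturbations
#' at identity (a convex warm start); shifts start at 0 and
#' broadening at 1.
#'
#' @param spectrum the measured \linkS4class{Spectrum}
#' @param mixture the \linkS4class{MixtureModel} of pure components
#' @param shiftBound half-width of the component-shift box, ppm
#' @param groupShiftBound half-width of the group-shift box, ppm
#' @param broadeningBound half-width of the width-multiplier box
#'   (0.15 means multipliers in [0.85, 1.15])
#' @param releaseShift,releaseGroupShift,releaseBroadening fit these
#'   perturbations (TRUE) or pin them at identity (FALSE)
#' @param maxIter optimizer iteration cap
#' @return a \linkS4class{FitResult} whose model is a
#'   \linkS4class{MixtureParams}; \code{diagnostics$areas} holds the
#'   per-component integrated areas of the fitted weighted components
#' @export
fitMixture <- function(spectrum, mixture,
                       shiftBound = 0.015, groupShiftBound = 0.01,
                       broadeningBound = 0.15,
                       releaseShift = TRUE, releaseGroupShift = TRUE,
                       releaseBroadening = TRUE, maxIter = 500L) {
  grid <- spectrum@grid
  nu <- ppmAxis(grid)
  yobs <- spectrum@intensity
  comps <- mixture@components
  K <- length(comps)
  nGr <- vapply(comps, nGroups, integer(1))
  dppm <- deltaPpm(grid)

  unitSpectra <- vapply(comps, function(m)
    evalComponent(m, grid, warnTruncation = FALSE), numeric(grid@nPoints))

  mkParams <- function(w, thS, thGS, thPB)
    MixtureParams(mixture, weights = w, componentShift = thS,
                  groupShift = thGS, peakBroadening = thPB)

  areasOf <- function(prm) vapply(seq_len(K), function(k) {
    if (prm@weights[k] == 0) return(0)
    y <- evalComponent(comps[[k]], grid,
                       componentShift = prm@componentShift[k],
                       groupShift = prm@groupShift[[k]],
                       broadening = prm@peakBroadening[k],
                       warnTruncation = FALSE)
    prm@weights[k] * .trapz(y, dppm)
  }, numeric(1))

  if (all(yobs == 0)) {
    prm <- mkParams(rep(0, K), rep(0, K),
                    lapply(nGr, function(g) rep(0, g)), rep(1, K))
    return(new("FitResult", model = prm, residualNorm = 0,
               converged = TRUE, nIterations = 0L,
               diagnostics = list(areas = areasOf(prm),
                                  message = "zero spectrum")))
  }

  w0 <- pracma::lsqnonneg(unitSpectra, yobs)$x

  # the parameter vector holds w (K) followed by the released blocks,
  # in release order: theta_S (K), theta_GS (sum nGr), theta_PB (K)
  unpack <- function(v, has) {
    w <- v[seq_len(K)]; i <- K
    thS <- rep(0, K); thPB <- rep(1, K)
    thGS <- lapply(nGr, function(g) rep(0, g))
    if (has["shift"]) { thS <- v[i + seq_len(K)]; i <- i + K }
    if (has["gshift"]) {
      for (k in seq_len(K)) {
        thGS[[k]] <- v[i + seq_len(nGr[k])]; i <- i + nGr[k]
      }
    }
    if (has["pb"]) thPB <- v[i + seq_len(K)]
    mkParams(w, thS, thGS, thPB)
  }
  resid <- function(v, has)
    evalMixture(mixture, grid, unpack(v, has))@intensity - yobs

  # Progressive release: the shift and width parameters couple with
  # the weights (and with each other through near-degeneracy of
  # component vs group shift), which opens local minima when all are
  # freed at once. Each stage starts from the previous optimum with
  # one more block released at its identity value, so the objective
  # is non-increasing across stages.
  ctrl <- minpack.lm::nls.lm.control(maxiter = as.integer(maxIter),
                                     ftol = 1e-10, ptol = 1e-10)
  has <- c(shift = FALSE, gshift = FALSE, pb = FALSE)
  par <- w0; lower <- rep(0, K); upper <- rep(Inf, K)
  niter <- 0L; rssStages <- sum(resid(par, has)^2)
  stagePlan <- c("none",
                 if (releaseShift) "shift",
                 if (releaseGroupShift) "gshift",
                 if (releaseBroadening) "pb")
  fit <- NULL
  for (block in stagePlan) {
    if (block == "shift") {
      has["shift"] <- TRUE
      par <- c(par, rep(0, K))
      lower <- c(lower, rep(-shiftBound, K))
      upper <- c(upper, rep(shiftBound, K))
    } else if (block == "gshift") {
      has["gshift"] <- TRUE
      par <- c(par, rep(0, sum(nGr)))
      lower <- c(lower, rep(-groupShiftBound, sum(nGr)))
      upper <- c(upper, rep(groupShiftBound, sum(nGr)))
    } else if (block == "pb") {
      has["pb"] <- TRUE
      par <- c(par, rep(1, K))
      lower <- c(lower, rep(1 - broadeningBound, K))
      upper <- c(upper, rep(1 + broadeningBound, K))
    }
    fit <- minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                              fn = resid, has = has, control = ctrl)
    par <- fit$par
    niter <- niter + as.integer(fit$niter)
    rssStages <- c(rssStages, fit$deviance)
  }
  prm <- unpack(par, has)
  new("FitResult", model = prm,
      residualNorm = sqrt(fit$deviance),
      converged = fit$info %in% 1:4,
      nIterations = niter,
      diagnostics = list(areas = areasOf(prm), message = fit$message,
                         info = fit$info, rssStages = rssStages,
                         rsstrace = fit$rsstrace))
}
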