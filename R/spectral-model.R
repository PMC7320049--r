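#' @include AllGenerics.R
NULL

# Pseudo-Voigt line shape, height-parameterised:
#   V(nu) = alpha * [beta * L(nu) + (1 - beta) * G(nu)]
# with L and G normalised to unit peak height and sharing gamma as the
# half width at half maximum (HWHM, ppm). beta = 1 is pure Lorentzian,
# the NMR-dominant limit; beta = 0 is pure Gaussian.
.pseudoVoigt <- function(nu, omega, alpha, gamma, beta) {
  d2 <- (nu - omega)^2
  L <- gamma^2 / (d2 + gamma^2)
  G <- exp(-log(2) * d2 / gamma^2)
  alpha * (beta * L + (1 - beta) * G)
}

# Closed-form area of one pseudo-Voigt peak (integral over the real line):
# Lorentzian part pi*alpha*gamma, Gaussian part alpha*gamma*sqrt(pi/ln 2).
.peakAnalyticArea <- function(alpha, gamma, beta) {
  alpha * gamma * (beta * pi + (1 - beta) * sqrt(pi / log(2)))
}

#' Evaluate a single pseudo-Voigt peak on a grid
#'
#' The line shape is the height-parameterised pseudo-Voigt
#' \deqn{V(\nu) = \alpha [\beta L(\nu) + (1-\beta) G(\nu)]}
#' where both the Lorentzian \eqn{L} and Gaussian \eqn{G} have unit
#' peak height and half width at half maximum \eqn{\gamma} (ppm), so
#' the value at \eqn{\nu = \omega} is exactly \eqn{\alpha}. If your
#' peak widths are full widths (FWHM), divide by 2 before use.
#'
#' @param omega peak position, ppm
#' @param alpha peak height, a.u. (>= 0)
#' @param gamma half width at half maximum, ppm (> 0)
#' @param beta Lorentzian weight in [0,1]; 1 = pure Lorentzian
#' @param grid a \linkS4class{SpectralGrid}
#' @return numeric intensity vector of length \code{nPoints}
#' @examples
#' g <- SpectralGrid(5.6, 9.0, 1692)
#' v <- evalPeak(7.0, 2, 0.01, 1, g)
#' @export
evalPeak <- function(omega, alpha, gamma, beta, grid) {
  if (!is.finite(gamma) || gamma <= 0)
    stop("gamma must be > 0 (HWHM in ppm)")
  if (alpha < 0) stop("alpha must be >= 0")
  if (beta < 0 || beta > 1) stop("beta must lie in [0,1]")
  .pseudoVoigt(ppmAxis(grid), omega, alpha, gamma, beta)
}

# Vectorised evaluation of a whole peak table (rows of omega/alpha/
# gamma/beta) on the grid; outer() keeps this one matrix expression.
.evalPeakTable <- function(p, nu) {
  d2 <- outer(nu, p$omega, "-")^2
  g2 <- matrix(p$gamma^2, nrow = length(nu), ncol = nrow(p), byrow = TRUE)
  L <- g2 / (d2 + g2)
  G <- exp(-log(2) * d2 / g2)
  bet <- matrix(p$beta, nrow = length(nu), ncol = nrow(p), byrow = TRUE)
  alp <- matrix(p$alpha, nrow = length(nu), ncol = nrow(p), byrow = TRUE)
  V <- alp * (bet * L + (1 - bet) * G)
  rowSums(V)
}

# Warn when more than 1% of a peak table's analytic area lies outside
# the grid window (silent truncation otherwise).
.checkTruncation <- function(p, grid, what) {
  total <- sum(.peakAnalyticArea(p$alpha, p$gamma, p$beta))
  if (total <= 0) return(invisible(NULL))
  lo <- grid@ppmStart; hi <- grid@ppmEnd
  # Lorentzian tail mass outside [lo, hi] dominates; use the beta-weighted
  # closed forms for both shapes.
  frac <- vapply(seq_len(nrow(p)), function(i) {
    om <- p$omega[i]; ga <- p$gamma[i]; be <- p$beta[i]
    inL <- (atan((hi - om) / ga) - atan((lo - om) / ga)) / pi
    s <- ga / sqrt(2 * log(2))          # Gaussian sd from HWHM
    inG <- stats::pnorm(hi, om, s) - stats::pnorm(lo, om, s)
    1 - (be * inL + (1 - be) * inG)
  }, numeric(1))
  outside <- sum(frac * .peakAnalyticArea(p$alpha, p$gamma, p$beta))
  if (outside > 0.01 * total)
    warning(sprintf("%s: %.1f%% of analytic peak area falls outside the grid",
                    what, 100 * outside / total))
  invisible(NULL)
}

#' Evaluate a pure-component model with perturbations
#'
#' Renders the sum of a component's peaks after applying the
#' simulation perturbations: each peak sits at effective position
#' \code{omega + peakJitter + groupShift[group] + componentShift}
#' (all additive, so composition order is immaterial) and has
#' effective width \code{gamma * broadening}. The output is linear in
#' the peak heights.
#'
#' @param model a \linkS4class{PureComponentModel}
#' @param grid a \linkS4class{SpectralGrid}
#' @param componentShift single shift applied to every peak, ppm
#' @param groupShift one shift per peak group, ppm
#' @param broadening width multiplier (> 0) applied to every gamma
#' @param peakJitter one position perturbation per peak, ppm
#' @param warnTruncation warn when > 1\% of analytic area leaves the grid
#' @return numeric intensity vector
#' @export
evalComponent <- function(model, grid, componentShift = 0,
                          groupShift = rep(0, nGroups(model)),
                          broadening = 1,
                          peakJitter = rep(0, nrow(peaks(model))),
                          warnTruncation = TRUE) {
  p <- model@peaks
  if (length(groupShift) != nGroups(model))
    stop("groupShift must have one entry per peak group")
  if (length(peakJitter) != nrow(p))
    stop("peakJitter must have one entry per peak")
  if (broadening <= 0) stop("broadening must be > 0")
  eff <- data.frame(
    omega = p$omega + peakJitter + groupShift[p$group + 1L] + componentShift,
    alpha = p$alpha,
    gamma = p$gamma * broadening,
    beta  = p$beta)
  if (warnTruncation) .checkTruncation(eff, grid, model@name)
  .evalPeakTable(eff, ppmAxis(grid))
}

#' Evaluate the parametric mixture model
#'
#' The mixture spectrum is the weighted sum of the perturbed component
#' spectra,
#' \deqn{\chi(\nu) = \sum_{k=1}^{K} w_k S_k(\nu),}
#' exactly linear in each weight \eqn{w_k}. Components with zero
#' weight are skipped.
#'
#' @param mixture a \linkS4class{MixtureModel}
#' @param grid a \linkS4class{SpectralGrid}
#' @param params a \linkS4class{MixtureParams} consistent with
#'   \code{mixture}
#' @param warnTruncation warn on > 1\% out-of-grid peak area
#' @return a \linkS4class{Spectrum}
#' @export
evalMixture <- function(mixture, grid, params, warnTruncation = FALSE) {
  comps <- mixture@components
  K <- length(comps)
  if (length(params@weights) != K)
    stop("params do not match the mixture's component count")
  for (k in seq_len(K)) {
    if (length(params@groupShift[[k]]) != nGroups(comps[[k]]))
      stop(sprintf("groupShift length mismatch for component '%s'",
                   comps[[k]]@name))
    if (length(params@peakJitter[[k]]) != nrow(comps[[k]]@peaks))
      stop(sprintf("peakJitter length mismatch for component '%s'",
                   comps[[k]]@name))
  }
  y <- numeric(grid@nPoints)
  for (k in seq_len(K)) {
    if (params@weights[k] == 0) next
    y <- y + params@weights[k] *
      evalComponent(comps[[k]], grid,
                    componentShift = params@componentShift[k],
                    groupShift = params@groupShift[[k]],
                    broadening = params@peakBroadening[k],
                    peakJitter = params@peakJitter[[k]],
                    warnTruncation = warnTruncation)
  }
  Spectrum(grid, y, meta = list(source = "evalMixture"))
}

#' Assign peak-group ids by position chaining
#'
#' Scans peak positions in ascending order; a peak joins the current
#' group when it lies within \code{deltaNu} ppm of the previous peak,
#' and opens a new group when it deviates by more than \code{deltaNu}.
#' Chaining means a group can span more than \code{deltaNu} in total —
#' only adjacent gaps are tested. Ids are contiguous from 0.
#'
#' @param omega peak positions in ppm, sorted ascending
#' @param deltaNu grouping threshold in ppm (default 0.12)
#' @return integer vector of group ids, same length as \code{omega}
#' @examples
#' assignGroups(c(7.00, 7.05, 7.30))   # 0 0 1
#' assignGroups(c(7.00, 7.11, 7.22))   # 0 0 0 (chained)
#' @export
assignGroups <- function(omega, deltaNu = 0.12) {
  if (deltaNu <= 0) stop("deltaNu must be > 0")
  n <- length(omega)
  if (n == 0L) return(integer(0))
  if (is.unsorted(omega)) stop("omega must be sorted ascending")
  if (n == 1L) return(0L)
  cumsum(c(0L, as.integer(diff(omega) > deltaNu)))
}

#' Integrate a spectrum over a ppm region
#'
#' Trapezoidal integration of the intensity over a chemical-shift
#' interval (default: the full grid). Because signal area is strictly
#' proportional to the number of contributing nuclei, this integral is
#' the quantity that stands in for concentration throughout.
#'
#' @param spectrum a \linkS4class{Spectrum}
#' @param region length-2 numeric ppm interval, or NULL for the full range
#' @return single numeric area (a.u. * ppm)
#' @export
integrateArea <- function(spectrum, region = NULL) {
  nu <- ppmAxis(spectrum)
  y <- spectrum@intensity
  if (!is.null(region)) {
    region <- sort(as.numeric(region))
    if (region[1] < spectrum@grid@ppmStart - 1e-12 ||
        region[2] > spectrum@grid@ppmEnd + 1e-12)
      stop("region must lie within the grid")
    keep <- nu >= region[1] & nu <= region[2]
    if (sum(keep) < 2L) stop("region too narrow: fewer than 2 grid points")
    nu <- nu[keep]; y <- y[keep]
  }
  sum(diff(nu) * (y[-length(y)] + y[-1])) / 2
}

# Trapezoid over a raw vector on the (uniform) grid — hot path for the
# dataset generators, avoids constructing Spectrum objects per draw.
.trapz <- function(y, dppm) dppm * (sum(y) - (y[1] + y[length(y)]) / 2)
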