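test_that("pseudo-Voigt peak height and half-width definitions hold", {
  # gridCoarse has points exactly at 7.00 and 7.01 ppm
  v <- evalPeak(7, 2, 0.01, 1, gridCoarse)
  nu <- ppmAxis(gridCoarse)
  expect_equal(v[which.min(abs(nu - 7))], 2.0)        # height = alpha
  expect_equal(v[which.min(abs(nu - 7.01))], 1.0)     # value at HWHM
  # Gaussian limit shares both properties
  vg <- evalPeak(7, 2, 0.01, 0, gridCoarse)
  expect_equal(vg[which.min(abs(nu - 7))], 2.0)
  expect_equal(vg[which.min(abs(nu - 7.01))], 1.0)
  expect_error(evalPeak(7, 2, -0.01, 1, gridCoarse), "gamma")
  expect_error(evalPeak(7, 2, 0.01, 1.5, gridCoarse), "beta")
})

test_that("peak areas match the closed forms on a fine grid", {
  # Lorentzian: pi * alpha * gamma
  sL <- Spectrum(gridFine, evalPeak(7.3, 1.7, 0.012, 1, gridFine))
  expect_equal(integrateArea(sL), pi * 1.7 * 0.012, tolerance = 5e-3)
  # Gaussian with HWHM parameterisation: alpha * gamma * sqrt(pi/ln 2)
  sG <- Spectrum(gridFine, evalPeak(7.3, 1, 0.02, 0, gridFine))
  expect_equal(integrateArea(sG), 0.02 * sqrt(pi / log(2)),
               tolerance = 5e-3)
  # mixing weight interpolates the two areas linearly
  sM <- Spectrum(gridFine, evalPeak(7.3, 1, 0.02, 0.4, gridFine))
  expect_equal(integrateArea(sM),
               0.4 * pi * 0.02 + 0.6 * 0.02 * sqrt(pi / log(2)),
               tolerance = 5e-3)
})

test_that("component perturbations act as documented", {
  m <- components(toy$mixture)[[1]]
  grid <- toy$grid
  # identity parameters reproduce the plain sum of peaks
  y0 <- evalComponent(m, grid)
  yRef <- numeric(grid@nPoints)
  p <- peaks(m)
  for (i in seq_len(nrow(p)))
    yRef <- yRef + evalPeak(p$omega[i], p$alpha[i], p$gamma[i], p$beta[i],
                            grid)
  expect_equal(y0, yRef, tolerance = 1e-14)
  # a component shift is a pure translation of the argmax
  single <- PureComponentModel("one",
    data.frame(omega = 7.2, alpha = 1, gamma = 0.02, beta = 1))
  a0 <- which.max(evalComponent(single, grid))
  a1 <- which.max(evalComponent(single, grid, componentShift = 0.1))
  expect_lte(abs(ppmAxis(grid)[a1] - ppmAxis(grid)[a0] - 0.1),
             deltaPpm(grid))
  # broadening scales a Lorentzian peak's area linearly in gamma
  fineOne <- evalComponent(single, gridFine)
  fineB <- evalComponent(single, gridFine, broadening = 1.15)
  r <- integrateArea(Spectrum(gridFine, fineB)) /
       integrateArea(Spectrum(gridFine, fineOne))
  expect_equal(r, 1.15, tolerance = 0.01)
  expect_error(evalComponent(m, grid, groupShift = c(0)), "group")
  expect_error(evalComponent(m, grid, broadening = 0), "broadening")
})

test_that("mixture evaluation equals the per-peak brute-force oracle", {
  grid <- toy$grid
  set.seed(31)
  prm <- MixtureParams(toy$mixture,
    weights = runif(4, 0, 2),
    componentShift = runif(4, -0.015, 0.015),
    groupShift = lapply(components(toy$mixture),
                        function(m) runif(nGroups(m), -0.01, 0.01)),
    peakBroadening = runif(4, 0.85, 1.15),
    peakJitter = lapply(components(toy$mixture),
                        function(m) runif(nrow(peaks(m)), -0.005, 0.005)))
  sp <- evalMixture(toy$mixture, grid, prm)
  expect_equal(intensity(sp), bruteMixture(toy$mixture, grid, prm),
               tolerance = 1e-12)
  # linearity in the weights
  prm2 <- MixtureParams(toy$mixture, weights = 2 * prm@weights,
                        componentShift = prm@componentShift,
                        groupShift = prm@groupShift,
                        peakBroadening = prm@peakBroadening,
                        peakJitter = prm@peakJitter)
  expect_equal(intensity(evalMixture(toy$mixture, grid, prm2)),
               2 * intensity(sp), tolerance = 1e-12)
  # zero weights give the zero spectrum
  prm0 <- MixtureParams(toy$mixture, weights = rep(0, 4))
  expect_identical(intensity(evalMixture(toy$mixture, grid, prm0)),
                   numeric(grid@nPoints))
})

test_that("integrated area is conserved under small shifts (interior peaks)", {
  m <- components(toy$mixture)[[2]]
  base <- integrateArea(Spectrum(toy$grid, evalComponent(m, toy$grid)))
  for (sh in c(-0.015, 0.008, 0.015)) {
    a <- integrateArea(Spectrum(toy$grid,
           evalComponent(m, toy$grid, componentShift = sh)))
    expect_equal(a, base, tolerance = 5e-3)
  }
})

test_that("group assignment follows the chaining rule", {
  expect_identical(assignGroups(c(7.00, 7.05, 7.30)), c(0L, 0L, 1L))
  expect_identical(assignGroups(c(7.00, 7.11, 7.22)), c(0L, 0L, 0L))
  expect_identical(assignGroups(7.0), 0L)
  expect_identical(assignGroups(numeric(0)), integer(0))
  # idempotent and order-stable for sorted input
  om <- sort(runif(20, 6, 9))
  g1 <- assignGroups(om)
  expect_identical(assignGroups(om), g1)
  expect_true(all(diff(g1) %in% c(0L, 1L)))
  expect_error(assignGroups(c(7.1, 7.0)), "sorted")
  expect_error(assignGroups(c(7, 8), deltaNu = 0), "deltaNu")
})

test_that("trapezoidal integration handles constants, zero and regions", {
  g <- SpectralGrid(5.6, 9.0, 100L)
  expect_equal(integrateArea(Spectrum(g, rep(1, 100))), 3.4)
  expect_equal(integrateArea(Spectrum(g, numeric(100))), 0.0)
  expect_equal(integrateArea(Spectrum(g, rep(2, 100)), c(6, 7)),
               2.0, tolerance = 0.05)  # region snapped to grid points
  expect_error(integrateArea(Spectrum(g, rep(1, 100)), c(5.0, 6.0)),
               "within the grid")
})
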