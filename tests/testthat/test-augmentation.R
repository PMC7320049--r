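test_that("line broadening preserves the integral and lowers the maximum", {
  m <- components(toy$mixture)[[3]]
  sp <- Spectrum(toy$grid, evalComponent(m, toy$grid))
  expect_identical(broadenSpectrum(sp, 0), sp)
  a0 <- integrateArea(sp)
  prevMax <- max(intensity(sp))
  for (lb in c(0.2, 0.5, 0.8, 1.0, 1.5)) {
    b <- broadenSpectrum(sp, lb)
    expect_equal(integrateArea(b), a0, tolerance = 5e-3)
    expect_lt(max(intensity(b)), prevMax)
    prevMax <- max(intensity(b))
  }
  expect_error(broadenSpectrum(sp, -0.1), "lb")
})

test_that("spectral shifting translates, preserves area, fills zeros", {
  m <- components(toy$mixture)[[1]]
  sp <- Spectrum(toy$grid, evalComponent(m, toy$grid))
  expect_identical(shiftSpectrum(sp, 0), sp)
  d <- deltaPpm(toy$grid)
  s1 <- shiftSpectrum(sp, d)      # exactly one grid step
  n <- toy$grid@nPoints
  expect_equal(intensity(s1)[-1], intensity(sp)[-n], tolerance = 1e-12)
  expect_identical(intensity(s1)[1], 0)
  expect_equal(integrateArea(shiftSpectrum(sp, 0.015)),
               integrateArea(sp), tolerance = 5e-3)
})

test_that("noise pool extraction reproduces known noise statistics", {
  g <- SpectralGrid(0, 10, 6001L)
  set.seed(77)
  sp <- Spectrum(g, rnorm(6001, 0, 0.05))
  pool <- extractNoisePool(sp, rbind(c(0, 10)))
  expect_gte(length(pool@samples), 5000L)
  expect_lte(abs(sd(pool@samples) / 0.05 - 1), 0.05)
  # an all-zero region gives a pool of zeros
  spz <- Spectrum(g, numeric(6001))
  poolz <- extractNoisePool(spz, rbind(c(0, 10)))
  expect_true(all(poolz@samples == 0))
  expect_error(extractNoisePool(sp, rbind(c(11, 12))), "outside")
  expect_error(extractNoisePool(sp, rbind(c(0, 0.01))), "100")
})

test_that("pure-spectrum dataset conserves labels and stays in range", {
  cfg <- XiConfig(nSpectra = 200L, seed = 3L)
  ds <- makeDatasetXi(toy$pureSpectra, cfg)
  dppm <- deltaPpm(toy$grid)
  # sum of labels equals the mixture integral up to the measured noise
  tot <- apply(spectra(ds), 1, function(y)
    dppm * (sum(y) - (y[1] + y[length(y)]) / 2))
  expect_lt(max(abs(rowSums(areaLabels(ds)) / tot - 1)), 0.01)
  # every sampled parameter lies in its configured range
  p <- paramsLog(ds)
  lb <- as.matrix(p[, grep("_lb$", names(p))])
  expect_true(all(lb %in% c(0.2, 0.5, 0.8, 1.0, 1.5)))
  sh <- as.matrix(p[, grep("_shift$", names(p))])
  expect_true(all(abs(sh) <= 0.015))
  ar <- as.matrix(p[, grep("_area$", names(p))])
  expect_true(all(ar >= 0 & ar <= 180))
  # labels match the sampled target areas by construction
  expect_equal(unname(as.matrix(areaLabels(ds))), unname(ar),
               tolerance = 1e-10)
})

test_that("spectral-model dataset conserves labels noise-free", {
  cfg <- XiiConfig(nSpectra = 100L, noiseOff = TRUE, seed = 4L)
  ds <- makeDatasetXii(toy$mixture, toy$grid, NULL, cfg)
  dppm <- deltaPpm(toy$grid)
  tot <- apply(spectra(ds), 1, function(y)
    dppm * (sum(y) - (y[1] + y[length(y)]) / 2))
  expect_lt(max(abs(rowSums(areaLabels(ds)) / tot - 1)), 5e-3)
})

test_that("labels are computed before noise and unaffected by it", {
  on <- makeDatasetXii(toy$mixture, toy$grid, toy$noisePool,
                       XiiConfig(nSpectra = 30L, seed = 8L))
  off <- makeDatasetXii(toy$mixture, toy$grid, toy$noisePool,
                        XiiConfig(nSpectra = 30L, seed = 8L,
                                  noiseOff = TRUE))
  expect_identical(areaLabels(on), areaLabels(off))
  expect_false(identical(spectra(on), spectra(off)))
  # the added noise is what separates the two builds
  resid <- spectra(on) - spectra(off)
  expect_lte(max(abs(resid)), max(abs(toy$noisePool@samples)) * 1.15)
})

test_that("dataset generation is a pure function of config and seed", {
  a <- makeDatasetXi(toy$pureSpectra, XiConfig(nSpectra = 25L, seed = 9L))
  b <- makeDatasetXi(toy$pureSpectra, XiConfig(nSpectra = 25L, seed = 9L))
  expect_identical(spectra(a), spectra(b))
  expect_identical(areaLabels(a), areaLabels(b))
  c1 <- makeDatasetXii(toy$mixture, toy$grid, toy$noisePool,
                       XiiConfig(nSpectra = 25L, seed = 10L))
  c2 <- makeDatasetXii(toy$mixture, toy$grid, toy$noisePool,
                       XiiConfig(nSpectra = 25L, seed = 10L))
  expect_identical(spectra(c1), spectra(c2))
  expect_identical(paramsLog(c1), paramsLog(c2))
  # a different seed changes the draw
  c3 <- makeDatasetXii(toy$mixture, toy$grid, toy$noisePool,
                       XiiConfig(nSpectra = 25L, seed = 11L))
  expect_false(identical(spectra(c1), spectra(c3)))
})

test_that("a zero-area component leaves no trace in spectrum or labels", {
  # force the area range to [0,0] for all: every label must be 0 and
  # the noise-free spectrum exactly zero
  cfg <- XiiConfig(nSpectra = 5L, areaRange = c(0, 0), noiseOff = TRUE,
                   seed = 12L)
  ds <- makeDatasetXii(toy$mixture, toy$grid, NULL, cfg)
  expect_true(all(areaLabels(ds) == 0))
  expect_true(all(spectra(ds) == 0))
})

test_that("doubling a target area doubles that component's contribution", {
  mix1 <- MixtureModel(components(toy$mixture)[[1]])
  d1 <- makeDatasetXii(mix1, toy$grid, NULL,
                       XiiConfig(nSpectra = 10L, areaRange = c(90, 90),
                                 noiseOff = TRUE, seed = 13L))
  d2 <- makeDatasetXii(mix1, toy$grid, NULL,
                       XiiConfig(nSpectra = 10L, areaRange = c(180, 180),
                                 noiseOff = TRUE, seed = 13L))
  expect_equal(2 * spectra(d1), spectra(d2), tolerance = 1e-12)
  expect_equal(2 * areaLabels(d1), areaLabels(d2), tolerance = 1e-12)
})
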