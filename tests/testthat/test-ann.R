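test_that("closed-form parameter count matches constructed models", {
  expect_identical(countParams(AnnConfig()), 10532L)
  # tiny geometry worked out by hand: P = 2 positions
  tiny <- AnnConfig(inputLength = 18L, outputNodes = 4L)
  expect_identical(countParams(tiny), 116L)
  # formula vs actual weight-array sizes for random valid geometries
  set.seed(21)
  for (i in 1:20) {
    L <- sample(30:400, 1)
    k <- sample(2:min(15, L), 1)
    s <- sample(1:k, 1)
    cfg <- AnnConfig(inputLength = L, kernelSize = k, strides = s,
                     nFilters = sample(1:6, 1),
                     outputNodes = sample(1:5, 1),
                     convType = sample(c("locally_connected", "shared"), 1))
    m <- buildAnn(cfg)
    actual <- sum(vapply(m@weights, length, integer(1)))
    expect_identical(actual, as.integer(countParams(cfg)))
  }
  # weight sharing strictly reduces the count for equal dims
  shared <- AnnConfig(convType = "shared")
  expect_lt(countParams(shared), countParams(AnnConfig()))
  expect_error(AnnConfig(inputLength = 5L, kernelSize = 9L), "kernelSize")
})

test_that("normalisation maps to [0,1] and round-trips labels", {
  ds <- makeDatasetXii(toy$mixture, toy$grid, NULL,
                       XiiConfig(nSpectra = 20L, noiseOff = TRUE,
                                 seed = 14L))
  nz <- normalizeDataset(ds)
  expect_identical(max(nz$x), 1)
  expect_identical(max(nz$y), 1)
  expect_equal(nz$y * nz$yScale, areaLabels(ds), tolerance = 1e-12)
})

test_that("train/validation split is a disjoint seeded cover", {
  s <- splitDataset(300000L, ratio = 0.95, seed = 2L)
  expect_identical(length(s$train), 285000L)
  expect_identical(length(s$val), 15000L)
  expect_identical(sort(c(s$train, s$val)), seq_len(300000L))
  expect_identical(splitDataset(300000L, ratio = 0.95, seed = 2L), s)
  expect_false(identical(splitDataset(300000L, 0.95, 3L), s))
})

test_that("learning-rate schedule steps at the configured epochs", {
  cfg <- AnnConfig()
  lrAt <- function(e) qNMRsynth:::.lrAt(cfg, e)
  expect_identical(lrAt(1), 1e-4)
  expect_identical(lrAt(169), 1e-4)
  expect_identical(lrAt(170), 3e-5)
  expect_identical(lrAt(239), 3e-5)
  expect_identical(lrAt(240), 1e-5)
  expect_identical(lrAt(400), 1e-5)
})

# a small 2-component training problem reused by the next blocks
.mix2 <- MixtureModel(components(toy$mixture)[[1]],
                      components(toy$mixture)[[4]])
.ds2 <- makeDatasetXii(.mix2, toy$grid, NULL,
                       XiiConfig(nSpectra = 600L, noiseOff = TRUE,
                                 seed = 15L))
.cfg2 <- AnnConfig(inputLength = toy$grid@nPoints, outputNodes = 2L,
                   batchSize = 128L, lrInitial = 1e-3,
                   lrSchedule = stats::setNames(numeric(0), character(0)),
                   epochs = 10L, seed = 16L)

test_that("training reduces the loss and records a full history", {
  m <- trainAnn(.ds2, .cfg2)
  h <- history(m)
  expect_identical(nrow(h), 10L)
  expect_lt(h$train_loss[10], h$train_loss[1])
  expect_true(all(h$lr == 1e-3))
  expect_true(all(is.finite(h$val_loss)))
})

test_that("reference-set MSE is tracked per epoch when supplied", {
  evalDs <- makeDatasetXii(.mix2, toy$grid, NULL,
                           XiiConfig(nSpectra = 50L, noiseOff = TRUE,
                                     seed = 17L))
  cfg <- .cfg2; cfg@epochs <- 3L
  m <- trainAnn(.ds2, cfg,
                reference = list(spectra = spectra(evalDs),
                                 areas = areaLabels(evalDs)))
  expect_true(all(is.finite(history(m)$ref_mse)))
})

test_that("prediction is deterministic, non-negative and batch-consistent", {
  m <- trainAnn(.ds2, .cfg2)
  X <- spectra(.ds2)[1:7, ]
  p1 <- predictAreas(m, X)
  p2 <- predictAreas(m, X)
  expect_identical(p1, p2)                 # AWGN is train-time only
  expect_true(all(p1 >= 0))                # ReLU output
  for (i in c(1, 4, 7))
    expect_equal(predictAreas(m, X[i, ]), p1[i, , drop = FALSE],
                 tolerance = 1e-12)
  # zero spectrum maps to finite non-negative areas
  p0 <- predictAreas(m, numeric(toy$grid@nPoints))
  expect_true(all(is.finite(p0)) && all(p0 >= 0))
  expect_error(predictAreas(m, numeric(10)), "points")
})

test_that("training is reproducible for a fixed seed and config", {
  cfg <- .cfg2; cfg@epochs <- 4L
  m1 <- trainAnn(.ds2, cfg)
  m2 <- trainAnn(.ds2, cfg)
  expect_equal(m1@weights, m2@weights, tolerance = 1e-12)
  expect_identical(history(m1)$train_loss, history(m2)$train_loss)
})

test_that("mean squared error evaluation matches hand arithmetic", {
  expect_identical(mseEval(c(1, 2), c(1, 4))$overall, 2.0)
  p <- matrix(c(1, 2, 3, 4), 2); r <- matrix(c(1, 0, 3, 8), 2)
  ev <- mseEval(p, r)
  expect_identical(ev$overall, mean(c(0, 4, 0, 16)))
  expect_identical(unname(ev$perComponent), c(2, 8))
  expect_identical(ev$overall, mean(ev$perComponent))
  expect_error(mseEval(matrix(1, 2, 2), matrix(1, 3, 2)), "shape")
})
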