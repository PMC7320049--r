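test_that("nearest-timestamp pairing picks the closest reference row", {
  tgt <- TimeSeriesTable(c(0.5, 1.0, 2.0),
                         matrix(1:3, ncol = 1,
                                dimnames = list(NULL, "a")), "lf")
  ref <- TimeSeriesTable(c(0.4, 1.1, 2.0),
                         matrix(4:6, ncol = 1,
                                dimnames = list(NULL, "a")), "hf")
  p <- matchNearest(tgt, ref)
  expect_identical(p$ref_idx, c(1L, 2L, 3L))   # 1.0 is closer to 1.1
  # identical axes give the identity pairing
  p2 <- matchNearest(tgt, tgt)
  expect_identical(p2$ref_idx, 1:3)
  expect_identical(p2$lf_a, p2$hf_a)
  # an exact midpoint tie resolves to the earlier reference row
  tie <- matchNearest(TimeSeriesTable(1.0, matrix(0, 1, 1,
                                                  dimnames = list(NULL, "a"))),
                      TimeSeriesTable(c(0.5, 1.5), matrix(1:2, ncol = 1,
                                                          dimnames = list(NULL, "a"))))
  expect_identical(tie$ref_idx, 1L)
  expect_error(matchNearest(tgt, TimeSeriesTable(numeric(0),
                                                 matrix(0, 0, 1))), "empty")
})

test_that("steady-state mask separates plateaus from ramps", {
  # constant series: every interior centre point is steady
  tc <- seq(0, 2, length.out = 40)
  const <- TimeSeriesTable(tc, matrix(0.5, 40, 2))
  m <- steadyStateMask(const)
  expect_true(all(m[6:35]))
  expect_true(all(!m[c(1:5, 36:40)]))
  # a ramp at 1 mol/h is never steady
  ramp <- TimeSeriesTable(tc, cbind(tc * 1.0, 0.5))
  expect_true(!any(steadyStateMask(ramp)))
  # markAll flags whole windows
  expect_gt(sum(steadyStateMask(const, markAll = TRUE)), sum(m))
  expect_warning(m0 <- steadyStateMask(TimeSeriesTable(1:5 / 10,
                                                       matrix(0, 5, 1))),
                 "shorter")
  expect_identical(m0, rep(FALSE, 5))
})

test_that("steady-state mask equals the brute-force window refit", {
  set.seed(41)
  t <- sort(runif(120, 0, 6))
  vals <- cbind(0.4 + 0.004 * rnorm(120),
                c(rep(0.3, 50), seq(0.3, 0.8, length.out = 20),
                  rep(0.8, 50)) + 0.003 * rnorm(120))
  ser <- TimeSeriesTable(t, vals)
  expect_identical(steadyStateMask(ser), bruteSteadyMask(ser))
  # piecewise plateau/ramp/plateau keeps steady points off the ramp
  tEven <- seq(0, 6, length.out = 120)
  pw <- TimeSeriesTable(tEven,
          matrix(c(rep(0.3, 50), seq(0.3, 0.8, length.out = 20),
                   rep(0.8, 50)), ncol = 1))
  mPw <- steadyStateMask(pw)
  expect_identical(mPw, bruteSteadyMask(pw))
  expect_true(!any(mPw[51:70]))
  expect_true(any(mPw[1:50]) && any(mPw[71:120]))
})

test_that("outlier removal is strict and component-wise", {
  # row 3's deviation is exactly the 0.04 threshold (0.04 - 0 is an
  # exact double), so "greater than" keeps it; row 2 and row 4 exceed it
  pairs <- data.frame(time = 1:4,
                      lf_a = c(0.50, 0.50, 0.00, 0.50),
                      lf_b = c(0.30, 0.30, 0.30, 0.30),
                      hf_a = c(0.50, 0.55, 0.04, 0.50),
                      hf_b = c(0.30, 0.30, 0.30, 0.25))
  out <- removeOutliers(pairs)
  expect_identical(out$time, c(1L, 3L))  # 0.05 dropped, exact 0.04 kept
  expect_identical(removeOutliers(pairs[1, , drop = FALSE]),
                   pairs[1, , drop = FALSE])
})

test_that("Kennard-Stone matches the exhaustive max-min oracle", {
  pts1 <- matrix(c(0, 1, 2, 10), ncol = 1)
  expect_identical(kennardStoneSelect(pts1, 4), c(1L, 4L, 3L, 2L))
  expect_identical(kennardStoneSelect(pts1, 2), c(1L, 4L))
  expect_identical(kennardStoneSelect(pts1, 3), c(1L, 4L, 3L))
  set.seed(51)
  for (rep in 1:5) {
    pts <- matrix(runif(24), ncol = 2)     # n = 12
    for (k in c(3L, 7L, 12L))
      expect_identical(kennardStoneSelect(pts, k),
                       as.integer(bruteKennardStone(pts, k)))
  }
  expect_error(kennardStoneSelect(pts1, 5), "k must be")
})

test_that("Kennard-Stone selections form a prefix chain in k", {
  set.seed(52)
  pts <- matrix(rnorm(60), ncol = 3)
  full <- kennardStoneSelect(pts, 20)
  for (k in 2:19)
    expect_identical(kennardStoneSelect(pts, k), full[seq_len(k)])
})

test_that("the full curation chain behaves on the toy trajectory", {
  cur <- curateReference(toy$lfSeries, toy$hfSeries, select = 60L)
  expect_identical(nrow(cur), 60L)
  # no curated point sits on a ramp of the underlying truth
  onRamp <- (cur$time > 2 & cur$time < 3) |
            (cur$time > 5 & cur$time < 6) |
            (cur$time > 8 & cur$time < 8.5)
  expect_true(!any(onRamp))
  # all injected reference outliers were removed
  expect_true(!any(cur$ref_idx %in% toy$outlierRows))
  # disagreement after curation is within the threshold everywhere
  lf <- as.matrix(cur[, grep("^lf_", names(cur))])
  hf <- as.matrix(cur[, grep("^hf_", names(cur))])
  expect_lte(max(abs(hf - lf)), 0.04)
})
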