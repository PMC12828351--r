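test_that("the plasma input is zero before injection and positive after", {
  expect_equal(plasmaInputFunction(c(-1, 0)), c(0, 0))
  tt <- seq(0.05, 60, by = 0.05)
  v <- plasmaInputFunction(tt)
  expect_true(all(v >= 0))
  expect_true(all(is.finite(v)))
  expect_gt(max(v), 0)
  # bolus shape: the peak is early
  expect_lt(tt[which.max(v)], 5)
})

test_that("the forward model agrees with an adaptive ODE solver", {
  schedule <- pkFrameSchedule()
  for (p in list(c(0.10, 0.30), c(0.05, 0.15), c(0.10, 0.10))) {
    got <- tacValues(simulateTissueTAC(p[1], p[2], schedule))
    want <- oracleTissueTAC(p[1], p[2], schedule)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("noiseless dynamic images are deterministic functions of DVR", {
  g <- unitGrid(c(3L, 3L, 1L))
  kin <- KineticParams()                      # noiseCV = 0
  dvr <- array(c(1, 1, 2, 2, NA, 0, 1.5, 1.5, 1), g@dim)
  dyn <- simulateDynamicPET(g, dvr, kin, pkFrameSchedule(), seed = 1L)
  Y <- tractopet:::dynamicMatrix(dyn)
  expect_equal(Y[, 1], Y[, 2])                # equal DVR, equal TAC
  expect_equal(Y[, 3], Y[, 4])
  expect_equal(Y[, 5], rep(0, 22))            # NA DVR -> no signal
  expect_equal(Y[, 6], rep(0, 22))            # zero DVR -> no signal
  expect_false(isTRUE(all.equal(Y[, 1], Y[, 3])))
  # a DVR-1 voxel reproduces the reference tissue curve exactly
  expect_equal(Y[, 1], tacValues(simulateTissueTAC(kin@K1, kin@k2,
                                                   pkFrameSchedule())))
})

test_that("higher DVR yields a larger late-time tissue-to-reference ratio", {
  g <- unitGrid(c(2L, 1L, 1L))
  dyn <- simulateDynamicPET(g, array(c(1, 2), g@dim), KineticParams(),
                            pkFrameSchedule(), seed = 1L)
  Y <- tractopet:::dynamicMatrix(dyn)
  late <- which(frameMidTimes(pkFrameSchedule()) >= 40)
  ratio <- mean(Y[late, 2] / Y[late, 1])
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("noise is seed-reproducible and scales with frame duration", {
  g <- unitGrid(c(20L, 20L, 5L))
  kin <- KineticParams(noiseCV = 0.1)
  dvr <- array(1, g@dim)
  a <- simulateDynamicPET(g, dvr, kin, pkFrameSchedule(), seed = 42L)
  b <- simulateDynamicPET(g, dvr, kin, pkFrameSchedule(), seed = 42L)
  d <- simulateDynamicPET(g, dvr, kin, pkFrameSchedule(), seed = 43L)
  expect_identical(a@data, b@data)
  expect_false(identical(a@data, d@data))
  clean <- simulateDynamicPET(g, dvr, KineticParams(), pkFrameSchedule(), 1L)
  rel <- tractopet:::dynamicMatrix(a) / tractopet:::dynamicMatrix(clean) - 1
  sds <- apply(rel, 1, sd)
  want <- 0.1 * sqrt(300 / frameDurations(pkFrameSchedule()))
  expect_equal(sds, want, tolerance = 0.1)
})

test_that("a kinetically distinct tissue class still meets its DVR target", {
  g <- unitGrid(c(2L, 1L, 1L))
  wm <- array(c(FALSE, TRUE), g@dim)
  dyn <- simulateDynamicPET(g, array(1.4, g@dim), KineticParams(),
                            pkFrameSchedule(), seed = 1L, tissueMask = wm,
                            tissueParams = KineticParams(K1 = 0.05, k2 = 0.15))
  Y <- tractopet:::dynamicMatrix(dyn)
  # white-matter voxel: K1 = 0.05 and DV = 1.4 * (0.1/0.3) -> k2 = K1/DV
  want <- oracleTissueTAC(0.05, 0.05 / (1.4 * (0.1 / 0.3)), pkFrameSchedule())
  expect_equal(Y[, 2], want, tolerance = 1e-3)
  expect_false(isTRUE(all.equal(Y[, 1], Y[, 2], tolerance = 0.01)))
})

test_that("dvr fields must be non-negative and grid-shaped", {
  g <- unitGrid(c(2L, 2L, 2L))
  expect_error(simulateDynamicPET(g, array(-1, g@dim), KineticParams(),
                                  pkFrameSchedule(), 1L), "non-negative")
  expect_error(simulateDynamicPET(g, array(1, c(3, 2, 2)), KineticParams(),
                                  pkFrameSchedule(), 1L), "dimensions")
})
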