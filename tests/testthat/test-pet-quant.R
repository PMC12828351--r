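test_that("exact NNLS by support enumeration matches a reference solver", {
  set.seed(21)
  schedule <- pkFrameSchedule()
  B <- tractopet:::defaultKineticClasses(schedule)@curves
  Y <- matrix(abs(rnorm(22 * 40, 1, 0.5)), 22)
  W <- tractopet:::nnlsBasis(B, Y)
  for (j in seq_len(ncol(Y))) {
    ref <- pracma::lsqnonneg(B, Y[, j])$x
    # compare achieved residuals (solutions can tie); both must be feasible
    expect_true(all(W[, j] >= 0))
    expect_lte(sum((Y[, j] - B %*% W[, j])^2),
               sum((Y[, j] - B %*% ref)^2) + 1e-8)
  }
})

test_that("reference extraction recovers a planted low-binding pool", {
  schedule <- pkFrameSchedule()
  g <- unitGrid(c(6L, 5L, 1L))
  classes <- defaultKineticClasses(schedule)
  gray <- tacValues(simulateTissueTAC(0.10, 0.30, schedule))
  white <- tacValues(simulateTissueTAC(0.05, 0.15, schedule))
  high <- tacValues(simulateTissueTAC(0.10, 0.10, schedule))
  Y <- cbind(matrix(gray, 22, 10), matrix(white, 22, 10),
             matrix(high, 22, 10))
  dyn <- new("DynamicImage", data = array(t(Y), c(g@dim, 22L)), grid = g,
             schedule = schedule)
  ref <- extractReferenceTAC(dyn, array(TRUE, g@dim), classes)
  expect_equal(tacValues(ref), gray, tolerance = 1e-8)
})

test_that("reference extraction validates its inputs", {
  schedule <- pkFrameSchedule()
  g <- unitGrid(c(2L, 2L, 1L))
  dyn <- simulateDynamicPET(g, array(1, g@dim), KineticParams(), schedule, 1L)
  classes <- defaultKineticClasses(schedule)
  expect_error(extractReferenceTAC(dyn, array(FALSE, g@dim), classes),
               "empty")
  expect_error(extractReferenceTAC(dyn, array(TRUE, g@dim), classes,
                                   selectFraction = 0), "selectFraction")
  expect_error(extractReferenceTAC(dyn, array(TRUE, g@dim), classes,
                                   selectFraction = 1.5), "selectFraction")
  zero <- new("DynamicImage", data = array(0, c(g@dim, 22L)), grid = g,
              schedule = schedule)
  expect_error(extractReferenceTAC(zero, array(TRUE, g@dim), classes),
               "positive integrated activity")
})

test_that("the Logan plot of a curve against itself has unit slope", {
  schedule <- pkFrameSchedule()
  tac <- simulateTissueTAC(0.1, 0.3, schedule)
  fit <- loganDVR(tac, tac, tStar = 20)
  expect_equal(fit$dvr, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("Logan DVR estimates recover the simulated DVR", {
  schedule <- pkFrameSchedule()
  ref <- simulateTissueTAC(0.1, 0.3, schedule)
  for (dvr in c(1.2, 1.5, 2.0)) {
    tgt <- simulateTissueTAC(0.1, 0.3 / dvr, schedule)
    fit <- loganDVR(tgt, ref, tStar = 20)
    expect_equal(fit$dvr, dvr, tolerance = 0.02 / dvr)
  }
})

test_that("Logan DVR is invariant to a common activity rescaling", {
  schedule <- pkFrameSchedule()
  ref <- simulateTissueTAC(0.1, 0.3, schedule)
  tgt <- simulateTissueTAC(0.1, 0.2, schedule)
  f1 <- loganDVR(tgt, ref)
  f2 <- loganDVR(TAC(schedule, tacValues(tgt) * 7),
                 TAC(schedule, tacValues(ref) * 7))
  expect_equal(f1$dvr, f2$dvr, tolerance = 1e-12)
})

test_that("the reference-efflux correction term is applied when requested", {
  schedule <- pkFrameSchedule()
  ref <- simulateTissueTAC(0.1, 0.3, schedule)
  tgt <- simulateTissueTAC(0.1, 0.15, schedule)
  plain <- loganDVR(tgt, ref, tStar = 20)
  corrected <- loganDVR(tgt, ref, tStar = 20, k2prime = 0.3)
  expect_false(isTRUE(all.equal(plain$dvr, corrected$dvr)))
  expect_equal(corrected$dvr, 2, tolerance = 0.02)
})

test_that("Logan fits reject unusable inputs", {
  schedule <- pkFrameSchedule()
  tac <- simulateTissueTAC(0.1, 0.3, schedule)
  expect_error(loganDVR(tac, tac, tStar = 70), "span")
  expect_error(loganDVR(tac, tac, tStar = 54), "fewer than 3")
  short <- buildFrameSchedule(list(c(22, 60)))
  expect_error(loganDVR(tac, TAC(short, rep(1, 22))), "schedules")
})

test_that("voxelwise DVR maps match the scalar fit and honour the mask", {
  schedule <- pkFrameSchedule()
  g <- unitGrid(c(2L, 2L, 1L))
  dvrField <- array(c(1, 1.3, 1.8, 1), g@dim)
  dyn <- simulateDynamicPET(g, dvrField, KineticParams(), schedule, 1L)
  ref <- simulateTissueTAC(0.1, 0.3, schedule)
  mask <- array(c(TRUE, TRUE, TRUE, FALSE), g@dim)
  m <- computeDVRMap(dyn, ref, mask = mask)
  Y <- tractopet:::dynamicMatrix(dyn)
  for (j in 1:3)
    expect_equal(m@values[j], loganDVR(TAC(schedule, Y[, j]), ref)$dvr,
                 tolerance = 1e-10)
  expect_true(is.na(m@values[4]))
})

test_that("voxels without usable signal are left undefined, not errors", {
  schedule <- pkFrameSchedule()
  g <- unitGrid(c(2L, 1L, 1L))
  dyn <- simulateDynamicPET(g, array(c(1, 0), g@dim), KineticParams(),
                            schedule, 1L)
  m <- computeDVRMap(dyn, simulateTissueTAC(0.1, 0.3, schedule))
  expect_false(is.na(m@values[1]))
  expect_true(is.na(m@values[2]))
})

test_that("DVR maps are invariant to rescaling the whole image", {
  schedule <- pkFrameSchedule()
  g <- unitGrid(c(3L, 2L, 1L))
  dyn <- simulateDynamicPET(g, array(1.4, g@dim), KineticParams(),
                            schedule, 1L)
  ref <- simulateTissueTAC(0.1, 0.3, schedule)
  scaled <- new("DynamicImage", data = dyn@data * 3, grid = g,
                schedule = schedule)
  m1 <- computeDVRMap(dyn, TAC(schedule, tacValues(ref)))
  m2 <- computeDVRMap(scaled, TAC(schedule, tacValues(ref) * 3))
  expect_equal(m1@values, m2@values, tolerance = 1e-12)
})
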