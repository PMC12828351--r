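test_that("an axis-aligned streamline traverses exactly the voxels it spans", {
  g <- unitGrid(c(4L, 4L, 4L))
  sl <- centerLine(g, cbind(0:3, 0, 0))      # through voxel centres
  vox <- voxelizeStreamline(sl, g)
  expect_equal(vox, cbind(1:4, 1L, 1L), ignore_attr = TRUE)
})

test_that("a diagonal streamline matches the traversal oracle", {
  g <- unitGrid(c(5L, 5L, 5L))
  sl <- centerLine(g, rbind(c(0.2, 0.1, 0), c(3.9, 4.2, 4.4)))
  got <- sort(g@dim[1] * g@dim[2] * (voxelizeStreamline(sl, g)[, 3] - 1L) +
                g@dim[1] * (voxelizeStreamline(sl, g)[, 2] - 1L) +
                voxelizeStreamline(sl, g)[, 1])
  expect_equal(got, oracleVoxelizeLinear(sl, g))
})

test_that("voxel traversal equals the independent oracle on random lines", {
  set.seed(71)
  g <- VolumeGrid(c(6L, 5L, 4L), c(1.5, 2, 1))
  for (i in 1:100) {
    sl <- randomStreamline(g, n = sample(2:10, 1))
    got <- sort(tractopet:::voxelizeLinear(sl, g))
    expect_equal(got, oracleVoxelizeLinear(sl, g))
  }
})

test_that("dense point sampling never finds voxels traversal misses", {
  set.seed(72)
  g <- unitGrid(c(6L, 6L, 6L))
  for (i in 1:20) {
    sl <- randomStreamline(g, n = 4)
    exact <- sort(tractopet:::voxelizeLinear(sl, g))
    dense <- denseVoxelizeLinear(sl, g)
    expect_true(all(dense %in% exact))
  }
})

test_that("points outside the grid contribute no voxels", {
  g <- unitGrid(c(3L, 3L, 3L))
  far <- rbind(c(100, 100, 100), c(120, 100, 100))
  expect_equal(nrow(voxelizeStreamline(far, g)), 0L)
})

test_that("a point on a shared face belongs to the higher-index voxel", {
  g <- unitGrid(c(4L, 4L, 4L))
  # 0-based voxel coordinate 0.5 is the face between voxels 0 and 1
  sl <- centerLine(g, rbind(c(0.5, 0, 0), c(0.5, 0.2, 0)))
  vox <- voxelizeStreamline(sl, g)
  expect_equal(unique(vox[, 1]), 2L)
})

test_that("streamlineIntersects detects mask crossings", {
  g <- unitGrid(c(4L, 4L, 4L))
  sl <- centerLine(g, cbind(0:3, 0, 0))
  m <- array(FALSE, g@dim); m[3, 1, 1] <- TRUE
  expect_true(streamlineIntersects(sl, m, g))
  m2 <- array(FALSE, g@dim); m2[1, 4, 4] <- TRUE
  expect_false(streamlineIntersects(sl, m2, g))
})

test_that("disruption counts match brute-force enumeration", {
  set.seed(5)
  g <- VolumeGrid(c(5L, 4L, 5L), c(2, 1, 1))
  sl <- lapply(1:15, function(i) randomStreamline(g, n = 6))
  tg <- Tractogram(sl, g)
  for (i in 1:10) {
    mask <- randomMask(g, 0.15)
    got <- computeDisruptionMap(tg, mask)
    want <- oracleDisruption(tg, mask)
    expect_identical(got@nThrough, want$nThrough)
    expect_identical(got@nLesioned, want$nLesioned)
    expect_equal(disruptionScore(got), want$score)
  }
})

test_that("scores are undefined exactly where no streamline passes", {
  g <- unitGrid(c(4L, 4L, 4L))
  tg <- Tractogram(list(centerLine(g, cbind(0:3, 0, 0))), g)
  s <- disruptionScore(computeDisruptionMap(tg, array(FALSE, g@dim)))
  expect_true(all(is.na(s[, 2:4, ])))
  expect_equal(s[, 1, 1], rep(0, 4))
})

test_that("growing the lesion mask never decreases any score", {
  set.seed(9)
  g <- unitGrid(c(6L, 6L, 6L))
  tg <- Tractogram(lapply(1:10, function(i) randomStreamline(g, 5)), g)
  small <- randomMask(g, 0.1)
  big <- small | randomMask(g, 0.15)
  s1 <- disruptionScore(computeDisruptionMap(tg, small))
  s2 <- disruptionScore(computeDisruptionMap(tg, big))
  ok <- !is.na(s1)
  expect_true(all(s2[ok] >= s1[ok]))
})

test_that("a union of lesions is bounded by its parts and their sum", {
  set.seed(10)
  g <- unitGrid(c(6L, 6L, 6L))
  tg <- Tractogram(lapply(1:12, function(i) randomStreamline(g, 5)), g)
  a <- randomMask(g, 0.08); b <- randomMask(g, 0.08)
  sa <- disruptionScore(computeDisruptionMap(tg, a))
  sb <- disruptionScore(computeDisruptionMap(tg, b))
  su <- disruptionScore(computeDisruptionMap(tg, a | b))
  ok <- !is.na(su)
  expect_true(all(su[ok] >= pmax(sa[ok], sb[ok]) - 1e-12))
  expect_true(all(su[ok] <= sa[ok] + sb[ok] + 1e-12))
})

test_that("scores are invariant to a uniform rescaling of the geometry", {
  set.seed(11)
  g1 <- unitGrid(c(5L, 5L, 5L))
  sl <- lapply(1:8, function(i) randomStreamline(g1, 5))
  mask <- randomMask(g1, 0.2)
  g2 <- VolumeGrid(c(5L, 5L, 5L), c(3, 3, 3))
  sl2 <- lapply(sl, function(s)
    voxelToWorldCoords(g2, worldToVoxelCoords(g1, s)))
  s1 <- disruptionScore(computeDisruptionMap(Tractogram(sl, g1), mask))
  s2 <- disruptionScore(computeDisruptionMap(Tractogram(sl2, g2), mask))
  expect_equal(s1, s2)
})

test_that("an empty tractogram cannot be scored", {
  g <- unitGrid()
  expect_error(computeDisruptionMap(Tractogram(list(), g),
                                    array(FALSE, g@dim)), "empty")
})

test_that("strata respect their boundary closures and partition the scores", {
  g <- unitGrid(c(11L, 1L, 1L))
  nT <- array(10L, g@dim)
  nL <- array(0:10, g@dim)                      # scores exactly 0, 0.1, ..., 1
  dm <- new("DisruptionMap", nThrough = nT, nLesioned = nL, grid = g)
  st <- stratifyDisruption(dm, sweep = TRUE)
  lab <- as.vector(st@labels)
  expect_equal(lab, c("none", "low", rep("mid", 7), "high", "high"))
  expect_false(any(is.na(lab)))                 # full partition when defined
  # sweep bins: left-open (l, l+0.1], so 0.1 -> bin 1 and 1.0 -> bin 10
  expect_equal(as.vector(st@sweepBin), c(NA, 1:10))
})
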