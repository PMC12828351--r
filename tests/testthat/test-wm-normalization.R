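test_that("group WM mask keeps voxels in strictly more than half the masks", {
  g <- unitGrid(c(11L, 1L, 1L))
  # voxel i is present in i-1 of the 11 masks
  masks <- lapply(1:11, function(k) array(c(rep(FALSE, 12 - k),
                                            rep(TRUE, k - 1)), g@dim))
  gm <- buildGroupWMMask(masks, g)
  counts <- Reduce(`+`, lapply(masks, function(m) m * 1))
  expect_identical(as.vector(gm@mask), as.vector(counts > 5.5))
  expect_false(gm@mask[6])   # present in 5/11: dropped
  expect_true(gm@mask[7])    # present in 6/11: kept
  expect_equal(gm@probability, counts / 11)
})

test_that("a high threshold reduces the group mask towards the intersection", {
  g <- unitGrid(c(4L, 4L, 1L))
  a <- array(TRUE, g@dim)
  b <- array(FALSE, g@dim); b[1:2, , ] <- TRUE
  gm <- buildGroupWMMask(list(a, b), g, threshold = 0.99)
  expect_identical(gm@mask, a & b)
  gmHalf <- buildGroupWMMask(list(a, b), g, threshold = 0.5)
  expect_true(sum(gmHalf@mask) >= sum(gm@mask))
})

test_that("boundary exclusion removes centre-to-centre neighbours within range", {
  g <- unitGrid(c(5L, 5L, 5L))
  excl <- array(FALSE, g@dim); excl[3, 3, 3] <- TRUE
  full <- array(TRUE, g@dim)
  out1 <- excludeBoundary(full, excl, g, distance = 1)
  removed <- which(!out1)
  # the voxel itself plus its 6 face neighbours (1 mm), not diagonals (~1.41)
  expect_equal(length(removed), 7L)
  expect_false(out1[3, 3, 3])
  expect_false(out1[2, 3, 3]); expect_false(out1[4, 3, 3])
  expect_true(out1[2, 2, 3])
  out0 <- excludeBoundary(full, excl, g, distance = 0)
  expect_equal(sum(!out0), 1L)
  out2 <- excludeBoundary(full, excl, g, distance = 1.5)
  expect_true(all(which(!out1) %in% which(!out2)))
  expect_gt(sum(!out2), sum(!out1))
})

test_that("boundary exclusion respects anisotropic voxel sizes", {
  g <- VolumeGrid(c(5L, 5L, 5L), c(2, 1, 1))
  excl <- array(FALSE, g@dim); excl[3, 3, 3] <- TRUE
  out <- excludeBoundary(array(TRUE, g@dim), excl, g, distance = 1)
  expect_true(out[2, 3, 3])      # 2 mm away along x: kept
  expect_false(out[3, 2, 3])     # 1 mm away along y: removed
  expect_false(out[3, 3, 4])     # 1 mm away along z: removed
})

test_that("z-scoring standardises against the HC pool voxelwise", {
  g <- unitGrid(c(3L, 2L, 1L))
  mk <- function(v) new("DVRMap", values = array(v, g@dim),
                        r2 = array(1, g@dim), grid = g)
  hc <- list(mk(c(1, 2, 3, 4, 5, 6)), mk(c(2, 2, 4, 4, 6, 6)),
             mk(c(3, 2, 5, 4, 7, 6)))
  subj <- mk(c(4, 2, 6, 4, 8, 6))
  mask <- array(TRUE, g@dim)
  z <- zscoreMap(subj, hc, mask)
  expect_equal(z@hcMean[1], 2)
  expect_equal(z@hcSd[1], 1)
  expect_equal(z@z[1], 2)
  # constant HC values -> zero variance -> undefined z
  expect_true(is.na(z@z[2]))
  expect_equal(z@z[3], (6 - 4) / 1)
})

test_that("z maps ignore voxels outside the analysis mask", {
  g <- unitGrid(c(2L, 1L, 1L))
  mk <- function(v) new("DVRMap", values = array(v, g@dim),
                        r2 = array(1, g@dim), grid = g)
  mask <- array(c(TRUE, FALSE), g@dim)
  z <- zscoreMap(mk(c(3, 3)), list(mk(c(1, 1)), mk(c(2, 2))), mask)
  expect_false(is.na(z@z[1]))
  expect_true(is.na(z@z[2]))
})

test_that("z-scoring needs at least two healthy controls", {
  g <- unitGrid(c(2L, 1L, 1L))
  mk <- function(v) new("DVRMap", values = array(v, g@dim),
                        r2 = array(1, g@dim), grid = g)
  expect_error(zscoreMap(mk(c(1, 1)), list(mk(c(1, 1))),
                         array(TRUE, g@dim)), "at least 2")
})

test_that("stratified means average exactly the stratum voxels", {
  g <- unitGrid(c(4L, 1L, 1L))
  z <- new("ZScoreMap", z = array(c(1, 2, 3, 4), g@dim),
           hcMean = array(0, g@dim), hcSd = array(1, g@dim), grid = g)
  st <- new("DisruptionStrata",
            labels = array(c("none", "none", "high", "high"), g@dim),
            sweepBin = array(integer(0), c(0L, 0L, 0L)),
            binEdges = seq(0, 1, 0.1), grid = g)
  sm <- stratifiedMeanZ(z, st)
  expect_equal(sm$mean_z[sm$stratum == "none"], 1.5)
  expect_equal(sm$mean_z[sm$stratum == "high"], 3.5)
  expect_equal(sm$n_voxels[sm$stratum == "low"], 0L)
  expect_true(is.na(sm$mean_z[sm$stratum == "low"]))
  expect_setequal(sm$stratum, c("none", "low", "mid", "high"))
})

test_that("stratified means are invariant to voxel ordering", {
  set.seed(31)
  g <- unitGrid(c(4L, 3L, 2L))
  zv <- rnorm(24)
  labs <- sample(c("none", "low", "mid", "high"), 24, replace = TRUE)
  perm <- sample(24)
  mkz <- function(v) new("ZScoreMap", z = array(v, g@dim),
                         hcMean = array(0, g@dim), hcSd = array(1, g@dim),
                         grid = g)
  mks <- function(l) new("DisruptionStrata", labels = array(l, g@dim),
                         sweepBin = array(integer(0), c(0L, 0L, 0L)),
                         binEdges = seq(0, 1, 0.1), grid = g)
  a <- stratifiedMeanZ(mkz(zv), mks(labs))
  b <- stratifiedMeanZ(mkz(zv[perm]), mks(labs[perm]))
  expect_equal(a, b)
})
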