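# deterministic sub-seed derivation, kept below 2^31
subSeed <- function(base, i) {
  as.integer((as.numeric(base) * 48271 + i) %% 2147483647)
}

#' Configure a synthetic cohort
#'
#' Defaults encode the target study design: 11 HC, 26 PRL-positive and 18
#' PRL-negative MS patients; PRL counts averaging about 3 per PRL-positive
#' patient; a 32 x 32 x 16 grid at 2 mm. The planted white-matter DVR field
#' of an MS subject is \code{1 + delta_s + effectSize * disruption(all
#' lesions) [+ prlBoost * effectSize * disruption(PRLs)]}, where
#' \code{delta_s ~ N(0, subjectSD)} is a per-subject diffuse-inflammation
#' random effect; healthy controls get \code{1 + delta_s}.
#'
#' @param nHC,nMSPRL,nMSNoPRL subject counts.
#' @param effectSize additive DVR elevation per unit disruption (0 = null).
#' @param prlBoost extra PRL-tract elevation as a multiple of effectSize.
#' @param subjectSD SD of the per-subject WM DVR random effect.
#' @param noiseCV fractional PET noise at 300-s frames.
#' @param prlCountRange,nonPrlCountRange inclusive integer ranges of lesion
#'   counts per subject (PRL counts apply to PRL-positive subjects only).
#' @param lesionRadiusRange lesion radius range, mm.
#' @param nStreamlines streamlines in the synthetic normative tractogram.
#' @param gridDim,gridSpacing grid geometry.
#' @param seed integer; fully determines the cohort.
#' @return a \linkS4class{CohortConfig}.
#' @export
CohortConfig <- function(nHC = 11L, nMSPRL = 26L, nMSNoPRL = 18L,
                         effectSize = 0.3, prlBoost = 0.5, subjectSD = 0.03,
                         noiseCV = 0.05, prlCountRange = c(1L, 5L),
                         nonPrlCountRange = c(2L, 6L),
                         lesionRadiusRange = c(3, 6), nStreamlines = 400L,
                         gridDim = c(32L, 32L, 16L), gridSpacing = c(2, 2, 2),
                         seed = 1L) {
  new("CohortConfig", nHC = as.integer(nHC), nMSPRL = as.integer(nMSPRL),
      nMSNoPRL = as.integer(nMSNoPRL), effectSize = effectSize,
      prlBoost = prlBoost, subjectSD = subjectSD, noiseCV = noiseCV,
      prlCountRange = as.integer(prlCountRange),
      nonPrlCountRange = as.integer(nonPrlCountRange),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      nStreamlines = as.integer(nStreamlines), gridDim = as.integer(gridDim),
      gridSpacing = as.numeric(gridSpacing), seed = as.integer(seed))
}

#' Generate a synthetic normative tractogram
#'
#' Streamlines are noisy quadratic arcs spanning the grid: endpoints sit on
#' opposite sides of a centred box covering \code{extent} of the bounding
#' box, the control point is drawn from the central region, and small
#' Gaussian jitter roughens the curve. All points are kept strictly inside
#' the grid's world bounding box. Identical seeds give identical output.
#'
#' @param grid a \linkS4class{VolumeGrid}; every axis must have >= 3 voxels.
#' @param nStreamlines number of streamlines (>= 1).
#' @param seed integer seed.
#' @param nPoints points per streamline.
#' @param extent fraction of the bounding box spanned by the bundle.
#' @param jitterSD point jitter, mm.
#' @return a \linkS4class{Tractogram}.
#' @export
generateTractogram <- function(grid, nStreamlines, seed, nPoints = 40L,
                               extent = 0.92, jitterSD = 0.2) {
  if (any(grid@dim < 3L))
    stop("grid too small: every axis needs >= 3 voxels", call. = FALSE)
  if (nStreamlines < 1L) stop("nStreamlines must be >= 1", call. = FALSE)
  bb <- gridBoundingBox(grid)
  ctr <- colMeans(bb)
  half <- extent * (bb[2, ] - bb[1, ]) / 2
  tt <- seq(0, 1, length.out = nPoints)
  lo <- bb[1, ] + 1e-6 * (bb[2, ] - bb[1, ])
  hi <- bb[2, ] - 1e-6 * (bb[2, ] - bb[1, ])
  sl <- withSeed(seed, lapply(seq_len(nStreamlines), function(i) {
    ax <- sample.int(3L, 1L)
    p0 <- ctr + runif(3, -1, 1) * half
    p1 <- ctr + runif(3, -1, 1) * half
    p0[ax] <- ctr[ax] - half[ax]
    p1[ax] <- ctr[ax] + half[ax]
    pc <- ctr + runif(3, -0.7, 0.7) * half
    bez <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), pc) +
      outer(tt^2, p1)
    pts <- bez + matrix(rnorm(length(bez), 0, jitterSD), nrow(bez))
    pts <- pmin(pmax(pts, rep(lo, each = nrow(pts))),
                rep(hi, each = nrow(pts)))
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
    pts[keep, , drop = FALSE]
  }))
  Tractogram(sl, grid)
}

# 6-neighbourhood dilation / erosion helpers
dilate6 <- function(a) {
  out <- a
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    off <- integer(3); off[ax] <- s
    out <- out | shiftArray(a, off)
  }
  out
}
erode6 <- function(a) {
  out <- a
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    off <- integer(3); off[ax] <- s
    out <- out & shiftArray(a, off)
  }
  out
}

# rasterize a sphere of radius r (mm) around a world-space centre
rasterizeSphere <- function(grid, center, radius, centers = NULL) {
  if (is.null(centers)) centers <- voxelCentersWorld(grid)
  d2 <- (centers[, 1] - center[1])^2 + (centers[, 2] - center[2])^2 +
    (centers[, 3] - center[3])^2
  array(d2 <= radius^2, grid@dim)
}

#' Generate spherical lesions on tract-traversed voxels
#'
#' Lesion centres are drawn from voxels traversed by at least one reference
#' streamline (so every lesion disrupts something) and rasterized as spheres.
#' Spheres are kept mutually disjoint and non-adjacent (so PRL component
#' counts equal lesion counts); a colliding draw is resampled up to
#' \code{maxRetries} times before an explicit failure.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param tractogram the reference \linkS4class{Tractogram}.
#' @param nPRL,nNonPRL lesion counts per class.
#' @param radiusRange mm range of lesion radii.
#' @param seed integer seed.
#' @param maxRetries resampling attempts per lesion.
#' @param voxelIndex optional precomputed tractogram voxelization.
#' @return a \linkS4class{LesionSet}.
#' @export
generateLesions <- function(grid, tractogram, nPRL, nNonPRL,
                            radiusRange = c(3, 6), seed = 1L,
                            maxRetries = 200L, voxelIndex = NULL) {
  if (any(radiusRange <= 0)) stop("radii must be positive", call. = FALSE)
  if (is.null(voxelIndex)) voxelIndex <- voxelizeTractogram(tractogram)
  covered <- unique(unlist(voxelIndex))
  if ((nPRL + nNonPRL) > 0 && length(covered) == 0L)
    stop("no voxel is traversed by the tractogram", call. = FALSE)
  centers <- voxelCentersWorld(grid)
  prl <- array(FALSE, grid@dim)
  nonPrl <- array(FALSE, grid@dim)
  withSeed(seed, {
    blocked <- array(FALSE, grid@dim)   # placed lesions plus their 6-halo
    for (cls in c(rep("prl", nPRL), rep("non_prl", nNonPRL))) {
      done <- FALSE
      for (try in seq_len(maxRetries)) {
        ctr <- centers[covered[sample.int(length(covered), 1L)], ]
        r <- runif(1, radiusRange[1], radiusRange[2])
        sph <- rasterizeSphere(grid, ctr, r, centers)
        if (!any(sph & blocked)) {
          blocked <- blocked | dilate6(sph)
          if (cls == "prl") prl <- prl | sph else nonPrl <- nonPrl | sph
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("could not place all lesions without overlap after ",
             maxRetries, " retries", call. = FALSE)
    }
  })
  new("LesionSet", prl = prl, nonPrl = nonPrl, grid = grid)
}

#' @rdname LesionSet-class
#' @export
setMethod("allLesions", "LesionSet", function(x) x@prl | x@nonPrl)

#' @rdname LesionSet-class
#' @export
setMethod("prlMask", "LesionSet", function(x) x@prl)

#' @rdname LesionSet-class
#' @export
setMethod("nonPrlMask", "LesionSet", function(x) x@nonPrl)

#' @rdname grid3d
#' @export
setMethod("grid3d", "LesionSet", function(x) x@grid)

setMethod("show", "LesionSet", function(object) {
  cat(sprintf("LesionSet: %d PRL voxels, %d non-PRL voxels\n",
              sum(object@prl), sum(object@nonPrl)))
})

# synthetic anatomy: brain ellipsoid, gray/WM split, exclusion regions
syntheticAnatomy <- function(grid, wm) {
  bb <- gridBoundingBox(grid)
  ctr <- colMeans(bb)
  half <- (bb[2, ] - bb[1, ]) / 2
  centers <- voxelCentersWorld(grid)
  inEll <- function(semi) {
    array(((centers[, 1] - ctr[1]) / semi[1])^2 +
          ((centers[, 2] - ctr[2]) / semi[2])^2 +
          ((centers[, 3] - ctr[3]) / semi[3])^2 <= 1, grid@dim)
  }
  brain <- inEll(0.95 * half) | wm
  ventricles <- inEll(0.12 * half)
  cortexShell <- brain & !erode6(brain)
  list(brain = brain, gray = brain & !wm,
       exclusion = ventricles | cortexShell)
}

#' Generate a complete synthetic cohort
#'
#' Builds the shared normative tractogram, per-subject lesion sets (drawn on
#' tract-traversed voxels), ground-truth DVR fields, dynamic PET images from
#' the one-tissue forward model (white matter kinetically distinct from the
#' gray-like reference pool), healthy-control WM masks, exclusion regions and
#' a covariate table. Healthy controls carry no lesions and a flat WM DVR of
#' \code{1 + delta_s}; MS subjects add \code{effectSize x disruption} along
#' lesion-disrupted tracts, PRL-positive subjects an extra
#' \code{prlBoost x effectSize x PRL-disruption}. Covariates follow the
#' target cohort's direction: PRL-positive patients younger, about 60 percent
#' female, EDSS a half-point-discretised Gamma, subtype mix dominated by
#' relapsing-remitting disease in the PRL-positive group.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return an \linkS4class{MSCohort}.
#' @export
generateCohort <- function(config) {
  validObject(config)
  base <- config@seed
  grid <- VolumeGrid(config@gridDim, config@gridSpacing)
  schedule <- pkFrameSchedule()
  kinetics <- KineticParams(K1 = 0.1, k2 = 0.3, noiseCV = config@noiseCV)
  wmKinetics <- KineticParams(K1 = 0.05, k2 = 0.15)
  tract <- generateTractogram(grid, config@nStreamlines, subSeed(base, 1))
  voxelIndex <- voxelizeTractogram(tract)
  nThrough <- tabulate(unlist(voxelIndex), nbins = prod(grid@dim))
  wm <- array(nThrough > 0L, grid@dim)
  anat <- syntheticAnatomy(grid, wm)

  nHC <- config@nHC; nP <- config@nMSPRL; nN <- config@nMSNoPRL
  n <- nHC + nP + nN
  group <- c(rep("HC", nHC), rep("MS", nP + nN))
  prlPos <- c(rep(FALSE, nHC), rep(TRUE, nP), rep(FALSE, nN))
  ids <- sprintf("S%03d", seq_len(n))

  covars <- withSeed(subSeed(base, 2), {
    age <- numeric(n); sex <- character(n)
    edss <- rep(NA_real_, n); msType <- rep(NA_character_, n)
    delta <- rnorm(n, 0, config@subjectSD)
    for (i in seq_len(n)) {
      if (group[i] == "HC") {
        age[i] <- rnorm(1, 53, 10)
        sex[i] <- if (runif(1) < 0.4) "F" else "M"
      } else {
        age[i] <- if (prlPos[i]) rnorm(1, 40, 11) else rnorm(1, 53, 14)
        sex[i] <- if (runif(1) < 0.6) "F" else "M"
        edss[i] <- min(10, round(rgamma(1, shape = 1.6, scale = 1.8) * 2) / 2)
        msType[i] <- if (prlPos[i])
          sample(c("RR", "PP", "SP"), 1, prob = c(0.73, 0.12, 0.15))
        else sample(c("RR", "PP", "SP"), 1, prob = c(0.44, 0.11, 0.45))
      }
    }
    list(age = pmin(pmax(age, 18), 85), sex = sex, edss = edss,
         msType = msType, delta = delta)
  })

  hcWMMasks <- lapply(seq_len(nHC), function(i) withSeed(subSeed(base, 500 + i), {
    ring <- which(wm & !erode6(wm))
    drop <- ring[runif(length(ring)) < 0.3]
    m <- wm
    m[drop] <- FALSE
    m
  }))

  nPrlDraw <- withSeed(subSeed(base, 3), {
    list(prl = sample(config@prlCountRange[1]:config@prlCountRange[2], n,
                      replace = TRUE),
         non = sample(config@nonPrlCountRange[1]:config@nonPrlCountRange[2],
                      n, replace = TRUE))
  })

  lesions <- list(); dynamics <- list(); dvrTrue <- list()
  for (i in seq_len(n)) {
    id <- ids[i]
    dvr <- array(NA_real_, grid@dim)
    dvr[anat$gray] <- 1
    dvr[wm] <- 1 + covars$delta[i]
    if (group[i] == "MS") {
      les <- generateLesions(grid, tract,
                             nPRL = if (prlPos[i]) nPrlDraw$prl[i] else 0L,
                             nNonPRL = nPrlDraw$non[i],
                             radiusRange = config@lesionRadiusRange,
                             seed = subSeed(base, 1000 + i),
                             voxelIndex = voxelIndex)
      dAll <- disruptionScore(computeDisruptionMap(tract, allLesions(les),
                                                   voxelIndex = voxelIndex))
      elev <- config@effectSize * dAll
      if (prlPos[i]) {
        dPrl <- disruptionScore(computeDisruptionMap(tract, prlMask(les),
                                                     voxelIndex = voxelIndex))
        elev <- elev + config@prlBoost * config@effectSize * dPrl
      }
      dvr[wm] <- dvr[wm] + elev[wm]
      lesions[[id]] <- les
    }
    dvr <- pmax(dvr, 0)
    dynamics[[id]] <- simulateDynamicPET(grid, dvr, kinetics, schedule,
                                         seed = subSeed(base, 2000 + i),
                                         tissueMask = wm,
                                         tissueParams = wmKinetics)
    dvrTrue[[id]] <- dvr
  }

  subjectsDf <- data.frame(
    id = ids, group = group, prl_positive = prlPos, age = covars$age,
    sex = covars$sex, edss = covars$edss, ms_type = covars$msType,
    stringsAsFactors = FALSE)

  new("MSCohort", tractogram = tract, subjects = subjectsDf,
      lesions = lesions, dynamics = dynamics, dvrTrue = dvrTrue,
      hcWMMasks = hcWMMasks, wmMask = wm, grayMask = anat$gray,
      brainMask = anat$brain, exclusionMask = anat$exclusion,
      schedule = schedule, kinetics = kinetics, config = config)
}

#' @rdname MSCohort-class
#' @export
setMethod("subjects", "MSCohort", function(x) x@subjects)

#' @rdname grid3d
#' @export
setMethod("grid3d", "MSCohort", function(x) x@tractogram@grid)

setMethod("show", "MSCohort", function(object) {
  s <- object@subjects
  cat(sprintf(
    "MSCohort: %d subjects (%d HC, %d PRL+, %d PRL-), %d streamlines, seed %d\n",
    nrow(s), sum(s$group == "HC"), sum(s$prl_positive),
    sum(s$group == "MS" & !s$prl_positive),
    nStreamlines(object@tractogram), object@config@seed))
})
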