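#' Build the group white-matter mask from healthy-control masks
#'
#' A voxel is kept iff it is present in \emph{strictly more than}
#' \code{threshold} of the HC masks (so with 11 HCs and the default 0.5,
#' presence in 6 masks keeps a voxel and presence in 5 drops it).
#'
#' @param hcMasks list of logical arrays on one grid.
#' @param grid the common \linkS4class{VolumeGrid}.
#' @param threshold proportion, default 0.5.
#' @return a \linkS4class{GroupWMMask}.
#' @export
buildGroupWMMask <- function(hcMasks, grid, threshold = 0.5) {
  if (length(hcMasks) < 1L) stop("need at least one HC mask", call. = FALSE)
  for (m in hcMasks) checkMask(m, grid, "HC mask")
  prob <- Reduce(`+`, lapply(hcMasks, function(m) m * 1)) / length(hcMasks)
  new("GroupWMMask", probability = prob, mask = prob > threshold,
      threshold = threshold, grid = grid)
}

setMethod("show", "GroupWMMask", function(object) {
  cat(sprintf("GroupWMMask: %d voxels above threshold %.2f\n",
              sum(object@mask), object@threshold))
})

#' @rdname grid3d
#' @export
setMethod("grid3d", "GroupWMMask", function(x) x@grid)

#' Remove mask voxels close to an exclusion region
#'
#' Removes every mask voxel whose centre lies within \code{distance} mm
#' (Euclidean, anisotropy-aware, centre-to-centre) of any exclusion-region
#' voxel centre — the partial-volume guard band around ventricles and gray
#' matter. With \code{distance = 0} only voxels overlapping the exclusion
#' region itself are removed.
#'
#' @param mask,exclusionMask logical arrays on the grid.
#' @param grid a \linkS4class{VolumeGrid}.
#' @param distance mm, default 1.
#' @return the pruned logical mask.
#' @export
excludeBoundary <- function(mask, exclusionMask, grid, distance = 1) {
  checkMask(mask, grid)
  checkMask(exclusionMask, grid, "exclusionMask")
  if (distance < 0) stop("distance must be >= 0", call. = FALSE)
  sp <- grid@spacing
  r <- floor(distance / sp)
  offs <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  d2 <- (offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 + (offs[, 3] * sp[3])^2
  offs <- offs[d2 <= distance^2 + 1e-12, , drop = FALSE]
  near <- array(FALSE, grid@dim)
  for (i in seq_len(nrow(offs))) near <- near | shiftArray(exclusionMask, offs[i, ])
  mask & !near
}

# shift a 3-D logical array by integer offset, padding with FALSE
shiftArray <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o) }
    else { dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Standardise a DVR map against a healthy-control cohort
#'
#' Per voxel, \code{z = (DVR - mean_HC) / sd_HC} with the sample (n-1)
#' standard deviation, computed over the analysis mask. Voxels where the HC
#' standard deviation falls below \code{1e-6 x |mean_HC|} (degenerate,
#' typically noiseless synthetic data) or where fewer than 2 HC values are
#' defined are left undefined.
#'
#' @param subjectDVR the subject's \linkS4class{DVRMap}.
#' @param hcDVRs list of at least 2 HC \linkS4class{DVRMap}s.
#' @param analysisMask logical array restricting the computation.
#' @return a \linkS4class{ZScoreMap}.
#' @export
zscoreMap <- function(subjectDVR, hcDVRs, analysisMask) {
  grid <- subjectDVR@grid
  if (length(hcDVRs) < 2L) stop("need at least 2 HC maps", call. = FALSE)
  for (h in hcDVRs) stopIfGridMismatch(grid, h@grid, "subject and HC maps")
  checkMask(analysisMask, grid, "analysisMask")
  idx <- which(as.logical(analysisMask))
  H <- matrix(vapply(hcDVRs, function(h) h@values[idx],
                     numeric(length(idx))), nrow = length(idx))
  nOk <- rowSums(!is.na(H))
  mu <- rowMeans(H, na.rm = TRUE)
  dev <- (H - mu)^2
  sdv <- sqrt(rowSums(dev, na.rm = TRUE) / pmax(nOk - 1L, 1L))
  sdv[nOk < 2L] <- NA_real_
  ok <- nOk >= 2 & !is.na(sdv) & sdv > 1e-6 * abs(mu)
  z <- array(NA_real_, grid@dim)
  hcMean <- array(NA_real_, grid@dim)
  hcSd <- array(NA_real_, grid@dim)
  zv <- (subjectDVR@values[idx] - mu) / sdv
  zv[!ok] <- NA_real_
  z[idx] <- zv
  hcMean[idx] <- mu
  hcSd[idx] <- sdv
  new("ZScoreMap", z = z, hcMean = hcMean, hcSd = hcSd, grid = grid)
}

#' @rdname ZScoreMap-class
#' @export
setMethod("zValues", "ZScoreMap", function(x) x@z)

#' @rdname grid3d
#' @export
setMethod("grid3d", "ZScoreMap", function(x) x@grid)

setMethod("show", "ZScoreMap", function(object) {
  ok <- !is.na(object@z)
  cat(sprintf("ZScoreMap: %d voxels defined, mean z %.3f\n",
              sum(ok), mean(object@z[ok])))
})

#' Per-stratum mean z-score
#'
#' Unweighted mean of defined z values over the voxels of each disruption
#' stratum (and, when present, each sweep bin). Empty strata yield NA, not
#' zero. The voxel count per stratum is reported alongside.
#'
#' @param zmap a \linkS4class{ZScoreMap}.
#' @param strata a \linkS4class{DisruptionStrata} on the same grid.
#' @return a data.frame with columns \code{stratum}, \code{mean_z},
#'   \code{n_voxels}; trio rows (none/low/mid/high) first, then sweep-bin
#'   rows when the strata carry them.
#' @export
stratifiedMeanZ <- function(zmap, strata) {
  stopIfGridMismatch(zmap@grid, strata@grid, "z map and strata")
  z <- zmap@z
  def <- !is.na(z)
  rows <- lapply(c("none", "low", "mid", "high"), function(lv) {
    inS <- def & !is.na(strata@labels) & strata@labels == lv
    data.frame(stratum = lv,
               mean_z = if (any(inS)) mean(z[inS]) else NA_real_,
               n_voxels = sum(inS))
  })
  out <- do.call(rbind, rows)
  if (length(strata@sweepBin)) {
    labs <- sweepBinLabels(strata@binEdges)
    srows <- lapply(seq_along(labs), function(b) {
      inS <- def & !is.na(strata@sweepBin) & strata@sweepBin == b
      data.frame(stratum = labs[b],
                 mean_z = if (any(inS)) mean(z[inS]) else NA_real_,
                 n_voxels = sum(inS))
    })
    out <- rbind(out, do.call(rbind, srows))
  }
  out
}
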