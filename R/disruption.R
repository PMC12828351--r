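#' Construct a tractogram
#'
#' @param streamlines list of n x 3 matrices of world (mm) coordinates.
#' @param grid the \linkS4class{VolumeGrid} the streamlines are scored on.
#' @return a \linkS4class{Tractogram}.
#' @export
Tractogram <- function(streamlines, grid) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s); storage.mode(s) <- "double"; dimnames(s) <- NULL; s
  })
  new("Tractogram", streamlines = streamlines, grid = grid)
}

#' @rdname Tractogram-class
#' @export
setMethod("streamlines", "Tractogram", function(x) x@streamlines)

#' @rdname Tractogram-class
#' @export
setMethod("nStreamlines", "Tractogram", function(x) length(x@streamlines))

#' @rdname grid3d
#' @export
setMethod("grid3d", "Tractogram", function(x) x@grid)

setMethod("show", "Tractogram", function(object) {
  np <- vapply(object@streamlines, nrow, 1L)
  cat(sprintf("Tractogram: %d streamlines (%s points each) on %s grid\n",
              length(object@streamlines),
              if (length(np)) paste0(min(np), "-", max(np)) else "0",
              paste(object@grid@dim, collapse = " x ")))
})

#' Voxels traversed by a streamline
#'
#' Exact segment-grid traversal: every voxel whose volume the polyline's
#' segments cross is returned, not merely the voxels containing the sample
#' points. Voxel ownership is half-open (\code{[i-0.5, i+0.5)} in continuous
#' 0-based voxel coordinates): a point exactly on a shared face belongs to
#' the higher-index voxel. Voxels outside the grid are dropped, so the result
#' can be empty.
#'
#' @param streamline an n x 3 matrix of world (mm) coordinates.
#' @param grid a \linkS4class{VolumeGrid}.
#' @return an m x 3 integer matrix of 1-based voxel indices (R array
#'   convention), one row per traversed voxel, ordered by linear index.
#' @export
voxelizeStreamline <- function(streamline, grid) {
  lin <- voxelizeLinear(streamline, grid)
  arrayInd(lin, grid@dim)
}

# 1-based linear indices of voxels traversed by one streamline
voxelizeLinear <- function(streamline, grid) {
  v <- worldToVoxelCoords(grid, streamline)
  .cppVoxelizePolyline(v, grid@dim)
}

#' Voxelize every streamline of a tractogram once
#'
#' Precomputes the traversed-voxel sets so that repeated
#' \code{\link{computeDisruptionMap}} calls over different lesion masks (via
#' its \code{voxelIndex} argument) skip the geometric traversal.
#'
#' @param tractogram a \linkS4class{Tractogram}.
#' @return a list with one sorted vector of 1-based linear voxel indices per
#'   streamline.
#' @export
voxelizeTractogram <- function(tractogram) {
  vlist <- lapply(tractogram@streamlines,
                  function(s) worldToVoxelCoords(tractogram@grid, s))
  .cppVoxelizeTractogram(vlist, tractogram@grid@dim)
}

#' Does a streamline pass through a mask?
#'
#' @param streamline an n x 3 matrix of world (mm) coordinates.
#' @param mask logical array on the grid.
#' @param grid a \linkS4class{VolumeGrid}.
#' @return TRUE iff any traversed voxel is in the mask.
#' @export
streamlineIntersects <- function(streamline, mask, grid) {
  checkMask(mask, grid)
  any(mask[voxelizeLinear(streamline, grid)])
}

#' Per-voxel disruption score from a tractogram and a lesion mask
#'
#' For every voxel, counts the reference streamlines traversing it
#' (\code{nThrough}) and those among them that also pass through the lesion
#' mask (\code{nLesioned}); the disruption score is their ratio, a value in
#' [0, 1] where 0 means no disruption and 1 complete disruption. Voxels with
#' no traversing streamline are undefined (NA score) and excluded from all
#' downstream averages. Each streamline is counted once per voxel it
#' traverses, unweighted by intra-voxel length.
#'
#' @param tractogram a non-empty \linkS4class{Tractogram}.
#' @param mask logical lesion mask on the grid.
#' @param grid the grid; defaults to the tractogram's.
#' @param voxelIndex optional precomputed result of the internal tractogram
#'   voxelization (used by the pipeline to score many masks against one
#'   tractogram without re-traversing it).
#' @return a \linkS4class{DisruptionMap}.
#' @export
computeDisruptionMap <- function(tractogram, mask, grid = grid3d(tractogram),
                                 voxelIndex = NULL) {
  if (nStreamlines(tractogram) == 0L)
    stop("tractogram is empty; nothing to score", call. = FALSE)
  stopIfGridMismatch(grid, tractogram@grid, "mask grid and tractogram grid")
  checkMask(mask, grid)
  if (is.null(voxelIndex)) voxelIndex <- voxelizeTractogram(tractogram)
  nv <- prod(grid@dim)
  nThrough <- tabulate(unlist(voxelIndex), nbins = nv)
  hit <- vapply(voxelIndex, function(v) length(v) > 0L && any(mask[v]),
                logical(1))
  nLesioned <- tabulate(unlist(c(voxelIndex[hit], list(integer(0)))),
                        nbins = nv)
  new("DisruptionMap",
      nThrough = array(as.integer(nThrough), grid@dim),
      nLesioned = array(as.integer(nLesioned), grid@dim),
      grid = grid)
}

#' @rdname disruptionScore
#' @export
setMethod("disruptionScore", "DisruptionMap", function(x) {
  s <- x@nLesioned / x@nThrough
  s[x@nThrough == 0L] <- NA_real_
  array(s, x@grid@dim)
})

#' @rdname grid3d
#' @export
setMethod("grid3d", "DisruptionMap", function(x) x@grid)

setMethod("show", "DisruptionMap", function(object) {
  s <- disruptionScore(object)
  cat(sprintf(
    "DisruptionMap: %d/%d voxels defined, score range [%.3g, %.3g]\n",
    sum(!is.na(s)), length(s), suppressWarnings(min(s, na.rm = TRUE)),
    suppressWarnings(max(s, na.rm = TRUE))))
})

#' Stratify voxels by disruption level
#'
#' Trio labels follow the closure none = \{0\}, low = (0, 0.1],
#' mid = (0.1, 0.9), high = [0.9, 1], so every defined score receives exactly
#' one label. With \code{sweep = TRUE} each defined voxel with score > 0 is
#' also assigned to one of the ten half-open bins (l, l + 0.1] for
#' l = 0, 0.1, ..., 0.9, supporting the disruption-level sweep analyses.
#'
#' @param map a \linkS4class{DisruptionMap}.
#' @param sweep also compute the 0.1-step sweep bins?
#' @return a \linkS4class{DisruptionStrata}.
#' @export
stratifyDisruption <- function(map, sweep = FALSE) {
  s <- disruptionScore(map)
  lab <- array(NA_character_, dim(s))
  def <- !is.na(s)
  lab[def & s == 0] <- "none"
  lab[def & s > 0 & s <= 0.1] <- "low"
  lab[def & s > 0.1 & s < 0.9] <- "mid"
  lab[def & s >= 0.9] <- "high"
  edges <- seq(0, 1, by = 0.1)
  if (sweep) {
    bin <- array(NA_integer_, dim(s))
    pos <- def & s > 0
    # left-open intervals: bin i covers (edges[i], edges[i+1]]
    bin[pos] <- findInterval(s[pos], edges, left.open = TRUE)
    sweepBin <- bin
  } else {
    sweepBin <- array(integer(0), c(0L, 0L, 0L))
  }
  new("DisruptionStrata", labels = lab, sweepBin = sweepBin,
      binEdges = edges, grid = map@grid)
}

#' @rdname grid3d
#' @export
setMethod("grid3d", "DisruptionStrata", function(x) x@grid)

setMethod("show", "DisruptionStrata", function(object) {
  tb <- table(factor(object@labels, c("none", "low", "mid", "high")))
  cat("DisruptionStrata:", paste(names(tb), tb, sep = "=", collapse = " "),
      sprintf("undefined=%d\n", sum(is.na(object@labels))))
})

# stratum labels for the sweep bins, e.g. "(0.1,0.2]"
sweepBinLabels <- function(edges = seq(0, 1, by = 0.1)) {
  n <- length(edges) - 1L
  sprintf("(%.1f,%.1f]", edges[-(n + 1L)], edges[-1L])
}
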