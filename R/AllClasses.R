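#' @useDynLib tractopet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats coef cor lm median model.matrix p.adjust pt quantile
#'   rbinom rgamma rnorm runif sd setNames t.test var complete.cases
#' @importFrom utils read.csv write.csv
NULL

#' Voxel grid shared by all volumes, masks and tractograms
#'
#' A \code{VolumeGrid} holds the array dimensions, voxel spacing (mm) and the
#' 4x4 voxel-to-world affine that place every image of an analysis in one
#' common millimetre space. World coordinates of the \emph{centre} of the
#' voxel with 0-based index \code{(i,j,k)} are
#' \code{affine \%*\% c(i,j,k,1)}. A voxel owns the half-open cube
#' \code{[i-0.5, i+0.5)} on each (0-based, continuous) axis, so a point
#' exactly on a shared face belongs to the higher-index voxel.
#'
#' @slot dim integer(3), voxels per axis.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot affine 4x4 voxel-to-world transform (mm).
#' @export
setClass("VolumeGrid",
  representation(dim = "integer", spacing = "numeric", affine = "matrix"))

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be 3 integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (!identical(base::dim(object@affine), c(4L, 4L)) ||
      any(!is.finite(object@affine)))
    msg <- c(msg, "affine must be a finite 4x4 matrix")
  else if (abs(det(object@affine)) < .Machine$double.eps * 64)
    msg <- c(msg, "affine must be invertible")
  if (length(msg)) msg else TRUE
})

#' Set of streamlines in world (mm) coordinates tied to a grid
#'
#' Stand-in container for a normative tractography reference set: a list of
#' polylines (n x 3 matrices of mm coordinates, n >= 2, consecutive points
#' distinct) plus the \linkS4class{VolumeGrid} they are scored against. The
#' container may be empty (e.g. after reading an empty file); disruption
#' scoring requires at least one streamline.
#'
#' @slot streamlines list of numeric matrices (n_i x 3), mm coordinates.
#' @slot grid a \linkS4class{VolumeGrid}.
#' @export
setClass("Tractogram",
  representation(streamlines = "list", grid = "VolumeGrid"))

setValidity("Tractogram", function(object) {
  for (s in object@streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L)
      return("each streamline must be an n x 3 matrix")
    if (nrow(s) < 2L) return("each streamline needs >= 2 points")
    if (any(!is.finite(s))) return("streamline coordinates must be finite")
    d <- diff(s)
    if (any(rowSums(abs(d)) == 0))
      return("consecutive streamline points must be distinct")
  }
  TRUE
})

#' Binary lesion masks split into PRL and non-PRL components
#'
#' Holds the paramagnetic-rim-lesion (PRL) and non-PRL masks on a common
#' grid. The all-lesion mask is their union; the two components must be
#' disjoint.
#'
#' @slot prl,nonPrl logical arrays with dim equal to the grid dim.
#' @slot grid a \linkS4class{VolumeGrid}.
#' @export
setClass("LesionSet",
  representation(prl = "array", nonPrl = "array", grid = "VolumeGrid"))

setValidity("LesionSet", function(object) {
  gd <- object@grid@dim
  if (!identical(base::dim(object@prl), gd) ||
      !identical(base::dim(object@nonPrl), gd))
    return("masks must match the grid dimensions")
  if (!is.logical(object@prl) || !is.logical(object@nonPrl))
    return("masks must be logical arrays")
  if (any(object@prl & object@nonPrl))
    return("prl and non-prl masks must be disjoint")
  TRUE
})

#' Dynamic PET frame schedule
#'
#' Contiguous acquisition frames: \code{starts[i+1] == starts[i] +
#' durations[i]}, first start 0. Stored in seconds; mid-times are reported in
#' minutes, the unit used by kinetic analysis.
#'
#' @slot starts,durations numeric vectors, seconds.
#' @export
setClass("FrameSchedule",
  representation(starts = "numeric", durations = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@starts; d <- object@durations
  if (length(s) < 1L || length(s) != length(d))
    return("starts and durations must be non-empty and equally long")
  if (any(d <= 0)) return("durations must be positive")
  if (s[1] != 0) return("first frame must start at 0")
  if (length(s) > 1L &&
      max(abs(s[-1] - (s[-length(s)] + d[-length(d)]))) > 1e-9)
    return("frames must be contiguous")
  TRUE
})

#' Time-activity curve on a frame schedule
#'
#' @slot schedule a \linkS4class{FrameSchedule}.
#' @slot values activity concentration per frame (arbitrary units).
#' @export
setClass("TAC",
  representation(schedule = "FrameSchedule", values = "numeric"))

setValidity("TAC", function(object) {
  if (length(object@values) != length(object@schedule@starts))
    return("values must have one entry per frame")
  TRUE
})

#' Kinetic parameters of the one-tissue forward model
#'
#' \code{K1} (per-min delivery) and \code{k2} (per-min clearance) define the
#' reference-tissue kinetics; \code{dvrTrue} is a global multiplier applied
#' to the per-voxel DVR field; \code{noiseCV} is the fractional (multiplicative
#' Gaussian) noise level at the nominal 300-s frame duration.
#'
#' @slot K1,k2,dvrTrue,noiseCV numeric scalars.
#' @export
setClass("KineticParams",
  representation(K1 = "numeric", k2 = "numeric", dvrTrue = "numeric",
                 noiseCV = "numeric"))

setValidity("KineticParams", function(object) {
  if (object@K1 <= 0 || object@k2 <= 0) return("K1 and k2 must be positive")
  if (object@dvrTrue < 0) return("dvrTrue must be >= 0")
  if (object@noiseCV < 0) return("noiseCV must be >= 0")
  TRUE
})

#' Predefined kinetic class curves for supervised reference extraction
#'
#' Area-normalised basis time-activity curves (one column per tissue class:
#' gray-like low binding, white-like, high-binding, blood-like) used to score
#' every voxel's curve by non-negative least squares; the class named by
#' \code{lowBinding} defines the reference pool.
#'
#' @slot schedule a \linkS4class{FrameSchedule}.
#' @slot curves numeric matrix, frames x classes, each column area-normalised.
#' @slot lowBinding name of the low-binding (reference) class.
#' @export
setClass("KineticClassSet",
  representation(schedule = "FrameSchedule", curves = "matrix",
                 lowBinding = "character"))

setValidity("KineticClassSet", function(object) {
  if (ncol(object@curves) < 2L) return("need at least 2 kinetic classes")
  if (is.null(colnames(object@curves))) return("curves must have class names")
  if (!(object@lowBinding %in% colnames(object@curves)))
    return("lowBinding must name a column of curves")
  if (nrow(object@curves) != length(object@schedule@starts))
    return("curves must have one row per frame")
  TRUE
})

#' 4-D dynamic PET image
#'
#' @slot data 4-D numeric array, grid dim x frames.
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot schedule a \linkS4class{FrameSchedule}.
#' @export
setClass("DynamicImage",
  representation(data = "array", grid = "VolumeGrid",
                 schedule = "FrameSchedule"))

setValidity("DynamicImage", function(object) {
  expected <- c(object@grid@dim, length(object@schedule@starts))
  if (!identical(base::dim(object@data), expected))
    return("data must be grid dim x number of frames")
  TRUE
})

#' Per-voxel streamline disruption counts and score
#'
#' For every voxel, \code{nThrough} counts reference streamlines traversing
#' it and \code{nLesioned} counts those that also pass through the lesion
#' mask. The disruption score is \code{nLesioned / nThrough} in [0, 1],
#' undefined (NA) exactly where no streamline passes.
#'
#' @slot nThrough,nLesioned integer arrays on the grid.
#' @slot grid a \linkS4class{VolumeGrid}.
#' @export
setClass("DisruptionMap",
  representation(nThrough = "array", nLesioned = "array",
                 grid = "VolumeGrid"))

setValidity("DisruptionMap", function(object) {
  gd <- object@grid@dim
  if (!identical(base::dim(object@nThrough), gd) ||
      !identical(base::dim(object@nLesioned), gd))
    return("count arrays must match the grid dimensions")
  if (any(object@nLesioned < 0) || any(object@nThrough < 0))
    return("counts must be non-negative")
  if (any(object@nLesioned > object@nThrough))
    return("nLesioned cannot exceed nThrough")
  TRUE
})

#' Disruption-level voxel categories
#'
#' Trio labels: \code{none} (score exactly 0), \code{low} (0 < score <= 0.1),
#' \code{high} (0.9 <= score <= 1), \code{mid} (everything between), and
#' \code{NA} where the score is undefined. When built with \code{sweep =
#' TRUE}, \code{sweepBin} additionally assigns each defined voxel with score
#' > 0 to one of the ten half-open bins \code{(l, l+0.1]}, \code{l = 0, 0.1,
#' ..., 0.9}.
#'
#' @slot labels character array (none/low/mid/high, NA undefined).
#' @slot sweepBin integer array (bin index 1..10, NA where score is 0 or
#'   undefined), or a 0-length array when no sweep was requested.
#' @slot binEdges numeric, the sweep bin edges.
#' @slot grid a \linkS4class{VolumeGrid}.
#' @export
setClass("DisruptionStrata",
  representation(labels = "array", sweepBin = "array", binEdges = "numeric",
                 grid = "VolumeGrid"))

#' Voxelwise distribution volume ratio map with fit quality
#'
#' @slot values numeric array of DVR estimates (NA where the fit failed).
#' @slot r2 numeric array of Logan-line R-squared values (NA where failed).
#' @slot grid a \linkS4class{VolumeGrid}.
#' @export
setClass("DVRMap",
  representation(values = "array", r2 = "array", grid = "VolumeGrid"))

setValidity("DVRMap", function(object) {
  gd <- object@grid@dim
  if (!identical(base::dim(object@values), gd) ||
      !identical(base::dim(object@r2), gd))
    return("values and r2 must match the grid dimensions")
  TRUE
})

#' Healthy-control-referenced z-score map
#'
#' @slot z numeric array of standardised DVR values (NA outside the analysis
#'   mask or where the HC standard deviation is degenerate).
#' @slot hcMean,hcSd numeric arrays of the per-voxel HC reference moments.
#' @slot grid a \linkS4class{VolumeGrid}.
#' @export
setClass("ZScoreMap",
  representation(z = "array", hcMean = "array", hcSd = "array",
                 grid = "VolumeGrid"))

#' Group white-matter mask built from healthy-control masks
#'
#' @slot probability numeric array, fraction of HC masks containing each voxel.
#' @slot mask logical array, probability strictly above the threshold.
#' @slot threshold the proportion used.
#' @slot grid a \linkS4class{VolumeGrid}.
#' @export
setClass("GroupWMMask",
  representation(probability = "array", mask = "array", threshold = "numeric",
                 grid = "VolumeGrid"))

#' Synthetic cohort configuration
#'
#' Defaults mirror the study design the pipeline targets: 11 healthy
#' controls, 26 PRL-positive and 18 PRL-negative MS patients; the planted
#' effect adds \code{effectSize * disruption} to the white-matter DVR of MS
#' subjects, with an extra \code{prlBoost * effectSize * PRL-disruption} term
#' in PRL-positive subjects.
#'
#' @slot nHC,nMSPRL,nMSNoPRL subject counts.
#' @slot effectSize additive DVR elevation per unit all-lesion disruption.
#' @slot prlBoost extra elevation per unit PRL disruption, as a multiple of
#'   \code{effectSize} (PRL-positive subjects only).
#' @slot subjectSD SD of the per-subject white-matter DVR random effect.
#' @slot noiseCV fractional PET noise at 300-s frames.
#' @slot prlCountRange,nonPrlCountRange integer ranges for lesion counts.
#' @slot lesionRadiusRange mm range for lesion radii.
#' @slot nStreamlines size of the synthetic normative tractogram.
#' @slot gridDim,gridSpacing grid geometry.
#' @slot seed integer; reproducibly determines every draw.
#' @export
setClass("CohortConfig",
  representation(nHC = "integer", nMSPRL = "integer", nMSNoPRL = "integer",
                 effectSize = "numeric", prlBoost = "numeric",
                 subjectSD = "numeric", noiseCV = "numeric",
                 prlCountRange = "integer", nonPrlCountRange = "integer",
                 lesionRadiusRange = "numeric", nStreamlines = "integer",
                 gridDim = "integer", gridSpacing = "numeric",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (any(c(object@nHC, object@nMSPRL, object@nMSNoPRL) < 0L))
    msg <- c(msg, "subject counts must be >= 0")
  if (!is.finite(object@effectSize)) msg <- c(msg, "effectSize must be finite")
  if (object@subjectSD < 0 || object@noiseCV < 0)
    msg <- c(msg, "subjectSD and noiseCV must be >= 0")
  if (length(object@prlCountRange) != 2L || any(object@prlCountRange < 0L) ||
      diff(object@prlCountRange) < 0L)
    msg <- c(msg, "prlCountRange must be a non-decreasing pair >= 0")
  if (length(object@nonPrlCountRange) != 2L ||
      any(object@nonPrlCountRange < 0L) || diff(object@nonPrlCountRange) < 0L)
    msg <- c(msg, "nonPrlCountRange must be a non-decreasing pair >= 0")
  if (length(object@lesionRadiusRange) != 2L ||
      any(object@lesionRadiusRange <= 0) || diff(object@lesionRadiusRange) < 0)
    msg <- c(msg, "lesionRadiusRange must be a positive non-decreasing pair")
  if (object@nStreamlines < 1L) msg <- c(msg, "nStreamlines must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A complete synthetic cohort
#'
#' Produced by \code{\link{generateCohort}}: the shared normative tractogram,
#' per-subject lesion masks and dynamic PET images, the subject covariate
#' table, the ground-truth DVR fields, healthy-control WM masks, the tissue
#' maps used by the forward model and full provenance (config and seed).
#'
#' @slot tractogram the shared \linkS4class{Tractogram}.
#' @slot subjects data.frame: id, group, prl_positive, age, sex, edss, ms_type.
#' @slot lesions named list of \linkS4class{LesionSet} (MS subjects).
#' @slot dynamics named list of \linkS4class{DynamicImage} (all subjects).
#' @slot dvrTrue named list of ground-truth DVR arrays (all subjects).
#' @slot hcWMMasks list of logical WM-mask arrays, one per HC.
#' @slot wmMask,grayMask,brainMask,exclusionMask logical arrays on the grid.
#' @slot schedule the \linkS4class{FrameSchedule} used.
#' @slot kinetics the reference \linkS4class{KineticParams}.
#' @slot config the \linkS4class{CohortConfig} that generated everything.
#' @export
setClass("MSCohort",
  representation(tractogram = "Tractogram", subjects = "data.frame",
                 lesions = "list", dynamics = "list", dvrTrue = "list",
                 hcWMMasks = "list", wmMask = "array", grayMask = "array",
                 brainMask = "array", exclusionMask = "array",
                 schedule = "FrameSchedule", kinetics = "KineticParams",
                 config = "CohortConfig"))
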