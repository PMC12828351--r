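#' @rdname VolumeGrid-class
#' @param x an object.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("gridAffine", function(x) standardGeneric("gridAffine"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname Tractogram-class
#' @param x an object.
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' @rdname Tractogram-class
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))

#' Grid accessor shared by gridded containers
#' @param x an object holding a \linkS4class{VolumeGrid}.
#' @export
setGeneric("grid3d", function(x) standardGeneric("grid3d"))

#' @rdname FrameSchedule-class
#' @param x an object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))

#' Frame mid-times in minutes
#' @param x a \linkS4class{FrameSchedule} or an object carrying one.
#' @export
setGeneric("frameMidTimes", function(x) standardGeneric("frameMidTimes"))

#' @rdname TAC-class
#' @param x an object.
#' @export
setGeneric("tacValues", function(x) standardGeneric("tacValues"))

#' @rdname LesionSet-class
#' @param x a \linkS4class{LesionSet}.
#' @export
setGeneric("allLesions", function(x) standardGeneric("allLesions"))

#' @rdname LesionSet-class
#' @export
setGeneric("prlMask", function(x) standardGeneric("prlMask"))

#' @rdname LesionSet-class
#' @export
setGeneric("nonPrlMask", function(x) standardGeneric("nonPrlMask"))

#' Per-voxel disruption score
#'
#' The fraction of reference streamlines through each voxel that also pass
#' through the lesion mask; NA where no streamline passes.
#' @param x a \linkS4class{DisruptionMap}.
#' @export
setGeneric("disruptionScore", function(x) standardGeneric("disruptionScore"))

#' @rdname DVRMap-class
#' @param x an object.
#' @export
setGeneric("dvrValues", function(x) standardGeneric("dvrValues"))

#' @rdname ZScoreMap-class
#' @param x an object.
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' @rdname MSCohort-class
#' @param x an \linkS4class{MSCohort}.
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))
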