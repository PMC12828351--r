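#' Write a volume (3-D or 4-D) to NIfTI-1
#'
#' The grid affine is stored in both the sform and qform; data are written as
#' float64 so values round-trip exactly. 4-D images should be accompanied by
#' a frame-schedule sidecar (\code{\link{writeFrameSchedule}}).
#'
#' @param data numeric or logical 3-D/4-D array (first three dims must match
#'   the grid).
#' @param grid a \linkS4class{VolumeGrid}.
#' @param path output path, \code{.nii} or \code{.nii.gz}.
#' @return the path, invisibly.
#' @export
writeVolume <- function(data, grid, path) {
  if (!identical(dim(data)[1:3], grid@dim))
    stop("data does not match the grid dimensions", call. = FALSE)
  if (is.logical(data)) data <- data * 1
  im <- RNifti::asNifti(data)
  RNifti::pixdim(im) <- grid@spacing
  aff <- structure(grid@affine, code = 2L)
  RNifti::sform(im) <- aff
  RNifti::qform(im) <- aff
  RNifti::writeNifti(im, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI volume together with its grid
#'
#' @param path a \code{.nii} or \code{.nii.gz} file.
#' @return a list with \code{data} (numeric array) and \code{grid}
#'   (\linkS4class{VolumeGrid} from the stored affine).
#' @export
readVolume <- function(path) {
  im <- RNifti::readNifti(path)
  aff <- matrix(unclass(RNifti::xform(im)), 4, 4)
  d <- dim(im)
  grid <- new("VolumeGrid", dim = as.integer(d[1:3]),
              spacing = as.numeric(RNifti::pixdim(im)[1:3]), affine = aff)
  list(data = array(as.numeric(im), d), grid = grid)
}

#' Read several volumes that must share one grid
#'
#' @param paths NIfTI files.
#' @return list of \code{readVolume} results; errors (naming both files and
#'   printing both affines) if any affine disagrees with the first.
#' @export
readVolumes <- function(paths) {
  vols <- lapply(paths, readVolume)
  for (i in seq_along(vols)[-1]) {
    if (!sameGrid(vols[[1]]$grid, vols[[i]]$grid))
      stop(sprintf(
        "grid mismatch between '%s' and '%s':\naffine A:\n%s\naffine B:\n%s",
        paths[1], paths[i],
        paste(capture.output(print(vols[[1]]$grid@affine)), collapse = "\n"),
        paste(capture.output(print(vols[[i]]$grid@affine)), collapse = "\n")),
        call. = FALSE)
  }
  vols
}

#' Write / read a frame-schedule JSON sidecar
#'
#' @param schedule a \linkS4class{FrameSchedule}.
#' @param path a \code{.json} file.
#' @return \code{writeFrameSchedule}: the path, invisibly;
#'   \code{readFrameSchedule}: a \linkS4class{FrameSchedule}.
#' @export
writeFrameSchedule <- function(schedule, path) {
  jsonlite::write_json(list(frame_starts_s = schedule@starts,
                            frame_durations_s = schedule@durations),
                       path, digits = NA)
  invisible(path)
}

#' @rdname writeFrameSchedule
#' @export
readFrameSchedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  FrameSchedule(x$frame_starts_s, x$frame_durations_s)
}

#' Read a 4-D NIfTI plus schedule sidecar as a DynamicImage
#'
#' @param path 4-D NIfTI file.
#' @param schedulePath JSON sidecar; defaults to the volume path with a
#'   \code{.json} extension.
#' @return a \linkS4class{DynamicImage}.
#' @export
readDynamicImage <- function(path, schedulePath = NULL) {
  if (is.null(schedulePath))
    schedulePath <- sub("\\.nii(\\.gz)?$", ".json", path)
  v <- readVolume(path)
  if (length(dim(v$data)) != 4L)
    stop("expected a 4-D volume: ", path, call. = FALSE)
  new("DynamicImage", data = v$data, grid = v$grid,
      schedule = readFrameSchedule(schedulePath))
}
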