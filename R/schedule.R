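#' Construct a frame schedule from explicit starts and durations
#'
#' @param starts,durations numeric vectors in seconds.
#' @return a \linkS4class{FrameSchedule}.
#' @export
FrameSchedule <- function(starts, durations) {
  new("FrameSchedule", starts = as.numeric(starts),
      durations = as.numeric(durations))
}

#' Expand a (count, duration) frame specification
#'
#' Dynamic PET protocols are usually quoted as groups of equal frames, e.g.
#' "four frames of 15 s, then 4 x 30 s, ...". This expands such a
#' specification into a contiguous \linkS4class{FrameSchedule}.
#'
#' @param spec a list of \code{c(count, duration_s)} pairs, or a 2-column
#'   matrix with one row per group.
#' @return a \linkS4class{FrameSchedule}.
#' @examples
#' sched <- buildFrameSchedule(list(c(4, 15), c(4, 30), c(3, 60),
#'                                  c(2, 120), c(8, 300), c(1, 600)))
#' nFrames(sched)          # 22
#' sum(frameDurations(sched))  # 3600 s
#' @export
buildFrameSchedule <- function(spec) {
  if (is.matrix(spec)) spec <- lapply(seq_len(nrow(spec)), function(i) spec[i, ])
  if (length(spec) == 0L) stop("empty frame specification", call. = FALSE)
  durations <- unlist(lapply(spec, function(g) {
    if (length(g) != 2L || g[1] < 1 || g[2] <= 0)
      stop("each group must be c(count >= 1, duration > 0)", call. = FALSE)
    rep(g[2], g[1])
  }))
  starts <- cumsum(c(0, durations[-length(durations)]))
  FrameSchedule(starts, durations)
}

#' The 22-frame, 60-minute dynamic acquisition schedule
#'
#' Four frames of 15 s, then 4 x 30 s, 3 x 60 s, 2 x 120 s, 8 x 300 s and one
#' 600 s frame: the standard 11C-PK11195 protocol this package targets.
#'
#' @return a \linkS4class{FrameSchedule} with 22 frames totalling 3600 s.
#' @export
pkFrameSchedule <- function() {
  buildFrameSchedule(list(c(4, 15), c(4, 30), c(3, 60),
                          c(2, 120), c(8, 300), c(1, 600)))
}

#' @rdname FrameSchedule-class
#' @export
setMethod("nFrames", "FrameSchedule", function(x) length(x@starts))

#' @rdname FrameSchedule-class
#' @export
setMethod("frameStarts", "FrameSchedule", function(x) x@starts)

#' @rdname FrameSchedule-class
#' @export
setMethod("frameDurations", "FrameSchedule", function(x) x@durations)

#' @rdname frameMidTimes
#' @export
setMethod("frameMidTimes", "FrameSchedule",
          function(x) (x@starts + x@durations / 2) / 60)

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.1f min total\n",
              length(object@starts),
              (object@starts[length(object@starts)] +
                 object@durations[length(object@durations)]) / 60))
})

#' Construct a time-activity curve
#'
#' @param schedule a \linkS4class{FrameSchedule}.
#' @param values one activity value per frame.
#' @return a \linkS4class{TAC}.
#' @export
TAC <- function(schedule, values) {
  new("TAC", schedule = schedule, values = as.numeric(values))
}

#' @rdname TAC-class
#' @export
setMethod("tacValues", "TAC", function(x) x@values)

#' @rdname frameMidTimes
#' @export
setMethod("frameMidTimes", "TAC", function(x) frameMidTimes(x@schedule))

#' @rdname FrameSchedule-class
#' @export
setMethod("nFrames", "TAC", function(x) nFrames(x@schedule))

setMethod("show", "TAC", function(object) {
  cat(sprintf("TAC: %d frames, peak %.3g at %.2f min\n",
              length(object@values), max(object@values),
              frameMidTimes(object)[which.max(object@values)]))
})
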