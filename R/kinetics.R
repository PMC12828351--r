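#' Analytic plasma input function
#'
#' A tri-exponential bolus (Feng-type) arterial input curve used by the
#' forward model that generates synthetic dynamic PET. Only distribution
#' volume \emph{ratios} matter downstream (the quantification is
#' reference-tissue based), so the shape is fixed and the scale arbitrary.
#'
#' @param tMinutes time(s) post injection, minutes.
#' @return plasma activity concentration (arbitrary units), 0 at t <= 0.
#' @export
plasmaInputFunction <- function(tMinutes) {
  A1 <- 851.1; A2 <- 21.9; A3 <- 20.8
  l1 <- -4.1339; l2 <- -0.1191; l3 <- -0.0104
  v <- (A1 * tMinutes - A2 - A3) * exp(l1 * tMinutes) +
    A2 * exp(l2 * tMinutes) + A3 * exp(l3 * tMinutes)
  v[tMinutes <= 0] <- 0
  pmax(v, 0)
}

#' Construct kinetic parameters for the one-tissue forward model
#'
#' Defaults describe a fast-equilibrating low-binding reference tissue
#' (K1 = 0.1 /min, k2 = 0.3 /min, DV = 1/3). Fast reference clearance is a
#' requirement of Logan reference-tissue quantification, whose operational
#' equation assumes the tissue-to-plasma ratio is constant after t*.
#'
#' @param K1 delivery rate, per minute.
#' @param k2 clearance rate, per minute.
#' @param dvrTrue global multiplier applied to any per-voxel DVR field.
#' @param noiseCV fractional multiplicative noise at 300-s frames.
#' @return a \linkS4class{KineticParams}.
#' @export
KineticParams <- function(K1 = 0.1, k2 = 0.3, dvrTrue = 1, noiseCV = 0) {
  new("KineticParams", K1 = K1, k2 = k2, dvrTrue = dvrTrue, noiseCV = noiseCV)
}

# ---- fine-grid numerical integration ---------------------------------------

# Per-frame subdivided fine time grid (minutes) plus the frame-averaging
# weight matrix W (nFrames x nt): frame average = trapezoid integral over the
# frame divided by its duration. Frame boundaries are grid points.
fineTimeGrid <- function(schedule, nSub = 60L) {
  st <- schedule@starts / 60
  du <- schedule@durations / 60
  nf <- length(st)
  pieces <- lapply(seq_len(nf), function(i)
    seq(st[i], st[i] + du[i], length.out = nSub + 1L))
  tf <- unique(unlist(pieces))
  W <- matrix(0, nf, length(tf))
  for (i in seq_len(nf)) {
    idx <- match(pieces[[i]], tf)
    dt <- diff(tf[idx])
    w <- numeric(length(idx))
    w[-length(w)] <- w[-length(w)] + dt / 2
    w[-1] <- w[-1] + dt / 2
    W[i, idx] <- w / du[i]
  }
  list(t = tf, W = W)
}

# One-tissue tissue curves on the fine grid for paired (K1, k2) vectors:
# C(t) = K1 * exp(-k2 t) * integral_0^t exp(k2 s) Cp(s) ds, computed by
# cumulative trapezoid. Returns an nt x np matrix.
tissueCurvesFine <- function(K1, k2, tf, cp) {
  np <- length(k2)
  nt <- length(tf)
  E <- exp(outer(tf, k2))            # nt x np
  A <- E * cp                        # column-wise recycling over cp
  inc <- (A[-1, , drop = FALSE] + A[-nt, , drop = FALSE]) / 2 * diff(tf)
  cum <- rbind(0, apply(inc, 2, cumsum))
  sweep(cum / E, 2, K1, `*`)
}

#' Simulate a noiseless one-tissue time-activity curve
#'
#' Integrates \code{dC/dt = K1 Cp - k2 C} against the package's plasma input
#' on a per-frame subdivided fine grid and reports duration-weighted frame
#' averages on the schedule.
#'
#' @param K1,k2 one-tissue rate constants, per minute.
#' @param schedule a \linkS4class{FrameSchedule}.
#' @param nSub fine-grid subdivisions per frame.
#' @return a \linkS4class{TAC}.
#' @export
simulateTissueTAC <- function(K1, k2, schedule, nSub = 60L) {
  fg <- fineTimeGrid(schedule, nSub)
  cp <- plasmaInputFunction(fg$t)
  vals <- fg$W %*% tissueCurvesFine(K1, k2, fg$t, cp)
  TAC(schedule, as.numeric(vals))
}

#' Default kinetic class curves for supervised reference extraction
#'
#' Four area-normalised basis curves generated by the package's own forward
#' model: a gray-matter-like low-binding class (K1 0.10, k2 0.30), a slower
#' white-matter-like class with the same distribution volume (K1 0.05, k2
#' 0.15), a high-binding class (K1 0.10, k2 0.10) and a blood-like class (the
#' plasma shape itself).
#'
#' @param schedule a \linkS4class{FrameSchedule}.
#' @return a \linkS4class{KineticClassSet} with \code{lowBinding = "gray"}.
#' @export
defaultKineticClasses <- function(schedule) {
  fg <- fineTimeGrid(schedule)
  cp <- plasmaInputFunction(fg$t)
  tissue <- fg$W %*% tissueCurvesFine(c(0.10, 0.05, 0.10),
                                      c(0.30, 0.15, 0.10), fg$t, cp)
  blood <- fg$W %*% cp
  curves <- cbind(tissue, blood)
  colnames(curves) <- c("gray", "white", "high", "blood")
  mid <- frameMidTimes(schedule)
  areas <- apply(curves, 2, function(v) trapzFromZero(mid, v))
  curves <- sweep(curves, 2, areas, `/`)
  new("KineticClassSet", schedule = schedule, curves = curves,
      lowBinding = "gray")
}

# trapezoid integral of v over mid-time points, with a leading (0, 0) node
# (zero activity at injection)
trapzFromZero <- function(mid, v) {
  n <- length(mid)
  sum(c(mid[1] * v[1] / 2, (v[-1] + v[-n]) / 2 * diff(mid)))
}

# running version, one value per frame
cumtrapzFromZero <- function(mid, v) {
  n <- length(mid)
  cumsum(c(mid[1] * v[1] / 2, (v[-1] + v[-n]) / 2 * diff(mid)))
}

# matrix version over columns: V is nFrames x nvox; column-wise running sums
# via a lower-triangular multiply (BLAS) rather than per-column loops
cumtrapzFromZeroMat <- function(mid, V) {
  n <- length(mid)
  inc <- rbind(mid[1] * V[1, , drop = FALSE] / 2,
               (V[-1, , drop = FALSE] + V[-n, , drop = FALSE]) / 2 * diff(mid))
  L <- matrix(0, n, n)
  L[lower.tri(L, diag = TRUE)] <- 1
  L %*% inc
}

# ---- dynamic image simulation ----------------------------------------------

#' Simulate a 4-D dynamic PET image from a DVR field
#'
#' Every voxel follows a plasma-input one-tissue model sharing the input
#' function; its clearance is scaled so that the voxel's distribution volume
#' equals \code{dvrTrue(voxel) x} the reference DV (\code{K1/k2} of
#' \code{kinetics}). Frame values are duration-weighted averages of the
#' instantaneous activity; multiplicative Gaussian noise is added per frame
#' with CV \code{noiseCV * sqrt(300 / duration_s)} (count-statistics-like
#' scaling, anchored at the 300-s frames).
#'
#' Voxels where \code{dvrField} is NA or 0 produce zero signal. If
#' \code{tissueMask}/\code{tissueParams} are given, voxels inside the mask
#' use \code{tissueParams@K1} for delivery (their clearance is still scaled
#' to meet the DVR target), emulating kinetically distinct tissue classes.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param dvrField numeric array on the grid, target DVR per voxel (>= 0).
#' @param kinetics reference \linkS4class{KineticParams}; its \code{noiseCV}
#'   and \code{dvrTrue} apply.
#' @param schedule a \linkS4class{FrameSchedule}.
#' @param seed integer seed; identical seeds give bitwise-identical images.
#' @param tissueMask optional logical array selecting the second tissue class.
#' @param tissueParams optional \linkS4class{KineticParams} for that class.
#' @param nSub fine-grid subdivisions per frame.
#' @return a \linkS4class{DynamicImage}.
#' @export
simulateDynamicPET <- function(grid, dvrField, kinetics, schedule, seed,
                               tissueMask = NULL, tissueParams = NULL,
                               nSub = 60L) {
  if (!identical(dim(dvrField), grid@dim))
    stop("dvrField does not match the grid dimensions", call. = FALSE)
  if (any(dvrField < 0, na.rm = TRUE))
    stop("dvrField must be non-negative", call. = FALSE)
  nf <- nFrames(schedule)
  nv <- prod(grid@dim)
  dvr <- kinetics@dvrTrue * as.numeric(dvrField)
  K1v <- rep(kinetics@K1, nv)
  if (!is.null(tissueMask)) {
    checkMask(tissueMask, grid, "tissueMask")
    if (is.null(tissueParams))
      stop("tissueParams required with tissueMask", call. = FALSE)
    K1v[as.logical(tissueMask)] <- tissueParams@K1
  }
  DVref <- kinetics@K1 / kinetics@k2
  active <- !is.na(dvr) & dvr > 0
  vals <- matrix(0, nf, nv)
  if (any(active)) {
    k2v <- K1v[active] / (dvr[active] * DVref)
    key <- complex(real = K1v[active], imaginary = k2v)
    u <- !duplicated(key)
    fg <- fineTimeGrid(schedule, nSub)
    cp <- plasmaInputFunction(fg$t)
    curves <- fg$W %*% tissueCurvesFine(K1v[active][u], k2v[u], fg$t, cp)
    va <- curves[, match(key, key[u]), drop = FALSE]
    if (kinetics@noiseCV > 0) {
      cvf <- kinetics@noiseCV * sqrt(300 / schedule@durations)
      eps <- withSeed(seed, matrix(rnorm(nf * sum(active)), nf))
      va <- va * (1 + cvf * eps)
    }
    vals[, active] <- va
  }
  new("DynamicImage", data = array(t(vals), c(grid@dim, nf)), grid = grid,
      schedule = schedule)
}

#' @rdname grid3d
#' @export
setMethod("grid3d", "DynamicImage", function(x) x@grid)

#' @rdname frameMidTimes
#' @export
setMethod("frameMidTimes", "DynamicImage",
          function(x) frameMidTimes(x@schedule))

setMethod("show", "DynamicImage", function(object) {
  cat(sprintf("DynamicImage: %s voxels x %d frames\n",
              paste(object@grid@dim, collapse = " x "),
              nFrames(object@schedule)))
})

# frames x nvox matrix view of a dynamic image
dynamicMatrix <- function(dynamic) {
  d <- dim(dynamic@data)
  t(matrix(dynamic@data, prod(d[1:3]), d[4]))
}
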