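#' @rdname grid3d
#' @export
setMethod("grid3d", "DVRMap", function(x) x@grid)

#' @rdname DVRMap-class
#' @export
setMethod("dvrValues", "DVRMap", function(x) x@values)

setMethod("show", "DVRMap", function(object) {
  ok <- !is.na(object@values)
  cat(sprintf("DVRMap: %d/%d voxels fitted, median DVR %.3f\n",
              sum(ok), length(ok), median(object@values[ok])))
})

# Exact non-negative least squares of every column of Y against a small basis
# B (frames x k), by enumeration of all supports: the NNLS optimum restricted
# to its support is the unconstrained optimum there, so the best feasible
# support solution is the NNLS solution. Vectorised across voxels; intended
# for k <= 5.
nnlsBasis <- function(B, Y) {
  k <- ncol(B)
  nv <- ncol(Y)
  W <- matrix(0, k, nv)
  yty <- colSums(Y^2)
  BtY <- crossprod(B, Y)                  # k x nv, shared by all supports
  best <- yty                             # empty support
  for (m in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    G <- crossprod(B[, S, drop = FALSE])
    if (rcond(G) < 1e-12) next
    Ws <- solve(G, BtY[S, , drop = FALSE])   # |S| x nv
    feas <- colSums(Ws < -1e-12) == 0L
    if (!any(feas)) next
    # on its support the solution satisfies the normal equations, so the
    # residual is ||y||^2 - w' B'y; no need to form the residual matrix
    res <- yty - colSums(Ws * BtY[S, , drop = FALSE])
    upd <- feas & res < best - 1e-12 * yty
    if (any(upd)) {
      best[upd] <- res[upd]
      W[, upd] <- 0
      W[S, upd] <- pmax(Ws[, upd, drop = FALSE], 0)
    }
  }
  W
}

# area weights such that sum(w * v) == trapzFromZero(mid, v)
areaWeights <- function(mid) {
  n <- length(mid)
  w <- numeric(n)
  d <- diff(mid)
  w[1] <- mid[1] / 2
  w[-n] <- w[-n] + d / 2
  w[-1] <- w[-1] + d / 2
  w
}

#' Extract a subject-specific reference TAC by supervised kinetic clustering
#'
#' Every in-mask voxel's area-normalised time-activity curve is scored by
#' non-negative least squares against the kinetic class basis; voxels whose
#' largest coefficient belongs to the low-binding class are candidate
#' reference voxels, the top \code{selectFraction} of them (ranked by that
#' coefficient) are pooled, and their \emph{raw} curves are averaged into the
#' reference TAC. This mirrors supervised-cluster reference extraction for
#' tracers with no usable anatomical reference region.
#'
#' @param dynamic a \linkS4class{DynamicImage}.
#' @param brainMask logical array of voxels to consider.
#' @param classes a \linkS4class{KineticClassSet} on the same schedule.
#' @param selectFraction proportion of low-binding-dominant voxels pooled.
#' @return a \linkS4class{TAC}.
#' @export
extractReferenceTAC <- function(dynamic, brainMask, classes,
                                selectFraction = 0.5) {
  checkMask(brainMask, dynamic@grid, "brainMask")
  if (!any(brainMask)) stop("brain mask is empty", call. = FALSE)
  if (nFrames(dynamic@schedule) != nrow(classes@curves))
    stop("class curves and dynamic image are on different schedules",
         call. = FALSE)
  if (selectFraction <= 0 || selectFraction > 1)
    stop("selectFraction must be in (0, 1]", call. = FALSE)
  Y <- dynamicMatrix(dynamic)[, as.logical(brainMask), drop = FALSE]
  mid <- frameMidTimes(dynamic@schedule)
  areas <- as.numeric(areaWeights(mid) %*% Y)
  ok <- areas > 0
  if (!any(ok))
    stop("no in-mask voxel has positive integrated activity", call. = FALSE)
  Yn <- sweep(Y[, ok, drop = FALSE], 2, areas[ok], `/`)
  W <- nnlsBasis(classes@curves, Yn)
  low <- match(classes@lowBinding, colnames(classes@curves))
  wmax <- W[cbind(max.col(t(W), ties.method = "first"), seq_len(ncol(W)))]
  dominant <- which(W[low, ] > 0 & W[low, ] >= wmax - 1e-12)
  if (length(dominant) == 0L)
    stop("no voxel matched the low-binding kinetic class; ",
         "consider a larger selectFraction or check the input",
         call. = FALSE)
  nSel <- max(1L, ceiling(selectFraction * length(dominant)))
  sel <- dominant[order(W[low, dominant], decreasing = TRUE)[seq_len(nSel)]]
  TAC(dynamic@schedule, rowMeans(Y[, ok, drop = FALSE][, sel, drop = FALSE]))
}

#' Logan reference-tissue graphical estimate of DVR
#'
#' Computes running integrals of the target and reference curves by the
#' trapezoid rule on frame mid-times (assuming zero activity at injection)
#' and regresses \code{int(Ct)/Ct} on \code{int(Cref)/Ct} over frames with
#' mid-time at or after \code{tStar}; the slope is the distribution volume
#' ratio. The reference-efflux correction term \code{Cref/(k2prime Ct)} is
#' omitted by default (late-time approximation) but applied when
#' \code{k2prime} is supplied.
#'
#' @param target,reference \linkS4class{TAC}s on one schedule.
#' @param tStar start of the linear segment, minutes.
#' @param k2prime optional reference-tissue efflux constant (per minute).
#' @return a list with \code{dvr} (the slope), \code{r2} of the Logan line
#'   and \code{nFrames} used.
#' @export
loganDVR <- function(target, reference, tStar = 20, k2prime = NULL) {
  mid <- frameMidTimes(target@schedule)
  if (length(tacValues(reference)) != length(mid) ||
      max(abs(frameMidTimes(reference@schedule) - mid)) > 1e-9)
    stop("target and reference are on different schedules", call. = FALSE)
  if (tStar < 0 || tStar > max(mid))
    stop("tStar outside the scan span", call. = FALSE)
  ct <- tacValues(target)
  cr <- tacValues(reference)
  intT <- cumtrapzFromZero(mid, ct)
  intR <- cumtrapzFromZero(mid, cr)
  use <- which(mid >= tStar & ct > 0)
  if (length(use) < 3L)
    stop("fewer than 3 usable frames at or after tStar", call. = FALSE)
  x <- intR[use] / ct[use]
  if (!is.null(k2prime)) x <- x + cr[use] / (k2prime * ct[use])
  y <- intT[use] / ct[use]
  n <- length(use)
  vx <- sum(x^2) - sum(x)^2 / n
  if (vx <= 0) stop("degenerate Logan plot (constant abscissa)", call. = FALSE)
  cxy <- sum(x * y) - sum(x) * sum(y) / n
  vy <- sum(y^2) - sum(y)^2 / n
  list(dvr = cxy / vx, r2 = if (vy > 0) cxy^2 / (vx * vy) else NA_real_,
       nFrames = n)
}

#' Voxelwise DVR map by the Logan reference method
#'
#' Applies \code{\link{loganDVR}} to every in-mask voxel (vectorised).
#' Frames with non-positive voxel activity are dropped per voxel; voxels with
#' fewer than 3 usable late frames, or a degenerate Logan abscissa, are left
#' undefined rather than aborting the map.
#'
#' @param dynamic a \linkS4class{DynamicImage}.
#' @param reference the reference \linkS4class{TAC}.
#' @param tStar start of the Logan linear segment, minutes.
#' @param mask logical array of voxels to fit (default: all).
#' @param k2prime optional reference efflux constant.
#' @return a \linkS4class{DVRMap} with per-voxel DVR and R-squared.
#' @export
computeDVRMap <- function(dynamic, reference, tStar = 20, mask = NULL,
                          k2prime = NULL) {
  grid <- dynamic@grid
  if (is.null(mask)) mask <- array(TRUE, grid@dim)
  checkMask(mask, grid)
  mid <- frameMidTimes(dynamic@schedule)
  if (max(abs(frameMidTimes(reference@schedule) - mid)) > 1e-9)
    stop("reference TAC is on a different schedule", call. = FALSE)
  vals <- array(NA_real_, grid@dim)
  r2 <- array(NA_real_, grid@dim)
  idx <- which(as.logical(mask))
  if (length(idx)) {
    Y <- dynamicMatrix(dynamic)[, idx, drop = FALSE]
    cr <- tacValues(reference)
    intR <- cumtrapzFromZero(mid, cr)
    intT <- cumtrapzFromZeroMat(mid, Y)
    late <- which(mid >= tStar)
    Yl <- Y[late, , drop = FALSE]
    M <- Yl > 0
    Ysafe <- ifelse(M, Yl, 1)            # placeholder; masked out below
    X <- intR[late] / Ysafe
    if (!is.null(k2prime)) X <- X + cr[late] / (k2prime * Ysafe)
    Yp <- intT[late, , drop = FALSE] / Ysafe
    X[!M] <- 0; Yp[!M] <- 0
    n <- colSums(M)
    sx <- colSums(X); sy <- colSums(Yp)
    sxx <- colSums(X^2); sxy <- colSums(X * Yp); syy <- colSums(Yp^2)
    dx <- n * sxx - sx^2
    dy <- n * syy - sy^2
    cxy <- n * sxy - sx * sy
    good <- n >= 3 & dx > 0
    slope <- ifelse(good, cxy / dx, NA_real_)
    rr <- ifelse(good & dy > 0, cxy^2 / (dx * dy), NA_real_)
    vals[idx] <- slope
    r2[idx] <- rr
  }
  new("DVRMap", values = vals, r2 = r2, grid = grid)
}
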