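# Independent reference implementations ("oracles") used to validate the
# package's numerics. These are deliberately written as plain, slow R code
# (or built on third-party solvers) so that agreement with the package is
# meaningful.

# ---- voxel traversal --------------------------------------------------------

# Plane-crossing voxelizer in pure R: voxel i owns [i-0.5, i+0.5) in 0-based
# continuous voxel-centre coordinates. Returns sorted 1-based linear indices.
oracleVoxelizeLinear <- function(streamline, grid) {
  u <- worldToVoxelCoords(grid, streamline) + 0.5   # corner coords
  d <- grid@dim
  out <- integer(0)
  addPoint <- function(pt) {
    c3 <- floor(pt)
    if (all(c3 >= 0) && all(c3 < d))
      out <<- c(out, 1L + as.integer(c3[1]) +
                  d[1] * (as.integer(c3[2]) + d[2] * as.integer(c3[3])))
  }
  n <- nrow(u)
  if (n == 1L) addPoint(u[1, ])
  if (n >= 2L) for (i in seq_len(n - 1L)) {
    p <- u[i, ]; q <- u[i + 1L, ]
    addPoint(p); addPoint(q)
    ts <- c(0, 1)
    for (ax in 1:3) {
      dd <- q[ax] - p[ax]
      if (dd == 0) next
      lo <- ceiling(min(p[ax], q[ax])); hi <- floor(max(p[ax], q[ax]))
      if (lo <= hi) for (k in lo:hi) {
        t <- (k - p[ax]) / dd
        if (t > 0 && t < 1) ts <- c(ts, t)
      }
    }
    ts <- sort(ts)
    for (j in seq_len(length(ts) - 1L)) {
      tm <- (ts[j] + ts[j + 1L]) / 2
      if (tm > 0 && tm < 1) addPoint(p + tm * (q - p))
    }
  }
  sort(unique(out))
}

# Dense-sampling voxelizer: voxels containing points sampled every `step`
# voxel units along each segment. A subset of the exact traversal (it can
# miss very short corner clips), used as a cross-check of different origin.
denseVoxelizeLinear <- function(streamline, grid, step = 1 / 200) {
  v <- worldToVoxelCoords(grid, streamline)
  d <- grid@dim
  pts <- v
  if (nrow(v) >= 2L) for (i in seq_len(nrow(v) - 1L)) {
    seg <- v[i + 1L, ] - v[i, ]
    ns <- max(2L, ceiling(sqrt(sum(seg^2)) / step))
    tt <- seq(0, 1, length.out = ns)
    pts <- rbind(pts, outer(rep(1, ns), v[i, ]) + outer(tt, seg))
  }
  c3 <- floor(pts + 0.5)
  keep <- c3[, 1] >= 0 & c3[, 1] < d[1] & c3[, 2] >= 0 & c3[, 2] < d[2] &
    c3[, 3] >= 0 & c3[, 3] < d[3]
  c3 <- c3[keep, , drop = FALSE]
  sort(unique(1L + as.integer(c3[, 1]) +
                d[1] * (as.integer(c3[, 2]) + d[2] * as.integer(c3[, 3]))))
}

# Brute-force disruption counting built on the oracle voxelizer.
oracleDisruption <- function(tractogram, mask) {
  grid <- grid3d(tractogram)
  nv <- prod(grid@dim)
  nThrough <- integer(nv)
  nLesioned <- integer(nv)
  for (s in streamlines(tractogram)) {
    v <- oracleVoxelizeLinear(s, grid)
    nThrough[v] <- nThrough[v] + 1L
    if (any(mask[v])) nLesioned[v] <- nLesioned[v] + 1L
  }
  score <- ifelse(nThrough == 0L, NA_real_, nLesioned / nThrough)
  list(nThrough = array(nThrough, grid@dim),
       nLesioned = array(nLesioned, grid@dim),
       score = array(score, grid@dim))
}

# ---- kinetics ---------------------------------------------------------------

# One-tissue frame-averaged TAC by adaptive ODE integration (deSolve), fully
# independent of the package's trapezoid forward model.
oracleTissueTAC <- function(K1, k2, schedule, nDense = 6000L) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  tEnd <- (max(schedule@starts + schedule@durations)) / 60
  bounds <- sort(unique(c(schedule@starts, schedule@starts +
                            schedule@durations))) / 60
  times <- sort(unique(c(seq(0, tEnd, length.out = nDense), bounds)))
  rhs <- function(t, y, p) list(K1 * plasmaInputFunction(t) - k2 * y)
  sol <- deSolve::lsoda(c(C = 0), times, rhs, rtol = 1e-10, atol = 1e-12)
  ct <- sol[, "C"]
  st <- schedule@starts / 60
  du <- schedule@durations / 60
  vapply(seq_along(st), function(i) {
    inF <- times >= st[i] - 1e-12 & times <= st[i] + du[i] + 1e-12
    tt <- times[inF]; vv <- ct[inF]
    sum((vv[-1] + vv[-length(vv)]) / 2 * diff(tt)) / du[i]
  }, numeric(1))
}

# ---- statistics -------------------------------------------------------------

# Brute-force Benjamini-Hochberg step-up adjustment.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    m <- Inf
    for (j in i:n) m <- min(m, n * ps[j] / j)
    adj[i] <- min(m, 1)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# ---- small fixtures ---------------------------------------------------------

unitGrid <- function(dim = c(5L, 5L, 5L), spacing = c(1, 1, 1)) {
  VolumeGrid(as.integer(dim), spacing)
}

# a streamline through the given 0-based voxel-centre coordinates
centerLine <- function(grid, vox) {
  voxelToWorldCoords(grid, as.matrix(vox))
}

randomStreamline <- function(grid, n = 12L, margin = 1.5) {
  bb <- gridBoundingBox(grid)
  lo <- bb[1, ] - margin; hi <- bb[2, ] + margin
  m <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
             runif(n, lo[3], hi[3]))
  m[!duplicated(m), , drop = FALSE]
}

randomMask <- function(grid, p = 0.2) {
  array(runif(prod(grid@dim)) < p, grid@dim)
}

# count 6-connected components of a logical array (BFS flood fill)
countComponents6 <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  idx <- which(mask)
  comp <- 0L
  for (start in idx) {
    if (seen[start]) next
    comp <- comp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      c3 <- arrayInd(cur, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- c3; nb[ax] <- nb[ax] + s
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        li <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
        if (mask[li] && !seen[li]) { seen[li] <- TRUE; queue <- c(queue, li) }
      }
    }
  }
  comp
}
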