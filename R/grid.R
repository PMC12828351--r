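#' Construct a voxel grid
#'
#' @param dim integer(3), voxels per axis.
#' @param spacing numeric(3), voxel edge lengths in mm (default 1 mm
#'   isotropic).
#' @param origin world coordinates (mm) of the centre of voxel (0,0,0); by
#'   default the grid is centred on the world origin.
#' @param affine optionally, a full 4x4 voxel-to-world matrix; overrides
#'   \code{origin}. Its 3x3 block must be consistent with \code{spacing}
#'   (column norms equal the spacing).
#' @return a \linkS4class{VolumeGrid}.
#' @examples
#' g <- VolumeGrid(c(32L, 32L, 16L), spacing = c(2, 2, 2))
#' voxelToWorldCoords(g, c(0, 0, 0))
#' @export
VolumeGrid <- function(dim, spacing = c(1, 1, 1), origin = NULL,
                       affine = NULL) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  if (is.null(affine)) {
    if (is.null(origin)) origin <- -(dim - 1) * spacing / 2
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  }
  new("VolumeGrid", dim = dim, spacing = spacing, affine = affine)
}

#' @rdname VolumeGrid-class
#' @export
setMethod("gridDim", "VolumeGrid", function(x) x@dim)

#' @rdname VolumeGrid-class
#' @export
setMethod("gridSpacing", "VolumeGrid", function(x) x@spacing)

#' @rdname VolumeGrid-class
#' @export
setMethod("gridAffine", "VolumeGrid", function(x) x@affine)

#' @rdname VolumeGrid-class
#' @export
setMethod("nVoxels", "VolumeGrid", function(x) prod(x@dim))

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid:", paste(object@dim, collapse = " x "), "voxels,",
      paste(signif(object@spacing, 4), collapse = " x "), "mm\n")
})

#' Convert world (mm) coordinates to continuous 0-based voxel coordinates
#'
#' Returned coordinates are voxel-centre based: the centre of voxel
#' \code{(i,j,k)} (0-based) maps to exactly \code{(i,j,k)}.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param xyz an n x 3 matrix (or length-3 vector) of world coordinates.
#' @return n x 3 matrix of continuous voxel coordinates.
#' @export
worldToVoxelCoords <- function(grid, xyz) {
  xyz <- rbind3(xyz)
  inv <- solve(grid@affine)
  t(inv %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' Convert continuous 0-based voxel coordinates to world (mm) coordinates
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param vox an n x 3 matrix (or length-3 vector) of voxel coordinates.
#' @return n x 3 matrix of world coordinates.
#' @export
voxelToWorldCoords <- function(grid, vox) {
  vox <- rbind3(vox)
  t(grid@affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
}

# coerce a length-3 vector to a 1 x 3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' World-space bounding box of a grid
#'
#' The box containing all voxel volumes (voxel centres plus half a voxel on
#' each side), for axis-aligned affines.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @return a 2 x 3 matrix (min and max rows).
#' @export
gridBoundingBox <- function(grid) {
  corners <- as.matrix(expand.grid(
    c(-0.5, grid@dim[1] - 0.5), c(-0.5, grid@dim[2] - 0.5),
    c(-0.5, grid@dim[3] - 0.5)))
  w <- voxelToWorldCoords(grid, corners)
  rbind(min = apply(w, 2, min), max = apply(w, 2, max))
}

#' World coordinates of every voxel centre
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @return an nVoxels x 3 matrix, rows in R array (column-major) order.
#' @export
voxelCentersWorld <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid@dim)), grid@dim) - 1L
  voxelToWorldCoords(grid, idx)
}

# identical grids (dims and affine)
sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@dim, b@dim) && max(abs(a@affine - b@affine)) <= tol
}

stopIfGridMismatch <- function(a, b, what = "inputs") {
  if (!sameGrid(a, b))
    stop(sprintf("grid mismatch between %s:\naffine A:\n%s\naffine B:\n%s",
                 what, paste(capture.output(print(a@affine)), collapse = "\n"),
                 paste(capture.output(print(b@affine)), collapse = "\n")),
         call. = FALSE)
  invisible(TRUE)
}

#' @importFrom utils capture.output
NULL

# check that a mask is a logical array on the grid
checkMask <- function(mask, grid, name = "mask") {
  if (!identical(dim(mask), grid@dim))
    stop(sprintf("%s does not match the grid dimensions", name), call. = FALSE)
  if (!is.logical(mask)) stop(sprintf("%s must be logical", name),
                              call. = FALSE)
  invisible(TRUE)
}

# run code with a fixed seed, restoring the caller's RNG state afterwards
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
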