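# --- shared binary helpers ---------------------------------------------------

rawPad <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) > n) stop("string too long for field", call. = FALSE)
  c(r, raw(n - length(r)))
}

# --- TRK (TrackVis) ----------------------------------------------------------

#' Write a tractogram to a TrackVis .trk file
#'
#' Version-2 TRK with a 1000-byte header carrying the grid dimensions, voxel
#' size and voxel-to-world affine. Points are stored in the TRK "voxmm"
#' convention: \code{(voxel_center_coord + 0.5) * voxel_size}, with 0-based
#' voxel-centre coordinates, so they round-trip through
#' \code{\link{readTractogram}} up to float32 precision. No per-point scalars
#' or per-streamline properties are written.
#'
#' @param tractogram a \linkS4class{Tractogram}.
#' @param path output path ending in \code{.trk} or \code{.tck}.
#' @return the path, invisibly.
#' @export
writeTractogram <- function(tractogram, path) {
  if (grepl("\\.tck$", path, ignore.case = TRUE))
    return(writeTck(tractogram, path))
  if (!grepl("\\.trk$", path, ignore.case = TRUE))
    stop("unsupported tractogram extension: ", path, call. = FALSE)
  grid <- grid3d(tractogram)
  sl <- streamlines(tractogram)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rawPad("TRACK", 6L), con)
  writeBin(as.integer(grid@dim), con, size = 2L, endian = "little")
  writeBin(as.numeric(grid@spacing), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")       # origin
  writeBin(0L, con, size = 2L, endian = "little")               # n_scalars
  writeBin(raw(200L), con)                                      # scalar names
  writeBin(0L, con, size = 2L, endian = "little")               # n_properties
  writeBin(raw(200L), con)                                      # property names
  writeBin(as.numeric(t(grid@affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                      # reserved
  writeBin(rawPad("RAS", 4L), con)                              # voxel_order
  writeBin(raw(4L), con)                                        # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4L, endian = "little")  # IOP
  writeBin(raw(2L), con)                                        # pad1
  writeBin(raw(6L), con)                                        # invert/swap
  writeBin(length(sl), con, size = 4L, endian = "little")       # n_count
  writeBin(2L, con, size = 4L, endian = "little")               # version
  writeBin(1000L, con, size = 4L, endian = "little")            # hdr_size
  for (pts in sl) {
    v <- worldToVoxelCoords(grid, pts)
    voxmm <- sweep(v + 0.5, 2L, grid@spacing, `*`)
    writeBin(nrow(pts), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

readTrk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    stop("not a TRK file (bad magic): ", path, call. = FALSE)
  dim3 <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  spacing <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")     # origin
  nScalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  nProps <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  aff <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)
  nCount <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdrSize <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdrSize, 1000L))
    stop("unsupported TRK header size: ", hdrSize, call. = FALSE)
  if (all(aff == 0))
    stop("TRK file lacks a voxel-to-world affine: ", path, call. = FALSE)
  grid <- new("VolumeGrid", dim = as.integer(dim3),
              spacing = as.numeric(spacing), affine = aff)
  sl <- list()
  repeat {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(n) == 0L) break
    vals <- readBin(con, "numeric", n * (3L + nScalars), size = 4L,
                    endian = "little")
    if (nProps > 0L)
      readBin(con, "numeric", nProps, size = 4L, endian = "little")
    m <- matrix(vals, ncol = 3L + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
    v <- sweep(m, 2L, spacing, `/`) - 0.5
    sl[[length(sl) + 1L]] <- voxelToWorldCoords(grid, v)
    if (nCount > 0L && length(sl) >= nCount) break
  }
  Tractogram(sl, grid)
}

# --- TCK (MRtrix) ------------------------------------------------------------

writeTck <- function(tractogram, path) {
  sl <- streamlines(tractogram)
  mkHeader <- function(off) paste0(
    "mrtrix tracks\ndatatype: Float32LE\ncount: ", length(sl),
    "\nfile: . ", off, "\nEND\n")
  off <- nchar(mkHeader(0L))
  while (nchar(mkHeader(off)) != off) off <- nchar(mkHeader(off))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(mkHeader(off)), con)
  for (pts in sl) {
    writeBin(as.numeric(t(pts)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

readTck <- function(path, grid) {
  if (is.null(grid))
    stop("TCK files carry no grid; supply one to read ", path, call. = FALSE)
  bytes <- readBin(path, "raw", file.size(path))
  nl <- which(bytes == charToRaw("\n"))
  starts <- c(1L, nl + 1L)
  offset <- NULL; count <- NA_integer_; datatype <- NULL
  for (i in seq_along(nl)) {
    line <- rawToChar(bytes[starts[i]:(nl[i] - 1L)])
    if (i == 1L && line != "mrtrix tracks")
      stop("not a TCK file (bad magic): ", path, call. = FALSE)
    if (grepl("^datatype:", line)) datatype <- trimws(sub("^datatype:", "", line))
    if (grepl("^count:", line)) count <- as.integer(trimws(sub("^count:", "", line)))
    if (grepl("^file:", line))
      offset <- as.integer(trimws(sub("^file:\\s*\\.", "", line)))
    if (trimws(line) == "END") break
  }
  if (is.null(offset)) stop("TCK header lacks a file offset", call. = FALSE)
  if (!identical(datatype, "Float32LE"))
    stop("unsupported TCK datatype: ", datatype, call. = FALSE)
  vals <- readBin(bytes[(offset + 1L):length(bytes)], "numeric",
                  (length(bytes) - offset) %/% 4L, size = 4L,
                  endian = "little")
  m <- matrix(vals[seq_len((length(vals) %/% 3L) * 3L)], ncol = 3L,
              byrow = TRUE)
  sl <- list(); cur <- 1L
  for (i in seq_len(nrow(m))) {
    if (all(is.infinite(m[i, ]))) break
    if (all(is.nan(m[i, ]))) {
      if (i > cur) sl[[length(sl) + 1L]] <- m[cur:(i - 1L), , drop = FALSE]
      cur <- i + 1L
    }
  }
  if (!is.na(count) && length(sl) != count)
    warning("TCK header count (", count, ") differs from streamlines read (",
            length(sl), ")")
  Tractogram(sl, grid)
}

#' Read a tractogram from a .trk or .tck file
#'
#' TRK files carry their own grid (dimensions, voxel size, affine) in the
#' header; TCK files store world-mm points only, so a \code{grid} must be
#' supplied. An empty (zero-byte) file yields an empty tractogram on the
#' supplied grid. Files with an unrecognised magic string are rejected.
#'
#' @param path a \code{.trk} or \code{.tck} file.
#' @param grid a \linkS4class{VolumeGrid}; required for TCK, overrides the
#'   header grid for TRK when given.
#' @return a \linkS4class{Tractogram}.
#' @export
readTractogram <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    if (is.null(grid))
      stop("empty tractogram file and no grid supplied: ", path,
           call. = FALSE)
    return(Tractogram(list(), grid))
  }
  if (grepl("\\.tck$", path, ignore.case = TRUE)) return(readTck(path, grid))
  if (grepl("\\.trk$", path, ignore.case = TRUE)) {
    tg <- readTrk(path)
    if (!is.null(grid)) tg <- Tractogram(streamlines(tg), grid)
    return(tg)
  }
  stop("unsupported tractogram extension: ", path, call. = FALSE)
}
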