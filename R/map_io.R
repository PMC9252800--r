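#' CCP4/MRC density map input/output
#'
#' Minimal mode-2 (32-bit float) reader/writer for orthogonal, unpermuted
#' maps (MAPC/MAPR/MAPS = 1/2/3, 90-degree cell angles, isotropic voxels).
#' The origin is taken from the MRC-2014 ORIGIN fields when set, otherwise
#' from NCSTART/NRSTART/NSSTART.
#'
#' @name map_io
NULL

#' @param path file path.
#' @return \code{read_ccp4}: a \code{density_grid}.
#' @rdname map_io
#' @export
read_ccp4 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", 10, size = 4, endian = "little")
  dims <- ints1[1:3]
  mode <- ints1[4]
  nstart <- ints1[5:7]
  if (mode != 2) stop("only mode-2 (float32) CCP4/MRC maps are supported")
  cell <- readBin(con, "numeric", 6, size = 4, endian = "little")
  if (any(abs(cell[4:6] - 90) > 1e-3)) stop("non-orthogonal cells are not supported")
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  if (!all(mapcrs == 1:3)) stop("permuted map axes are not supported")
  readBin(con, "numeric", 3, size = 4, endian = "little")      # dmin dmax dmean
  readBin(con, "integer", 2, size = 4, endian = "little")      # ispg nsymbt
  readBin(con, "integer", 25, size = 4, endian = "little")     # extra
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "integer", 4, size = 4, endian = "little")      # MAP, MACHST, RMS, NLABL... (partial)
  seek(con, 1024)
  vox <- cell[1:3] / ints1[8:10]
  if (diff(range(vox)) > 1e-4) stop("anisotropic voxels are not supported")
  if (all(abs(origin) < 1e-6)) origin <- nstart * vox[1]
  vals <- readBin(con, "numeric", prod(dims), size = 4, endian = "little")
  density_grid(vals, origin, vox[1], dims)
}

#' @param map a \code{density_grid}.
#' @rdname map_io
#' @export
write_ccp4 <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- map$dims
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                 # NC NR NS
  wi(2)                 # MODE
  wi(c(0, 0, 0))        # NCSTART..
  wi(d)                 # NX NY NZ (sampling)
  wf(d * map$voxel)     # CELLA
  wf(c(90, 90, 90))     # CELLB
  wi(1:3)               # MAPC MAPR MAPS
  v <- map$values
  wf(c(min(v), max(v), mean(v)))
  wi(c(1, 0))           # ISPG, NSYMBT
  wi(rep(0, 25))        # extra
  wf(map$origin)        # ORIGIN (MRC-2014)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(v))
  wi(0)                 # NLABL
  writeBin(raw(800), con)
  wf(v)
  invisible(path)
}
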