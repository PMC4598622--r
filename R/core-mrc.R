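#' MRC2014 volume input/output
#'
#' Minimal, standards-conforming reader/writer for mode-2 (32-bit float)
#' MRC2014 volumes: the interchange format for all maps produced by the
#' package.  The writer records dimensions, mode 2, cell dimensions encoding
#' the pixel spacing, axis order X/Y/Z, density statistics, the "MAP " stamp
#' and little-endian machine stamp.  The reader validates the stamp and mode
#' and errors naming the offending header field on malformed files.
#'
#' @param map \code{density_map} to write.
#' @param path file path.
#' @return \code{write_mrc} returns \code{path} invisibly; \code{read_mrc}
#'   returns a \code{density_map}.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # NX NY NZ
  wi(2)                                   # MODE 2 = float32
  wi(c(0, 0, 0))                          # NXSTART NYSTART NZSTART
  wi(d)                                   # MX MY MZ
  wf(d * map$voxel_size)                  # CELLA
  wf(c(90, 90, 90))                       # CELLB
  wi(c(1, 2, 3))                          # MAPC MAPR MAPS
  wf(c(min(map$grid), max(map$grid), mean(map$grid)))  # DMIN DMAX DMEAN
  wi(1)                                   # ISPG
  wi(0)                                   # NSYMBT
  writeBin(raw(100), con)                 # EXTRA (words 26-49)
  wf(map$origin)                          # ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)   # MAP stamp
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(as.vector(map$grid)))      # RMS
  wi(0)                                   # NLABL
  writeBin(raw(800), con)                 # labels
  writeBin(as.numeric(map$grid), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4, endian = "little")
  d <- ri(3)
  if (any(d <= 0) || any(d > 1e5))
    stop("malformed MRC file: implausible NX/NY/NZ = ", paste(d, collapse = ","))
  mode <- ri(1)
  if (mode != 2)
    stop("unsupported MRC MODE ", mode, " (only mode 2, 32-bit float)")
  ri(3)                                   # NXSTART..
  m <- ri(3)                              # MX MY MZ
  cella <- rf(3)
  rf(3)                                   # CELLB
  mapcrs <- ri(3)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order MAPC/MAPR/MAPS = ",
         paste(mapcrs, collapse = ","))
  rf(3)                                   # stats
  ri(1); nsymbt <- ri(1)
  readBin(con, "raw", n = 100)
  origin <- rf(3)
  stamp <- readChar(con, 4, useBytes = TRUE)
  if (!identical(substr(stamp, 1, 3), "MAP"))
    stop("malformed MRC file: missing 'MAP ' stamp in header word 53")
  readBin(con, "raw", n = 4)              # MACHST
  rf(1)                                   # RMS
  ri(1)                                   # NLABL
  readBin(con, "raw", n = 800)
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  vals <- readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
  if (length(vals) < prod(d))
    stop("malformed MRC file: data section truncated (expected ", prod(d),
         " voxels, got ", length(vals), ")")
  vs <- cella[1] / m[1]
  density_map(array(vals, dim = d), voxel_size = vs, origin = origin)
}
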