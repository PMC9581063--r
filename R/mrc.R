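# MRC2014 volume input/output.
#
# Hand-rolled binary reader/writer for the MRC2014 map format (the standard
# interchange format for cryo-EM volumes). Only orthogonal cells and data
# modes 0 (int8), 1 (int16) and 2 (float32) are supported; files are written
# in mode 2 with canonical (x, y, z) axis order, and arbitrary MAPC/MAPR/MAPS
# axis permutations are honored on read.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC2014 density map
#'
#' Reads a volume in MRC format and returns it with canonical (x, y, z) axis
#' order regardless of the header's MAPC/MAPR/MAPS permutation. The origin is
#' taken as `ORIGIN + NSTART * voxel_size` so that both header conventions
#' place voxels at the same world coordinates.
#'
#' @param path path to an MRC file.
#' @return A [density_map()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  fsize <- file.info(path)$size
  if (is.na(fsize) || fsize < MRC_HEADER_BYTES)
    stop("malformed MRC header: file shorter than 1024 bytes (", path, ")")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", MRC_HEADER_BYTES)

  int_at <- function(w) readBin(hdr[(4 * (w - 1) + 1):(4 * w)], "integer",
                                size = 4L, endian = "little")
  flt_at <- function(w) readBin(hdr[(4 * (w - 1) + 1):(4 * w)], "numeric",
                                size = 4L, endian = "little")

  nxyz  <- vapply(1:3, int_at, integer(1))   # columns, rows, sections
  mode  <- int_at(4L)
  nstart <- vapply(5:7, int_at, integer(1))
  mxyz  <- vapply(8:10, int_at, integer(1))
  cella <- vapply(11:13, flt_at, numeric(1))
  mapcrs <- vapply(17:19, int_at, integer(1))
  nsymbt <- int_at(24L)
  orig  <- vapply(50:52, flt_at, numeric(1))
  map_stamp_ok <- identical(hdr[(4 * 52 + 1):(4 * 52 + 3)], charToRaw("MAP"))

  if (any(nxyz < 1L) || any(nxyz > 100000L) || any(mxyz < 1L))
    stop("malformed MRC header: implausible dimensions in ", path)
  if (!identical(sort(mapcrs), 1:3))
    stop("malformed MRC header: MAPC/MAPR/MAPS = ",
         paste(mapcrs, collapse = ","), " is not a permutation of 1:3")
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode ", mode,
         " (only 0 = int8, 1 = int16, 2 = float32 are supported)")
  if (nsymbt < 0L) stop("malformed MRC header: negative NSYMBT")
  if (!map_stamp_ok)
    warning("MRC file lacks 'MAP ' stamp; attempting to read anyway")

  n <- prod(as.double(nxyz))
  need <- MRC_HEADER_BYTES + nsymbt + n * c(`0` = 1, `1` = 2, `2` = 4)[[as.character(mode)]]
  if (fsize < need)
    stop("malformed MRC file: data section truncated (", path, ")")
  if (nsymbt > 0L) readBin(con, "raw", nsymbt)

  vals <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE,
                             endian = "little")),
    `1` = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE,
                             endian = "little")),
    `2` = readBin(con, "numeric", n, size = 4L, endian = "little"))

  a_file <- array(vals, dim = nxyz)          # axes (MAPC, MAPR, MAPS)
  perm <- order(mapcrs)                      # file dim holding world axis a
  a <- aperm(a_file, perm)

  voxel_size <- cella / mxyz
  if (any(voxel_size <= 0)) stop("malformed MRC header: non-positive voxel size")
  nstart_xyz <- numeric(3)
  nstart_xyz[mapcrs] <- nstart               # starts are in file axis order
  origin <- orig + nstart_xyz * voxel_size

  density_map(a, origin = origin, voxel_size = voxel_size)
}

#' Write a density map as MRC2014
#'
#' Writes mode 2 (float32) with canonical axis order, the grid origin in the
#' ORIGIN header words, and CELLA = dimensions x voxel size.
#'
#' @param map a [density_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))

  d <- dim(map$data)
  vals <- as.numeric(map$data)
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  wi(d)                                  # 1-3   NX NY NZ
  wi(2L)                                 # 4     MODE float32
  wi(c(0L, 0L, 0L))                      # 5-7   NSTART
  wi(d)                                  # 8-10  MX MY MZ
  wf(d * map$voxel_size)                 # 11-13 CELLA
  wf(c(90, 90, 90))                      # 14-16 CELLB
  wi(1:3)                                # 17-19 MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))# 20-22 DMIN DMAX DMEAN
  wi(c(0L, 0L))                          # 23-24 ISPG NSYMBT
  wi(rep(0L, 2L))                        # 25-26 extra
  writeBin(charToRaw("MRCO"), con)       # 27    EXTTYP
  wi(20140L)                             # 28    NVERSION
  wi(rep(0L, 21L))                       # 29-49 extra
  wf(map$origin)                         # 50-52 ORIGIN
  writeBin(charToRaw("MAP "), con)       # 53    map stamp
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # 54 MACHST little-endian
  wf(stats::sd(vals) * sqrt(max(length(vals) - 1, 1) / length(vals)))  # 55 RMS
  wi(0L)                                 # 56    NLABL
  writeBin(raw(800L), con)               # labels
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(path)
}
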