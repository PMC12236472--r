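#' Read an MRC/CCP4 density map
#'
#' Minimal MRC2014 reader covering the map modes used for cryo-EM volumes
#' (mode 0 int8, 1 int16, 2 float32). Axis correspondence is taken from the
#' MAPC/MAPR/MAPS header words and the volume is reordered so the returned
#' array is indexed (z, y, x). The origin is read from the ORIGIN header
#' words; when those are all zero the NxSTART words (times the voxel size)
#' are used, which is the common CCP4 convention.
#'
#' @param path path to an MRC/CCP4 file.
#' @return A [density_map].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("read_map: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256L, size = 4L, endian = "little")
  seek(con, 0L)
  hdr_dbl <- readBin(con, "numeric", n = 256L, size = 4L, endian = "little")

  nc <- hdr_int[1]; nr <- hdr_int[2]; ns <- hdr_int[3]
  mode <- hdr_int[4]
  if (any(c(nc, nr, ns) <= 0L))
    stop("read_map: data is not a 3-D volume (nx/ny/nz = ",
         paste(c(nc, nr, ns), collapse = "x"), ")")
  nstart <- hdr_int[5:7]
  m <- hdr_int[8:10]                     # mx, my, mz (sampling grid)
  cella <- hdr_dbl[11:13]                # cell dimensions in Angstrom
  mapc <- hdr_int[17]; mapr <- hdr_int[18]; maps <- hdr_int[19]
  if (!all(sort(c(mapc, mapr, maps)) == 1:3))
    stop("read_map: corrupt header: MAPC/MAPR/MAPS must be a permutation of 1:3")
  seek(con, 49L * 4L)          # ORIGIN: header words 50-52
  origin_words <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, 208L)
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic[1:3], as.raw(c(0x4d, 0x41, 0x50))))
    warning("read_map: missing 'MAP ' magic; attempting to read anyway")

  if (any(m <= 0L)) m <- c(nc, nr, ns)[order(c(mapc, mapr, maps))]
  voxel <- ifelse(cella > 0, cella / m, 1)

  seek(con, 1024L + hdr_int[24])         # skip extended header (NSYMBT bytes)
  nvox <- as.double(nc) * nr * ns
  dat <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = nvox, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = nvox, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = nvox, size = 4L, endian = "little"),
    stop("read_map: unsupported MRC mode ", mode))
  if (length(dat) < nvox)
    stop("read_map: truncated data section (expected ", nvox,
         " voxels, got ", length(dat), ")")
  vol <- array(as.numeric(dat), dim = c(nc, nr, ns))  # column, row, section

  # permute so that axis order is x, y, z, then flip to (z, y, x) indexing
  ax <- c(mapc, mapr, maps)              # axis (1=x,2=y,3=z) of col/row/sec
  perm <- match(1:3, ax)                 # which array dim holds x, y, z
  vol_xyz <- aperm(vol, perm)
  vol_zyx <- aperm(vol_xyz, c(3L, 2L, 1L))

  origin <- origin_words
  if (all(origin == 0) && any(nstart != 0L)) {
    start_xyz <- nstart[perm]
    origin <- start_xyz * voxel
  }
  density_map(vol_zyx, origin = origin, voxel_size = voxel)
}

#' Write a density map as MRC2014 (mode 2 float)
#'
#' @param map a [density_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$data)                     # nz, ny, nx
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, nz))                      # NX NY NZ (columns = x fastest)
  wi(2L)                                 # MODE 2 = float32
  wi(c(0L, 0L, 0L))                      # NXSTART..
  wi(c(nx, ny, nz))                      # MX MY MZ
  wf(c(nx, ny, nz) * map$voxel_size)     # CELLA
  wf(c(90, 90, 90))                      # CELLB
  wi(c(1L, 2L, 3L))                      # MAPC MAPR MAPS
  wf(c(min(map$data), max(map$data), mean(map$data)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))                          # ISPG, NSYMBT
  wi(rep(0L, 25L))                       # EXTRA (words 26-50)
  wf(map$origin)                         # ORIGIN x y z (words 50-52)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)     # MACHST little-endian
  wf(stats::sd(as.numeric(map$data)))    # RMS
  wi(0L)                                 # NLABL
  writeBin(raw(800L), con)               # labels
  vol_xyz <- aperm(map$data, c(3L, 2L, 1L))            # back to x fastest
  writeBin(as.numeric(vol_xyz), con, size = 4L, endian = "little")
  invisible(path)
}
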