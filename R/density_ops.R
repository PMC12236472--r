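#' Resample a density map to 1 Angstrom voxels
#'
#' Trilinear interpolation onto a unit-spacing grid sharing the map origin.
#' The resampled dimension along each axis is `round(extent_A) + 1` where
#' `extent_A = (n - 1) * voxel`, so the physical extent is preserved to
#' within one voxel. A map already at 1 A spacing is returned unchanged.
#'
#' @param map a [density_map].
#' @param target numeric, target spacing in Angstrom (default 1).
#' @return A [density_map] with `voxel_size = (target, target, target)`.
#' @export
resample_to_unit_voxel <- function(map, target = 1.0) {
  stopifnot(inherits(map, "density_map"))
  if (all(abs(map$voxel_size - target) < 1e-9)) return(map)
  d <- dim(map$data)                              # nz, ny, nx
  vs_zyx <- rev(map$voxel_size)                   # voxel along z, y, x
  new_d <- pmax(1L, as.integer(round_half_up((d - 1L) * vs_zyx / target)) + 1L)

  # positions of the new grid points in old fractional (1-based) indices
  ax <- lapply(1:3, function(a) {
    pos <- (seq_len(new_d[a]) - 1) * target / vs_zyx[a] + 1
    pmin(pmax(pos, 1), d[a])
  })
  i0 <- lapply(1:3, function(a) pmin(floor(ax[[a]]), d[a] - (d[a] > 1L)))
  fr <- lapply(1:3, function(a) ax[[a]] - i0[[a]])

  out <- array(0, dim = new_d)
  g <- expand.grid(z = seq_len(new_d[1]), y = seq_len(new_d[2]),
                   x = seq_len(new_d[3]))
  z0 <- i0[[1]][g$z]; y0 <- i0[[2]][g$y]; x0 <- i0[[3]][g$x]
  fz <- fr[[1]][g$z]; fy <- fr[[2]][g$y]; fx <- fr[[3]][g$x]
  z1 <- pmin(z0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); x1 <- pmin(x0 + 1L, d[3])
  v <- map$data
  idx <- function(a, b, c) v[cbind(a, b, c)]
  out[] <-
    idx(z0, y0, x0) * (1 - fz) * (1 - fy) * (1 - fx) +
    idx(z1, y0, x0) * fz       * (1 - fy) * (1 - fx) +
    idx(z0, y1, x0) * (1 - fz) * fy       * (1 - fx) +
    idx(z0, y0, x1) * (1 - fz) * (1 - fy) * fx +
    idx(z1, y1, x0) * fz       * fy       * (1 - fx) +
    idx(z1, y0, x1) * fz       * (1 - fy) * fx +
    idx(z0, y1, x1) * (1 - fz) * fy       * fx +
    idx(z1, y1, x1) * fz       * fy       * fx
  density_map(out, origin = map$origin, voxel_size = rep(target, 3),
              resolution = map$resolution)
}

#' Normalize a density map to [0, 1]
#'
#' Robust standardization: subtract the median, clip values above the 99.9th
#' percentile of the median-subtracted data to that percentile, floor
#' negatives at zero, then min-max scale to [0, 1]. An all-constant map maps
#' to all zeros (degenerate case, no error).
#'
#' @param map a [density_map].
#' @param upper_quantile upper clipping quantile (default 0.999).
#' @return A [density_map] with all values in [0, 1].
#' @export
normalize_map <- function(map, upper_quantile = 0.999) {
  stopifnot(inherits(map, "density_map"))
  v <- as.numeric(map$data)
  if (any(!is.finite(v))) stop("normalize_map: map contains non-finite values")
  v <- v - stats::median(v)
  hi <- stats::quantile(v, probs = upper_quantile, names = FALSE, type = 7)
  v[v > hi] <- hi
  v[v < 0] <- 0
  mx <- max(v)
  v <- if (mx > 0) v / mx else v * 0
  out <- map
  out$data <- array(v, dim = dim(map$data))
  out
}

#' Partition a map into padded processing windows
#'
#' Tiles the volume with non-overlapping `core`-sized cubes starting at the
#' origin corner and wraps each core with `pad` voxels of context on all six
#' faces (default 48 + 2*8 = 64). Context falling outside the map, and the
#' remainder of partial edge tiles, is zero-filled.
#'
#' @param map a [density_map] (or a bare 3-D array).
#' @param core core tile edge length in voxels (default 48).
#' @param pad context padding per face in voxels (default 8).
#' @return A `grid_batch`: list with `windows` (list of (core+2*pad)^3
#'   arrays), `core_offsets` (integer matrix of zero-based (i,j,k) core
#'   origins), `full_shape`, `core`, `pad`.
#' @export
partition_grids <- function(map, core = 48L, pad = 8L) {
  vol <- if (inherits(map, "density_map")) map$data else map
  if (!is.array(vol) || length(dim(vol)) != 3L || any(dim(vol) < 1L))
    stop("partition_grids: need a non-empty 3-D volume")
  d <- dim(vol)
  win <- core + 2L * pad
  ntile <- as.integer(ceiling(d / core))
  offs <- as.matrix(expand.grid(
    i = (seq_len(ntile[1]) - 1L) * core,
    j = (seq_len(ntile[2]) - 1L) * core,
    k = (seq_len(ntile[3]) - 1L) * core))
  windows <- vector("list", nrow(offs))
  for (w in seq_len(nrow(offs))) {
    block <- array(0, dim = rep(win, 3L))
    # window spans [off - pad, off - pad + win) in zero-based map indices
    lo <- offs[w, ] - pad                        # zero-based inclusive
    src_lo <- pmax(lo, 0L); src_hi <- pmin(lo + win, d) - 1L
    if (all(src_hi >= src_lo)) {
      dst_lo <- src_lo - lo
      block[(dst_lo[1] + 1L):(dst_lo[1] + 1L + src_hi[1] - src_lo[1]),
            (dst_lo[2] + 1L):(dst_lo[2] + 1L + src_hi[2] - src_lo[2]),
            (dst_lo[3] + 1L):(dst_lo[3] + 1L + src_hi[3] - src_lo[3])] <-
        vol[(src_lo[1] + 1L):(src_hi[1] + 1L),
            (src_lo[2] + 1L):(src_hi[2] + 1L),
            (src_lo[3] + 1L):(src_hi[3] + 1L)]
    }
    windows[[w]] <- block
  }
  structure(list(windows = windows, core_offsets = offs, full_shape = d,
                 core = as.integer(core), pad = as.integer(pad)),
            class = "grid_batch")
}

#' Re-stitch per-window outputs into a full-map volume
#'
#' Writes only the central `core`^3 region of each window at its core offset
#' and crops to the original map shape, so `stitch_volumes(partition_grids(x)
#' $windows, batch)` reproduces `x` exactly. Window outputs may carry a
#' leading channel dimension (4-D arrays, channels first).
#'
#' @param batch_outputs list of per-window outputs, each a `win^3` array or a
#'   `C x win^3` 4-D array.
#' @param batch the `grid_batch` the windows came from.
#' @return A 3-D array of `full_shape`, or a 4-D `C x full_shape` array.
#' @export
stitch_volumes <- function(batch_outputs, batch) {
  stopifnot(inherits(batch, "grid_batch"))
  nwin <- nrow(batch$core_offsets)
  if (length(batch_outputs) != nwin)
    stop("stitch_volumes: expected ", nwin, " window outputs, got ",
         length(batch_outputs))
  win <- batch$core + 2L * batch$pad
  first <- batch_outputs[[1]]
  nd <- length(dim(first))
  if (!nd %in% c(3L, 4L)) stop("stitch_volumes: outputs must be 3-D or 4-D")
  nchan <- if (nd == 4L) dim(first)[1] else 1L
  for (w in seq_len(nwin)) {
    dw <- dim(batch_outputs[[w]])
    if (!identical(unname(dw[(nd - 2L):nd]), rep(win, 3L)) ||
        length(dw) != nd || (nd == 4L && dw[1] != nchan))
      stop("stitch_volumes: window ", w, " has wrong shape")
  }
  d <- batch$full_shape
  out <- array(0, dim = c(nchan, d))
  pad <- batch$pad; core <- batch$core
  for (w in seq_len(nwin)) {
    x <- batch_outputs[[w]]
    if (nd == 3L) dim(x) <- c(1L, dim(x))
    off <- batch$core_offsets[w, ]
    take <- pmin(core, d - off)                 # crop partial edge tiles
    out[, (off[1] + 1L):(off[1] + take[1]),
          (off[2] + 1L):(off[2] + take[2]),
          (off[3] + 1L):(off[3] + take[3])] <-
      x[, (pad + 1L):(pad + take[1]),
          (pad + 1L):(pad + take[2]),
          (pad + 1L):(pad + take[3])]
  }
  if (nchan == 1L) { dim(out) <- d; out } else out
}
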