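#' Density map object
#'
#' A cryo-EM density volume plus the header metadata needed to relate voxel
#' indices to Cartesian coordinates. Data are stored internally as a 3-D
#' array indexed `[i, j, k]` with i running along z, j along y and k along x
#' (the z,y,x convention used throughout the package); all file I/O converts
#' explicitly.
#'
#' @param data numeric 3-D array, dim = (nz, ny, nx).
#' @param origin numeric length-3, map origin in Angstrom as (x, y, z).
#' @param voxel_size numeric length-3, Angstrom per voxel as (x, y, z);
#'   a scalar is recycled.
#' @param resolution optional nominal map resolution in Angstrom (metadata).
#' @return An object of class `density_map`.
#' @export
density_map <- function(data, origin = c(0, 0, 0), voxel_size = c(1, 1, 1),
                        resolution = NA_real_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("density_map: `data` must be a 3-D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("density_map: voxel_size components must be > 0")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(
    list(data = data, origin = origin, voxel_size = voxel_size,
         resolution = as.numeric(resolution)),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_map> %d x %d x %d voxels (z,y,x)\n", d[1], d[2], d[3]))
  cat(sprintf("  origin (x,y,z):  %.3f %.3f %.3f A\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  voxel  (x,y,z):  %.3f %.3f %.3f A\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  if (is.finite(x$resolution))
    cat(sprintf("  resolution:      %.2f A\n", x$resolution))
  cat(sprintf("  value range:     [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$data)

# half-up nearest-integer rounding; base round() is half-to-even
round_half_up <- function(x) floor(x + 0.5)

#' Convert Cartesian coordinates to voxel indices
#'
#' Maps an atom coordinate (x, y, z) in Angstrom to zero-based grid indices
#' (i, j, k) of the map, with i derived from z, j from y and k from x:
#' `index = round((coord - origin) / voxel)` with half-up rounding. Indices
#' may fall outside the map; callers are expected to bounds-check.
#'
#' @param xyz numeric matrix (n x 3) or length-3 vector of coordinates in
#'   Angstrom, columns (x, y, z).
#' @param map a [density_map].
#' @return Integer matrix (n x 3) of zero-based indices, columns (i, j, k).
#' @export
coord_to_index <- function(xyz, map) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  i <- round_half_up((xyz[, 3] - map$origin[3]) / map$voxel_size[3])
  j <- round_half_up((xyz[, 2] - map$origin[2]) / map$voxel_size[2])
  k <- round_half_up((xyz[, 1] - map$origin[1]) / map$voxel_size[1])
  cbind(i = as.integer(i), j = as.integer(j), k = as.integer(k))
}

#' Convert voxel indices to Cartesian coordinates of voxel centers
#'
#' Inverse of [coord_to_index()] up to rounding: (i, j, k) zero-based indices
#' map to `(x, y, z) = origin + (k, j, i) * voxel`.
#'
#' @param ijk integer matrix (n x 3) of zero-based indices, columns (i, j, k).
#' @param map a [density_map].
#' @return Numeric matrix (n x 3), columns (x, y, z), Angstrom.
#' @export
index_to_coord <- function(ijk, map) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3L)
  x <- map$origin[1] + ijk[, 3] * map$voxel_size[1]
  y <- map$origin[2] + ijk[, 2] * map$voxel_size[2]
  z <- map$origin[3] + ijk[, 1] * map$voxel_size[3]
  cbind(x = x, y = y, z = z)
}

in_bounds <- function(ijk, shape) {
  ijk[, 1] >= 0L & ijk[, 1] < shape[1] &
    ijk[, 2] >= 0L & ijk[, 2] < shape[2] &
    ijk[, 3] >= 0L & ijk[, 3] < shape[3]
}
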