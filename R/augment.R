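#' Augment one training window
#'
#' On-the-fly augmentation for (density, encoding, masks) windows. Intensity
#' augmentations -- additive Gaussian noise, Gaussian blurring and a random
#' multiplicative intensity scale -- touch the density channel only. Spatial
#' augmentations -- random 90-degree rotations about the three axes, axis
#' flips, and small integer translations (zero-filled) -- are applied
#' identically to the density window, every encoding channel and every mask,
#' so voxel correspondence is preserved and masks stay integer-valued.
#'
#' @param density `w^3` numeric array.
#' @param af3 `24 x w^3` numeric array or NULL.
#' @param masks `label_masks` list (integer arrays), or NULL.
#' @param rng_seed integer seed making the draw reproducible.
#' @param noise_sd sd of additive Gaussian noise (density units).
#' @param blur_sd sd in voxels of the Gaussian blur (0 disables).
#' @param max_shift maximum translation per axis, voxels.
#' @return List with augmented `density`, `af3`, `masks`.
#' @export
augment_batch <- function(density, af3 = NULL, masks = NULL, rng_seed = 1L,
                          noise_sd = 0.02, blur_sd = 0.5, max_shift = 4L) {
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  d <- dim(density)

  # intensity (density only)
  if (stats::runif(1) < 0.5 && blur_sd > 0)
    density <- gaussian_blur3(density, blur_sd)
  if (noise_sd > 0)
    density <- density + array(stats::rnorm(length(density), sd = noise_sd), d)
  density <- density * stats::runif(1, 0.9, 1.1)

  # spatial transform: rotation k in 0..3 per axis pair, flips, translation
  rots <- sample(0:3, 3L, replace = TRUE)
  flips <- stats::runif(3) < 0.5
  shift <- sample(seq(-max_shift, max_shift), 3L, replace = TRUE)
  tf <- function(a) spatial_transform(a, rots, flips, shift)

  density <- tf(density)
  if (!is.null(af3)) {
    for (c1 in seq_len(dim(af3)[1]))
      af3[c1, , , ] <- tf(array(af3[c1, , , ], d))
  }
  if (!is.null(masks))
    masks <- structure(lapply(masks, function(m) {
      if (length(dim(m)) == 3L) {
        mm <- tf(m); storage.mode(mm) <- "integer"; mm
      } else m
    }), class = class(masks))
  list(density = density, af3 = af3, masks = masks)
}

# rotations are about axis 3, then 2, then 1 (90 deg * rots[i]); flips
# reverse axes; translation shifts with zero fill. Cubic windows only.
spatial_transform <- function(a, rots, flips, shift) {
  rot90_ax <- function(x, axes) {
    # rotate 90 degrees in the plane of the two given axes
    perm <- seq_along(dim(x)); perm[axes] <- axes[2:1]
    x <- aperm(x, perm)
    idx <- rep(list(quote(expr = )), 3L)
    idx[[axes[1]]] <- rev(seq_len(dim(x)[axes[1]]))
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  for (ax in 1:3) {
    pair <- setdiff(1:3, ax)
    r <- rots[ax] %% 4L
    while (r > 0L) { a <- rot90_ax(a, pair); r <- r - 1L }
  }
  for (ax in 1:3) if (flips[ax]) {
    idx <- rep(list(quote(expr = )), 3L)
    idx[[ax]] <- rev(seq_len(dim(a)[ax]))
    a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  if (any(shift != 0L)) {
    d <- dim(a)
    out <- array(if (is.integer(a)) 0L else 0, d)
    src <- dst <- vector("list", 3L)
    for (ax in 1:3) {
      s <- shift[ax]
      src[[ax]] <- seq_len(d[ax])[seq_len(d[ax]) - s >= 1 &
                                  seq_len(d[ax]) - s <= d[ax]] - s
      dst[[ax]] <- src[[ax]] + s
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    a <- out
  }
  a
}

#' Gaussian blur of a 3-D volume
#'
#' Separable Gaussian smoothing (truncated at 3 sd), used by the
#' augmentation pipeline and available for simulating lower-resolution maps.
#'
#' @param a 3-D numeric array.
#' @param sd kernel standard deviation in voxels.
#' @return Blurred array of the same shape.
#' @export
gaussian_blur3 <- function(a, sd) {
  r <- max(1L, ceiling(3 * sd))
  kx <- stats::dnorm(-r:r, sd = sd); kx <- kx / sum(kx)
  k <- length(kx)
  d <- dim(a)
  # separable passes via the conv3d kernel (1-channel, kernel on one axis)
  for (ax in 1:3) {
    kern <- array(0, rep(k, 3L)); mid <- r + 1L
    idx <- rep(list(mid), 3L); idx[[ax]] <- seq_len(k)
    kern[cbind(idx[[1]], idx[[2]], idx[[3]])] <- kx
    w <- matrix(as.numeric(kern), nrow = 1L)
    a <- array(conv3d_fw(matrix(as.numeric(a), 1L), d, w, 0, k), d)
  }
  a
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
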