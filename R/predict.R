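#' Whole-map network inference
#'
#' Partitions a normalized map (and its optional predicted-structure
#' encoding) into padded windows, runs the network on each, stitches the
#' per-window logits back to the full map shape, and converts logits to the
#' three probability volumes: `backbone_p` and `calpha_p` are the softmax
#' probability of the atom class (label 3) of their 4-class tasks, and
#' `amino_p` is the 21-class softmax with the "no amino acid" class dropped
#' and the 20 type probabilities renormalized per voxel.
#'
#' @param model a `voxel_model` whose window size matches `core + 2*pad`.
#' @param map a normalized [density_map] at 1 Angstrom voxels.
#' @param af3 optional `af3_encoding` (24 x map-shape array) or NULL.
#' @param core,pad partition geometry (defaults 48 and 8).
#' @return A `prediction_volumes` list: `backbone_p`, `calpha_p` (arrays of
#'   the map shape) and `amino_p` (20 x map shape).
#' @export
predict_map <- function(model, map, af3 = NULL, core = 48L, pad = 8L) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$data)
  if (!is.null(af3)) {
    da <- dim(af3)
    if (length(da) != 4L || da[1] != 24L || !identical(unname(da[2:4]), d))
      stop("predict_map: AF3 encoding shape does not match the map")
  }
  win <- core + 2L * pad
  if (model$config$window != win)
    stop("predict_map: model window (", model$config$window,
         ") != core + 2*pad (", win, ")")
  batch <- partition_grids(map, core = core, pad = pad)
  nwin <- nrow(batch$core_offsets)
  out_bb <- vector("list", nwin); out_ca <- vector("list", nwin)
  out_aa <- vector("list", nwin)
  for (w in seq_len(nwin)) {
    af3_win <- if (is.null(af3)) NULL else
      channel_window(af3, batch$core_offsets[w, ], win, pad, d)
    fw <- forward_window(model, batch$windows[[w]], af3_win)
    out_bb[[w]] <- fw$backbone; out_ca[[w]] <- fw$calpha
    out_aa[[w]] <- fw$amino
  }
  bb_logit <- stitch_volumes(out_bb, batch)      # 4 x map shape
  ca_logit <- stitch_volumes(out_ca, batch)
  aa_logit <- stitch_volumes(out_aa, batch)      # 21 x map shape

  structure(list(
    backbone_p = array(softmax_class(bb_logit, 4L), d),
    calpha_p = array(softmax_class(ca_logit, 4L), d),
    amino_p = amino_softmax(aa_logit)),
    class = "prediction_volumes")
}

# per-voxel softmax over the channel dimension; returns the probability of
# the given 1-based class channel
softmax_class <- function(logit4, class_channel) {
  m <- matrix(logit4, nrow = dim(logit4)[1])
  mx <- apply(m, 2L, max)
  ex <- exp(sweep(m, 2L, mx))
  ex[class_channel, ] / colSums(ex)
}

# 21-channel softmax; channel 1 ("no amino acid") dropped, rest renormalized
amino_softmax <- function(logit21) {
  d <- dim(logit21)
  m <- matrix(logit21, nrow = 21L)
  mx <- apply(m, 2L, max)
  ex <- exp(sweep(m, 2L, mx))
  p <- sweep(ex, 2L, colSums(ex), `/`)
  p20 <- p[-1L, , drop = FALSE]
  p20 <- sweep(p20, 2L, pmax(colSums(p20), 1e-12), `/`)
  array(p20, c(20L, d[2:4]))
}

# extract the (win^3) block of a multi-channel volume matching a partition
# window at the given core offset (zero-filled outside the map)
channel_window <- function(vol, off, win, pad, d) {
  C <- dim(vol)[1]
  block <- array(0, c(C, win, win, win))
  lo <- off - pad
  src_lo <- pmax(lo, 0L); src_hi <- pmin(lo + win, d) - 1L
  if (all(src_hi >= src_lo)) {
    dst_lo <- src_lo - lo
    block[, (dst_lo[1] + 1L):(dst_lo[1] + 1L + src_hi[1] - src_lo[1]),
            (dst_lo[2] + 1L):(dst_lo[2] + 1L + src_hi[2] - src_lo[2]),
            (dst_lo[3] + 1L):(dst_lo[3] + 1L + src_hi[3] - src_lo[3])] <-
      vol[, (src_lo[1] + 1L):(src_hi[1] + 1L),
            (src_lo[2] + 1L):(src_hi[2] + 1L),
            (src_lo[3] + 1L):(src_hi[3] + 1L)]
  }
  block
}
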