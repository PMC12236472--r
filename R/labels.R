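#' Build training label masks from a reference structure
#'
#' Produces the three integer voxel masks used as multi-task training
#' targets, all shaped like the paired map:
#'
#' * `backbone`: 3 at voxels containing any backbone atom (N, CA, C, O),
#'   2 at voxels containing any other atom, 1 at voxels 26-adjacent to any
#'   atom, 0 elsewhere.
#' * `calpha`: 3 at CA voxels, 2 at voxels containing any other atom,
#'   1 at neighbors, 0 elsewhere.
#' * `amino`: the residue's amino-acid code (1-20) at each CA voxel and its
#'   26-neighborhood, 0 elsewhere. When two residues claim a voxel the one
#'   whose CA is nearer the voxel center wins.
#'
#' Higher labels always take precedence; out-of-bounds atoms are skipped.
#'
#' @param truth a [protein_structure] in the map frame.
#' @param map the paired [density_map].
#' @return A list of class `label_masks` with integer arrays `backbone`,
#'   `calpha`, `amino`.
#' @export
make_label_masks <- function(truth, map) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$data)
  backbone <- array(0L, d); calpha <- array(0L, d); amino <- array(0L, d)
  a <- truth$atoms
  if (nrow(a) == 0L) {
    warning("make_label_masks: empty structure; masks are all zero")
    return(structure(list(backbone = backbone, calpha = calpha, amino = amino),
                     class = "label_masks"))
  }
  ijk <- coord_to_index(as.matrix(a[, c("x", "y", "z")]), map)
  ok <- in_bounds(ijk, d)
  a <- a[ok, , drop = FALSE]; ijk <- ijk[ok, , drop = FALSE]
  if (nrow(a) == 0L) {
    warning("make_label_masks: no in-bounds atoms; masks are all zero")
    return(structure(list(backbone = backbone, calpha = calpha, amino = amino),
                     class = "label_masks"))
  }
  sub <- ijk + 1L                               # 1-based array subscripts

  # label 1: 26-neighborhood of every atom (lowest precedence, write first)
  nb <- neighbor_subs(sub, d)
  backbone[nb] <- 1L
  calpha[nb] <- 1L

  # label 2: voxels with atoms (any atom for backbone mask; non-CA for both)
  is_bb <- a$atom %in% c("N", "CA", "C", "O")
  is_ca <- a$atom == "CA"
  backbone[sub[!is_bb, , drop = FALSE]] <- 2L
  calpha[sub[!is_ca, , drop = FALSE]] <- 2L

  # label 3: backbone atoms / CA atoms (highest precedence)
  backbone[sub[is_bb, , drop = FALSE]] <- 3L
  calpha[sub[is_ca, , drop = FALSE]] <- 3L

  # amino mask: CA voxel + neighborhood get the residue's code; nearest CA
  # wins on collision
  ca <- a[is_ca, , drop = FALSE]
  ca_sub <- sub[is_ca, , drop = FALSE]
  code <- aa_code(ca$aa)
  keep <- !is.na(code)
  ca <- ca[keep, , drop = FALSE]; ca_sub <- ca_sub[keep, , drop = FALSE]
  code <- code[keep]
  if (nrow(ca) > 0L) {
    offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    best <- array(Inf, d)                       # distance of winning CA
    for (r in seq_len(nrow(ca))) {
      pts <- sweep(offs, 2L, unname(ca_sub[r, ]), `+`)
      inb <- pts[, 1] >= 1L & pts[, 1] <= d[1] &
             pts[, 2] >= 1L & pts[, 2] <= d[2] &
             pts[, 3] >= 1L & pts[, 3] <= d[3]
      pts <- pts[inb, , drop = FALSE]
      centers <- index_to_coord(pts - 1L, map)
      dist2 <- (centers[, 1] - ca$x[r])^2 + (centers[, 2] - ca$y[r])^2 +
               (centers[, 3] - ca$z[r])^2
      for (q in seq_len(nrow(pts))) {
        if (dist2[q] < best[pts[q, 1], pts[q, 2], pts[q, 3]]) {
          best[pts[q, 1], pts[q, 2], pts[q, 3]] <- dist2[q]
          amino[pts[q, 1], pts[q, 2], pts[q, 3]] <- code[r]
        }
      }
    }
  }
  structure(list(backbone = backbone, calpha = calpha, amino = amino),
            class = "label_masks")
}

# 1-based subscripts of the 26-neighborhoods of the given voxels, clipped to
# the volume; returns a deduplicated n x 3 matrix
neighbor_subs <- function(sub, d) {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(offs != 0L) > 0L, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
    sweep(sub, 2L, offs[r, ], `+`)))
  out <- out[out[, 1] >= 1L & out[, 1] <= d[1] &
             out[, 2] >= 1L & out[, 2] <= d[2] &
             out[, 3] >= 1L & out[, 3] <= d[3], , drop = FALSE]
  unique(out)
}
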