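#' Encode a placed predicted structure as a 24-channel voxel volume
#'
#' Binary channel-wise encoding of a predicted structure already docked into
#' the map coordinate frame: channels 1-4 mark voxels containing backbone
#' CA, N, C and O atoms respectively; channels 5-24 mark, at each residue's
#' CA voxel, the residue's amino-acid type (codes 1-20, see [aa_alphabet()]).
#' The volume shape matches the paired density map exactly. Atoms falling
#' outside the map are skipped (a message reports the count); nonstandard
#' residues set no amino-acid channel.
#'
#' @param structure a [protein_structure] in the map frame.
#' @param map the paired [density_map] (1 Angstrom voxels).
#' @return Numeric 4-D array `24 x nz x ny x nx` with values in {0, 1},
#'   class `af3_encoding`. Channel order: CA, N, C, O, then the 20
#'   amino-acid types in code order.
#' @export
encode_af3 <- function(structure, map) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$data)
  enc <- array(0, dim = c(24L, d))
  atom_channels <- c(CA = 1L, N = 2L, C = 3L, O = 4L)
  a <- if (inherits(structure, "protein_structure")) structure$atoms else structure
  bb <- a[a$atom %in% names(atom_channels), , drop = FALSE]
  n_skipped <- 0L
  if (nrow(bb) > 0L) {
    ijk <- coord_to_index(as.matrix(bb[, c("x", "y", "z")]), map)
    ok <- in_bounds(ijk, d)
    n_skipped <- sum(!ok)
    if (any(ok)) {
      sel <- which(ok)
      ch <- atom_channels[bb$atom[sel]]
      enc[cbind(ch, ijk[sel, 1] + 1L, ijk[sel, 2] + 1L, ijk[sel, 3] + 1L)] <- 1
      is_ca <- bb$atom[sel] == "CA"
      code <- aa_code(bb$aa[sel])
      aa_ok <- is_ca & !is.na(code)
      if (any(aa_ok))
        enc[cbind(4L + code[aa_ok], ijk[sel[aa_ok], 1] + 1L,
                  ijk[sel[aa_ok], 2] + 1L, ijk[sel[aa_ok], 3] + 1L)] <- 1
    }
  }
  if (n_skipped > 0L)
    message("encode_af3: skipped ", n_skipped, " out-of-map atoms")
  if (nrow(bb) == 0L || n_skipped == nrow(bb))
    warning("encode_af3: no in-bounds backbone atoms; encoding is all zero")
  class(enc) <- c("af3_encoding", class(enc))
  enc
}
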