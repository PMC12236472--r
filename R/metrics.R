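#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation and translation mapping point set A onto B, minimizing
#' the RMSD over paired rows. Proper rotations only (reflections excluded).
#'
#' @param A,B numeric matrices (n x 3), paired rows, n >= 3.
#' @return List with `R` (3 x 3 rotation applied to centered A),
#'   `center_a`, `center_b`, `rmsd`, and `transformed` (A mapped onto B's
#'   frame).
#' @export
superpose_rmsd <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), nrow(A) >= 3L)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  At <- A0 %*% t(R) + matrix(cb, nrow(A), 3L, byrow = TRUE)
  list(R = R, center_a = ca, center_b = cb,
       rmsd = sqrt(mean(rowSums((At - B)^2))), transformed = At)
}

# coordinate matrices of model / truth C-alpha records
model_ca_coords <- function(model) {
  if (inherits(model, "backbone_model"))
    list(xyz = as.matrix(model[, c("x", "y", "z")]), aa = model$aa,
         resno = model$resno)
  else {
    ca <- ca_table(model)
    list(xyz = as.matrix(ca[, c("x", "y", "z")]), aa = ca$aa,
         resno = ca$resno)
  }
}

#' Greedy mutually-nearest C-alpha pairing
#'
#' One-to-one correspondence between model and reference C-alpha atoms in
#' the shared map frame (no superposition): pairs are accepted globally
#' closest first, each atom used at most once, only distances within
#' `cutoff`. Ties break lexicographically by (distance, model index,
#' reference index).
#'
#' @param model a `backbone_model` or [protein_structure].
#' @param truth the reference [protein_structure].
#' @param cutoff pairing distance cutoff, Angstrom (default 3.0).
#' @return data.frame with model_idx, truth_idx, dist (possibly 0 rows).
#' @export
ca_correspondence <- function(model, truth, cutoff = 3.0) {
  M <- model_ca_coords(model); TT <- model_ca_coords(truth)
  nm <- nrow(M$xyz); nt <- nrow(TT$xyz)
  empty <- data.frame(model_idx = integer(0), truth_idx = integer(0),
                      dist = numeric(0))
  if (nm == 0L || nt == 0L) return(empty)
  dd <- outer(rowSums(M$xyz^2), rowSums(TT$xyz^2), `+`) -
    2 * M$xyz %*% t(TT$xyz)
  dd <- sqrt(pmax(dd, 0))
  cand <- which(dd <= cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  ord <- order(dd[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_m <- rep(FALSE, nm); used_t <- rep(FALSE, nt)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    mi <- cand[r, 1]; ti <- cand[r, 2]
    if (!used_m[mi] && !used_t[ti]) {
      used_m[mi] <- TRUE; used_t[ti] <- TRUE; keep[r] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(model_idx = cand[, 1], truth_idx = cand[, 2],
             dist = dd[cand])
}

#' C-alpha match percentage
#'
#' Percentage of model C-alpha atoms paired with a reference C-alpha within
#' the cutoff (map-frame comparison, no superposition).
#'
#' @inheritParams ca_correspondence
#' @param pairing optional precomputed [ca_correspondence()] result.
#' @return Percentage in [0, 100].
#' @export
ca_match <- function(model, truth, cutoff = 3.0, pairing = NULL) {
  M <- model_ca_coords(model)
  if (nrow(M$xyz) == 0L) return(0)
  if (is.null(pairing)) pairing <- ca_correspondence(model, truth, cutoff)
  100 * nrow(pairing) / nrow(M$xyz)
}

#' C-alpha quality score
#'
#' Precision times coverage: the C-alpha match percentage multiplied by the
#' ratio of model residues to reference residues. Exceeds 100 when the
#' model contains more residues than the reference.
#'
#' @param match_pct C-alpha match percentage (vectorized).
#' @param model_length number of residues in the model.
#' @param reference_length number of residues in the reference (> 0).
#' @return The quality score(s).
#' @export
ca_quality_score <- function(match_pct, model_length, reference_length) {
  if (any(reference_length <= 0))
    stop("ca_quality_score: reference_length must be > 0")
  match_pct * model_length / reference_length
}

#' Sequence match percentage
#'
#' Percentage of paired C-alpha atoms whose amino-acid types agree.
#'
#' @inheritParams ca_match
#' @return Percentage in [0, 100]; 0 (with a warning) when no pairs exist.
#' @export
sequence_match <- function(model, truth, cutoff = 3.0, pairing = NULL) {
  if (is.null(pairing)) pairing <- ca_correspondence(model, truth, cutoff)
  if (nrow(pairing) == 0L) {
    warning("sequence_match: no paired C-alpha atoms")
    return(0)
  }
  M <- model_ca_coords(model); TT <- model_ca_coords(truth)
  100 * mean(M$aa[pairing$model_idx] == TT$aa[pairing$truth_idx])
}

#' TM-score over a given correspondence
#'
#' Rigid least-squares superposition of the paired C-alpha atoms followed
#' by the length-normalized similarity sum `TM = (1/L_ref) * sum_i
#' 1 / (1 + (d_i/d0)^2)` with `d0 = 1.24 * (L_ref - 15)^(1/3) - 1.8`
#' (floored at 0.5). Invariant to rigid motions of either structure. The
#' full alignment-search variant is delegated to an external structural
#' alignment tool (see [parse_usalign()]); this internal route scores a
#' supplied pairing.
#'
#' @inheritParams ca_match
#' @param pairing optional precomputed pairing; defaults to
#'   [ca_correspondence()] at the cutoff.
#' @return List with `tm` in [0, 1], `rmsd` over pairs, `n_pairs`,
#'   `d0`, and `undefined` (TRUE when fewer than 3 pairs exist; `tm` is 0).
#' @export
tm_score <- function(model, truth, cutoff = 3.0, pairing = NULL) {
  M <- model_ca_coords(model); TT <- model_ca_coords(truth)
  L_ref <- nrow(TT$xyz)
  if (is.null(pairing)) pairing <- ca_correspondence(model, truth, cutoff)
  if (nrow(pairing) < 3L)
    return(list(tm = 0, rmsd = NA_real_, n_pairs = nrow(pairing),
                d0 = NA_real_, undefined = TRUE))
  A <- M$xyz[pairing$model_idx, , drop = FALSE]
  B <- TT$xyz[pairing$truth_idx, , drop = FALSE]
  fit <- superpose_rmsd(A, B)
  d <- sqrt(rowSums((fit$transformed - B)^2))
  d0 <- max(1.24 * (L_ref - 15)^(1 / 3) - 1.8, 0.5)
  list(tm = sum(1 / (1 + (d / d0)^2)) / L_ref, rmsd = fit$rmsd,
       n_pairs = nrow(pairing), d0 = d0, undefined = FALSE)
}

#' Sequence identity and aligned length over a pairing
#'
#' Internal route of the two alignment-based metrics: the aligned C-alpha
#' length is the number of paired atoms and the sequence identity is the
#' fraction of pairs with identical amino-acid types. When an external
#' structural-alignment result file is available, use [parse_usalign()]
#' instead.
#'
#' @inheritParams ca_match
#' @return List with `sequence_identity` in [0, 1] and `aligned_length`.
#' @export
sequence_identity <- function(model, truth, cutoff = 3.0, pairing = NULL) {
  if (is.null(pairing)) pairing <- ca_correspondence(model, truth, cutoff)
  if (nrow(pairing) == 0L)
    return(list(sequence_identity = 0, aligned_length = 0L))
  M <- model_ca_coords(model); TT <- model_ca_coords(truth)
  list(sequence_identity =
         mean(M$aa[pairing$model_idx] == TT$aa[pairing$truth_idx]),
       aligned_length = nrow(pairing))
}

#' Parse an external US-align result file
#'
#' Extracts the TM-score (normalized by the reference length), aligned
#' length and sequence identity from a US-align standard-output dump.
#'
#' @param path path to a text file containing US-align output.
#' @return List with `tm`, `aligned_length`, `sequence_identity` (NA for
#'   fields not found).
#' @export
parse_usalign <- function(path) {
  txt <- readLines(path, warn = FALSE)
  num <- function(pattern) {
    ln <- grep(pattern, txt, value = TRUE)
    if (length(ln) == 0L) return(NA_real_)
    m <- regmatches(ln[1], regexpr("[0-9]+\\.?[0-9]*", sub(pattern, "", ln[1])))
    if (length(m) == 0L) NA_real_ else as.numeric(m)
  }
  al <- grep("Aligned length", txt, value = TRUE)
  aligned <- if (length(al) > 0L)
    as.numeric(regmatches(al[1], regexpr("[0-9]+", al[1]))) else NA_real_
  seqid <- NA_real_
  if (length(al) > 0L && grepl("Seq_ID", al[1]))
    seqid <- suppressWarnings(
      as.numeric(sub(".*Seq_ID[^0-9]*([0-9.]+).*", "\\1", al[1])))
  tm_lines <- grep("^TM-score=", txt, value = TRUE)
  tm <- NA_real_
  if (length(tm_lines) > 0L) {
    ref_ln <- grep("Structure_2|Chain_2|reference", tm_lines, value = TRUE)
    pick <- if (length(ref_ln) > 0L) ref_ln[1] else tm_lines[1]
    tm <- as.numeric(regmatches(pick, regexpr("0\\.[0-9]+|1\\.0*", pick)))
  }
  list(tm = tm, aligned_length = aligned, sequence_identity = seqid)
}

#' Evaluate a backbone model against a reference structure
#'
#' Computes the six benchmark metrics over the map-frame C-alpha
#' correspondence: TM-score, C-alpha match, C-alpha quality score, aligned
#' C-alpha length, sequence identity and sequence match.
#'
#' @param model a `backbone_model` or [protein_structure].
#' @param truth the reference [protein_structure].
#' @param cutoff pairing cutoff, Angstrom (default 3.0).
#' @return An `eval_report` list with fields `tm_score`, `ca_match`,
#'   `ca_quality_score`, `aligned_ca_length`, `sequence_identity`,
#'   `sequence_match`, `model_length`, `reference_length`, `rmsd_paired`.
#' @export
evaluate_model <- function(model, truth, cutoff = 3.0) {
  M <- model_ca_coords(model); TT <- model_ca_coords(truth)
  pairing <- ca_correspondence(model, truth, cutoff)
  cm <- ca_match(model, truth, cutoff, pairing)
  tm <- tm_score(model, truth, cutoff, pairing)
  si <- sequence_identity(model, truth, cutoff, pairing)
  rep <- list(
    tm_score = tm$tm,
    ca_match = cm,
    ca_quality_score = ca_quality_score(cm, nrow(M$xyz), nrow(TT$xyz)),
    aligned_ca_length = si$aligned_length,
    sequence_identity = si$sequence_identity,
    sequence_match = if (nrow(pairing) > 0L)
      sequence_match(model, truth, cutoff, pairing) else 0,
    model_length = nrow(M$xyz),
    reference_length = nrow(TT$xyz),
    rmsd_paired = tm$rmsd)
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  TM-score:            %.3f\n", x$tm_score))
  cat(sprintf("  Ca match:            %.1f%%\n", x$ca_match))
  cat(sprintf("  Ca quality score:    %.3f\n", x$ca_quality_score))
  cat(sprintf("  aligned Ca length:   %d\n", as.integer(x$aligned_ca_length)))
  cat(sprintf("  sequence identity:   %.3f\n", x$sequence_identity))
  cat(sprintf("  sequence match:      %.1f%%\n", x$sequence_match))
  cat(sprintf("  model/reference:     %d / %d residues\n",
              as.integer(x$model_length), as.integer(x$reference_length)))
  invisible(x)
}
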