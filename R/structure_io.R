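#' Protein structure object
#'
#' A light container for atomic structures: one flat atom table plus chain
#' ordering. Residues within a chain are kept in author order (residue
#' number, then insertion code).
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer),
#'   `ins` (insertion code, "" when absent), `aa` (one-letter code, `X` for
#'   nonstandard), `atom` (atom name, e.g. "CA"), `x`, `y`, `z` (Angstrom).
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(atoms) {
  need <- c("chain", "resno", "ins", "aa", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("protein_structure: atoms must have columns ",
         paste(need, collapse = ", "))
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$ins <- ifelse(is.na(atoms$ins), "", as.character(atoms$ins))
  atoms$aa <- as.character(atoms$aa)
  atoms$atom <- as.character(atoms$atom)
  ord <- order(match(atoms$chain, unique(atoms$chain)),
               atoms$resno, atoms$ins)
  atoms <- atoms[ord, need, drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  a <- x$atoms
  ch <- unique(a$chain)
  nres <- nrow(unique(a[, c("chain", "resno", "ins")]))
  cat(sprintf("<protein_structure> %d chains, %d residues, %d atoms\n",
              length(ch), nres, nrow(a)))
  for (c1 in ch) {
    sub <- a[a$chain == c1, ]
    cat(sprintf("  chain %s: %d residues\n", c1,
                nrow(unique(sub[, c("resno", "ins")]))))
  }
  invisible(x)
}

#' Chain identifiers of a structure, in file order
#' @param s a [protein_structure].
#' @return Character vector of chain ids.
#' @export
structure_chains <- function(s) unique(s$atoms$chain)

#' Per-chain one-letter sequences
#' @param s a [protein_structure].
#' @return Named character vector, one sequence string per chain.
#' @export
structure_sequences <- function(s) {
  vapply(structure_chains(s), function(ch) {
    sub <- s$atoms[s$atoms$chain == ch, ]
    res <- unique(sub[, c("resno", "ins", "aa")])
    paste(res$aa, collapse = "")
  }, character(1))
}

#' C-alpha records of a structure
#' @param s a [protein_structure].
#' @return data.frame with chain, resno, ins, aa, x, y, z (one row per
#'   residue that has a CA atom).
#' @export
ca_table <- function(s) {
  ca <- s$atoms[s$atoms$atom == "CA", ]
  rownames(ca) <- NULL
  ca
}

#' Read a structure from PDB or mmCIF
#'
#' Thin wrapper over bio3d's parsers; keeps protein ATOM records, maps
#' residue names to one-letter codes (nonstandard residues become `X`), and
#' orders residues by author numbering then insertion code.
#'
#' @param path path to a `.pdb` / `.ent` or `.cif` file.
#' @return A [protein_structure].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("read_structure: cannot parse ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("read_structure: no protein ATOM records in ", path)
  aa1 <- suppressWarnings(bio3d::aa321(a$resid))
  aa1[is.na(aa1) | !aa1 %in% aa_alphabet()] <- "X"
  ins <- if ("insert" %in% names(a)) ifelse(is.na(a$insert), "", a$insert) else ""
  protein_structure(data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, ins = ins, aa = aa1, atom = a$elety,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}

#' Write a structure to PDB
#'
#' @param s a [protein_structure].
#' @param path output path (PDB format).
#' @param occupancy optional numeric vector (one per atom) written to the
#'   occupancy column; used downstream to flag gap-filled residues.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, occupancy = NULL) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms
  if (is.null(occupancy)) occupancy <- rep(1, nrow(a))
  resid3 <- bio3d::aa123(ifelse(a$aa %in% aa_alphabet(), a$aa, "G"))
  resid3[a$aa == "X"] <- "UNK"
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = resid3,
                   elety = a$atom, insert = ifelse(a$ins == "", NA, a$ins),
                   o = occupancy, b = rep(0, nrow(a)))
  invisible(path)
}
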