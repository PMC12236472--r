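#' Canonical amino-acid code table
#'
#' Single source of truth for the integer codes used across the voxel
#' encodings, label masks and decoders: the 20 canonical one-letter codes in
#' alphabetical order, coded 1 (A) through 20 (Y). Code 0 means "no amino
#' acid" / unknown.
#'
#' @return Character vector of the 20 one-letter codes, in code order.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Map one-letter amino-acid codes to integer codes 1..20
#'
#' @param aa character vector of one-letter codes.
#' @return Integer codes; `NA_integer_` for letters outside the 20 canonical
#'   types (callers treat these as unknown).
#' @export
aa_code <- function(aa) {
  match(toupper(aa), aa_alphabet())
}

#' Map integer codes 1..20 back to one-letter codes
#'
#' @param code integer vector in 1..20 (0/NA give `NA_character_`).
#' @return Character vector of one-letter codes.
#' @export
aa_letter <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code) & code >= 1 & code <= 20
  out[ok] <- aa_alphabet()[code[ok]]
  out
}
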