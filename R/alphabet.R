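#' Amino-acid alphabet used throughout the package
#'
#' The fixed, ordered 20-letter amino-acid alphabet. All coefficient matrices
#' are indexed by this order; peptide strings are validated against it.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
AA_STRING <- paste(AA_ALPHABET, collapse = "")

# Placeholder residue used for windows that run past a protein terminus;
# scored at the column mean, see ddg().
PAD_CHAR <- "-"
PAD_CODE <- 21L

#' Encode peptides as an integer matrix
#'
#' @param peptides character vector of equal-length peptides.
#' @param allow_pad allow the terminus placeholder `-` (encoded as 21).
#' @return integer matrix, one row per peptide, entries in `1:20` (or 21 for
#'   the placeholder), columns are residue positions.
#' @keywords internal
encode_peptides <- function(peptides, allow_pad = FALSE) {
  if (length(peptides) == 0L) stop("no peptides to encode")
  n <- nchar(peptides)
  if (any(n != n[1L])) stop("peptides must all have the same length")
  chars <- unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE)
  codes <- match(chars, AA_ALPHABET)
  if (allow_pad) codes[chars == PAD_CHAR] <- PAD_CODE
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("peptide contains letters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "))
  }
  matrix(codes, ncol = n[1L], byrow = TRUE)
}

#' @keywords internal
decode_peptides <- function(mat) {
  letters <- c(AA_ALPHABET, PAD_CHAR)
  apply(mat, 1L, function(r) paste(letters[r], collapse = ""))
}

# All 32 NNS codons (any base at positions 1-2, G or C at position 3) with
# their standard-genetic-code translation. TAG (amber) is the single stop.
#' @keywords internal
nns_codons <- function() {
  bases <- c("A", "C", "G", "T")
  cod <- as.vector(outer(outer(bases, bases, paste0), c("G", "C"), paste0))
  aa <- unname(Biostrings::GENETIC_CODE[cod])
  data.frame(codon = cod, aa = aa, stringsAsFactors = FALSE)
}

#' Amino-acid frequencies induced by an NNS-degenerate codon
#'
#' Enumerates the 32 NNS codons, removes the single amber stop (TAG), and
#' returns per-residue probabilities (codon count / 31) in alphabet order.
#' Leucine, arginine and serine each have 3 NNS codons; tryptophan has 1.
#'
#' @return named numeric vector of length 20 summing to 1.
#' @export
nns_aa_frequencies <- function() {
  tab <- nns_codons()
  tab <- tab[tab$aa != "*", ]
  counts <- table(factor(tab$aa, levels = AA_ALPHABET))
  p <- as.numeric(counts) / sum(counts)
  names(p) <- AA_ALPHABET
  p
}

#' @keywords internal
codons_for_aa <- function(aa) {
  tab <- nns_codons()
  tab$codon[tab$aa == aa]
}

#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
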