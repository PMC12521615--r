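#' Declare a displayed-peptide library design
#'
#' A library design records the geometry of the variable region (length `L`
#' residues, encoded by `3L` nucleotides of NNS codons), any fixed residues
#' (e.g. the central tyrosine of an X5YX5 library), the constant DNA anchors
#' used to locate the variable region in a sequencing read, and the constant
#' peptide flanks displayed on either side of the variable region.
#'
#' @param name short design label.
#' @param length variable-region length `L` in residues.
#' @param fixed_positions named list or integer-named character vector mapping
#'   1-based positions to required residues, e.g. `c("6" = "Y")`. May be empty.
#' @param dna_left_anchor,dna_right_anchor constant DNA immediately left/right
#'   of the variable region.
#' @param protein_flank_left,protein_flank_right constant displayed peptide
#'   sequence on either side of the variable region.
#' @param codon_pattern degenerate codon scheme of the variable region; only
#'   `"NNS"` is supported.
#' @return an object of class `library_design`.
#' @examples
#' design_x5yx5()
#' library_design("X3", length = 3)
#' @export
library_design <- function(name,
                           length,
                           fixed_positions = character(),
                           dna_left_anchor = "GTAGCTGGCCAGTCTGGCCAG",
                           dna_right_anchor = "GGAGGGCAGTCTGGGCAGTC",
                           protein_flank_left = "GQSGQ",
                           protein_flank_right = "GGQSG",
                           codon_pattern = "NNS") {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  if (codon_pattern != "NNS") stop("only the NNS codon pattern is supported")
  fp <- unlist(fixed_positions)
  if (length(fp)) {
    pos <- as.integer(names(fp))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length))
      stop("fixed_positions must map positions in 1..L to residues")
    if (!all(fp %in% AA_ALPHABET))
      stop("fixed residues must be amino-acid letters")
    fixed <- structure(as.character(fp), names = as.character(pos))
  } else {
    fixed <- structure(character(), names = character())
  }
  for (fl in c(protein_flank_left, protein_flank_right)) {
    if (nchar(fl) && !all(strsplit(fl, "")[[1]] %in% AA_ALPHABET))
      stop("protein flanks must be drawn from the amino-acid alphabet")
  }
  for (an in c(dna_left_anchor, dna_right_anchor)) {
    if (!grepl("^[ACGT]+$", an)) stop("DNA anchors must be ACGT strings")
  }
  structure(
    list(name = name,
         alphabet = AA_ALPHABET,
         length = length,
         fixed_positions = fixed,
         dna_left_anchor = dna_left_anchor,
         dna_right_anchor = dna_right_anchor,
         protein_flank_left = protein_flank_left,
         protein_flank_right = protein_flank_right,
         codon_pattern = codon_pattern),
    class = "library_design")
}

#' Built-in library designs
#'
#' `design_x5yx5()` is the 11-mer design with a fixed central tyrosine between
#' two fully degenerate 5-residue flanks; `design_x11()` is the fully random
#' 11-mer design.
#'
#' @return a [library_design()] object.
#' @rdname builtin_designs
#' @export
design_x5yx5 <- function() {
  library_design("X5YX5", length = 11L, fixed_positions = c("6" = "Y"))
}

#' @rdname builtin_designs
#' @export
design_x11 <- function() {
  library_design("X11", length = 11L)
}

#' @export
print.library_design <- function(x, ...) {
  fp <- if (length(x$fixed_positions)) {
    paste(sprintf("%s=%s", names(x$fixed_positions), x$fixed_positions),
          collapse = ", ")
  } else "none"
  cat(sprintf("library_design '%s': L=%d, fixed: %s\n", x$name, x$length, fp))
  cat(sprintf("  DNA anchors: %s ... %s\n", x$dna_left_anchor, x$dna_right_anchor))
  cat(sprintf("  peptide flanks: %s-[%d]-%s, codons %s\n",
              x$protein_flank_left, x$length, x$protein_flank_right,
              x$codon_pattern))
  invisible(x)
}

#' @keywords internal
validate_peptides_for_design <- function(peptides, design) {
  if (any(nchar(peptides) != design$length))
    stop("peptides must have the design length L = ", design$length)
  for (p in names(design$fixed_positions)) {
    res <- design$fixed_positions[[p]]
    got <- substr(peptides, as.integer(p), as.integer(p))
    if (any(got != res))
      stop("peptide violates fixed position ", p, " (expected ", res, ")")
  }
  invisible(TRUE)
}
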