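#' A sequencing read with per-base qualities
#'
#' @param sequence DNA string (ACGTN).
#' @param quality integer PHRED scores, one per base.
#' @return object of class `read_record`.
#' @export
read_record <- function(sequence, quality) {
  if (nchar(sequence) != length(quality))
    stop("sequence and quality must have equal lengths")
  structure(list(sequence = sequence, quality = as.integer(quality)),
            class = "read_record")
}

#' Read a FASTQ file (Sanger PHRED+33, gzip transparent)
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return list with `sequences` (character) and `qualities` (list of
#'   integer vectors).
#' @export
read_fastq <- function(path) {
  # the FASTQ ids are not needed; Biostrings warns when dropping them
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- as(Biostrings::quality(x), "IntegerList")
  list(sequences = as.character(x), qualities = as.list(quals))
}

#' @keywords internal
write_fastq <- function(path, ids, sequences, qualities) {
  qchar <- vapply(qualities,
                  function(q) rawToChar(as.raw(q + 33L)), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", sequences, "\n+\n", qchar), con)
  invisible(path)
}

#' Merge a read pair by its best ungapped overlap
#'
#' A convenience merger for paired amplicon reads: the reverse complement of
#' `r2` is aligned to `r1` at every ungapped offset; the best-matching overlap
#' of at least `min_overlap` bases and at least 90% identity wins, with the
#' higher-quality base taken at disagreements.
#'
#' @param r1,r2 [read_record()] objects (r2 as sequenced, i.e. reverse strand).
#' @param min_overlap minimum acceptable overlap length (default 10).
#' @return merged [read_record()], or `NULL` if no acceptable overlap exists.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L) {
  stopifnot(inherits(r1, "read_record"), inherits(r2, "read_record"))
  if (!nchar(r1$sequence) || !nchar(r2$sequence)) stop("empty read")
  s2 <- revcomp(r2$sequence)
  q2 <- rev(r2$quality)
  c1 <- strsplit(r1$sequence, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  n1 <- length(c1); n2 <- length(c2)
  best <- NULL
  for (s in seq_len(n1)) {              # s = start of r2rc within r1
    ov <- min(n1 - s + 1L, n2)
    if (ov < min_overlap) next
    i1 <- s:(s + ov - 1L)
    m <- sum(c1[i1] == c2[seq_len(ov)])
    if (m / ov < 0.9) next
    score <- 2L * m - ov                # matches minus mismatches
    if (is.null(best) || score > best$score) best <- list(s = s, ov = ov,
                                                          score = score)
  }
  if (is.null(best)) return(NULL)
  s <- best$s; ov <- best$ov
  head_seq <- c1[seq_len(s - 1L)]
  head_q <- r1$quality[seq_len(s - 1L)]
  o1 <- s:(s + ov - 1L)
  o2 <- seq_len(ov)
  take2 <- c1[o1] != c2[o2] & q2[o2] > r1$quality[o1]
  mid_seq <- ifelse(take2, c2[o2], c1[o1])
  mid_q <- pmax(r1$quality[o1], q2[o2])
  tail_seq <- if (ov < n2) c2[(ov + 1L):n2] else character()
  tail_q <- if (ov < n2) q2[(ov + 1L):n2] else integer()
  read_record(paste(c(head_seq, mid_seq, tail_seq), collapse = ""),
              c(head_q, mid_q, tail_q))
}

#' Locate the variable region of a read between its constant DNA anchors
#'
#' Scans all ungapped placements of `left anchor + 3L nt + right anchor` and
#' returns the variable region whose two anchors each match with Hamming
#' distance at most `max_mismatches`. Among qualifying placements the one
#' with fewest total anchor mismatches wins, ties broken leftmost.
#'
#' @param read DNA string.
#' @param design a [library_design()].
#' @param max_mismatches per-anchor mismatch allowance (default 5).
#' @return list with `region` (3L-nt string) and `start` (1-based offset of
#'   the region), or `NULL` if no placement qualifies.
#' @export
locate_variable_region <- function(read, design, max_mismatches = 5L) {
  la <- strsplit(design$dna_left_anchor, "")[[1]]
  ra <- strsplit(design$dna_right_anchor, "")[[1]]
  reg_len <- 3L * design$length
  chars <- strsplit(read, "")[[1]]
  n <- length(chars)
  span <- length(la) + reg_len + length(ra)
  if (n < span) return(NULL)
  starts <- seq_len(n - span + 1L)      # placement = start of left anchor
  mm <- integer(length(starts))
  for (i in seq_along(la)) mm <- mm + (chars[starts + i - 1L] != la[i])
  roff <- length(la) + reg_len          # right anchor offset within placement
  for (i in seq_along(ra)) mm <- mm + (chars[starts + roff + i - 1L] != ra[i])
  mml <- integer(length(starts))
  for (i in seq_along(la)) mml <- mml + (chars[starts + i - 1L] != la[i])
  ok <- mml <= max_mismatches & (mm - mml) <= max_mismatches
  if (!any(ok)) return(NULL)
  best <- starts[ok][which.min(mm[ok])] # which.min takes the first = leftmost
  reg_start <- best + length(la)
  list(region = substr(read, reg_start, reg_start + reg_len - 1L),
       start = reg_start)
}

#' PHRED quality filter for a cropped variable region
#'
#' @param region_quality integer PHRED scores of the variable region.
#' @param min_phred minimum acceptable score (default 20); a read passes iff
#'   every position is at least `min_phred`.
#' @return logical scalar.
#' @export
quality_pass <- function(region_quality, min_phred = 20L) {
  if (!length(region_quality)) stop("empty quality region")
  all(region_quality >= min_phred)
}

#' Check a variable region against the library design and translate it
#'
#' Returns `NULL` when any codon violates the NNS pattern (third base must be
#' G or C), encodes a stop, or a fixed design position translates to the
#' wrong residue; otherwise the L-residue peptide under the standard genetic
#' code.
#'
#' @param region DNA string of length `3L`.
#' @param design a [library_design()].
#' @return peptide string or `NULL`.
#' @export
match_and_translate <- function(region, design) {
  if (nchar(region) %% 3L != 0L)
    stop("region length must be a multiple of 3")
  if (nchar(region) != 3L * design$length)
    stop("region length does not match the design")
  starts <- seq(1L, nchar(region), by = 3L)
  codons <- substring(region, starts, starts + 2L)
  if (!all(grepl("^[ACGT]{3}$", codons))) return(NULL)
  third <- substr(codons, 3L, 3L)
  if (any(!third %in% c("G", "C"))) return(NULL)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (any(aa == "*")) return(NULL)
  for (p in names(design$fixed_positions)) {
    if (aa[as.integer(p)] != design$fixed_positions[[p]]) return(NULL)
  }
  paste(aa, collapse = "")
}

# Run the full locate -> quality -> match/translate pipeline over one
# library. Returns surviving peptides plus per-stage discard counts.
#' @keywords internal
process_reads <- function(sequences, qualities, design,
                          max_mismatches = 5L, min_phred = 20L) {
  n <- length(sequences)
  peptides <- character(n)
  n_unlocated <- 0L; n_quality <- 0L; n_mismatch <- 0L
  for (i in seq_len(n)) {
    loc <- locate_variable_region(sequences[i], design, max_mismatches)
    if (is.null(loc)) { n_unlocated <- n_unlocated + 1L; next }
    q <- qualities[[i]][loc$start:(loc$start + 3L * design$length - 1L)]
    if (!quality_pass(q, min_phred)) { n_quality <- n_quality + 1L; next }
    pep <- match_and_translate(loc$region, design)
    if (is.null(pep)) { n_mismatch <- n_mismatch + 1L; next }
    peptides[i] <- pep
  }
  keep <- nzchar(peptides)
  list(peptides = peptides[keep],
       report = c(total = n,
                  unlocated = n_unlocated,
                  low_quality = n_quality,
                  design_mismatch = n_mismatch,
                  kept = sum(keep)))
}

#' Build a count table from raw input and bound reads
#'
#' Applies, per read, the fixed pipeline locate -> PHRED filter on the cropped
#' region -> design match and translation, then tallies surviving peptides in
#' the input and bound columns. Reads may be given as FASTQ paths or as the
#' structure returned by [read_fastq()].
#'
#' @param input_reads,bound_reads FASTQ path or `read_fastq()` result.
#' @param design a [library_design()].
#' @param round_id selection round index.
#' @param max_mismatches per-anchor mismatch allowance (default 5).
#' @param min_phred PHRED threshold on the cropped region (default 20).
#' @return list with `table` (a [count_table()]) and `report`, a two-row
#'   matrix of per-stage read counts (input and bound). The per-stage counts
#'   sum to the total, so no read is lost or double-counted.
#' @export
build_count_table <- function(input_reads, bound_reads, design,
                              round_id = 1L, max_mismatches = 5L,
                              min_phred = 20L) {
  as_reads <- function(x) if (is.character(x)) read_fastq(x) else x
  inp <- as_reads(input_reads); bnd <- as_reads(bound_reads)
  if (!length(inp$sequences) || !length(bnd$sequences))
    stop("empty read stream")
  pi <- process_reads(inp$sequences, inp$qualities, design,
                      max_mismatches, min_phred)
  pb <- process_reads(bnd$sequences, bnd$qualities, design,
                      max_mismatches, min_phred)
  if (pi$report[["kept"]] == 0L || pb$report[["kept"]] == 0L)
    stop("no reads survived processing in the ",
         if (pi$report[["kept"]] == 0L) "input" else "bound", " column")
  seqs <- sort(unique(c(pi$peptides, pb$peptides)))
  ci <- table(factor(pi$peptides, levels = seqs))
  cb <- table(factor(pb$peptides, levels = seqs))
  tab <- count_table(seqs, as.integer(ci), as.integer(cb), design, round_id)
  list(table = tab, report = rbind(input = pi$report, bound = pb$report))
}
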