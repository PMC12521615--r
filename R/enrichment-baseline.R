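#' Position-wise amino-acid log-enrichment matrix
#'
#' The simple baseline analysis: read-weighted positional residue frequencies
#' are computed before (input) and after (bound) selection and compared as
#' `ln((f_bound + e_B) / (f_input + e_I))`, where `e = pseudocount / column
#' read total` is a frequency floor guarding against zero counts. Fixed
#' design positions are masked (reported as 0 with a logical `mask`
#' attribute) rather than dropped, so matrices from different designs stay
#' comparable cell-wise.
#'
#' @param table a [count_table()].
#' @param pseudocount frequency-floor pseudocount (default 0.5).
#' @return `L x 20` matrix of class `enrichment_matrix` with attributes
#'   `mask` (logical `L x 20`, TRUE at fixed positions) and `pseudocount`.
#' @export
aa_log_enrichment <- function(table, pseudocount = 0.5) {
  stopifnot(inherits(table, "count_table"), pseudocount > 0)
  design <- attr(table, "design")
  L <- design$length
  m <- encode_peptides(table$sequence)
  pos_freq <- function(counts) {
    tot <- sum(counts)
    f <- matrix(0, L, 20L)
    for (p in seq_len(L)) {
      f[p, ] <- vapply(seq_len(20L),
                       function(a) sum(counts[m[, p] == a]), numeric(1))
    }
    f / tot
  }
  fI <- pos_freq(table$count_input)
  fB <- pos_freq(table$count_bound)
  eI <- pseudocount / sum(table$count_input)
  eB <- pseudocount / sum(table$count_bound)
  em <- log((fB + eB) / (fI + eI))
  mask <- matrix(FALSE, L, 20L)
  for (p in names(design$fixed_positions)) mask[as.integer(p), ] <- TRUE
  em[mask] <- 0
  dimnames(em) <- list(seq_len(L), AA_ALPHABET)
  structure(em, mask = mask, pseudocount = pseudocount,
            source_round = attr(table, "round_id"),
            class = c("enrichment_matrix", "matrix", "array"))
}

#' Down-sample a count table column-wise without replacement
#'
#' Each column is subsampled hypergeometrically (as if drawing `n_reads`
#' physical reads without replacement), so column totals equal `n_reads`
#' exactly. Deterministic given `seed`.
#'
#' @param table a [count_table()].
#' @param n_reads target reads per column.
#' @param seed RNG seed.
#' @return a [count_table()] (rows whose counts both reach zero are dropped).
#' @export
downsample <- function(table, n_reads, seed) {
  stopifnot(inherits(table, "count_table"))
  sample_col <- function(counts) {
    tot <- sum(counts)
    if (n_reads > tot) stop("n_reads exceeds the column total (", tot, ")")
    if (n_reads == tot) return(counts)
    reads <- rep.int(seq_along(counts), counts)
    keep <- sample(reads, n_reads, replace = FALSE)
    tabulate(keep, nbins = length(counts))
  }
  with_seed(seed, {
    ci <- sample_col(table$count_input)
    cb <- sample_col(table$count_bound)
    count_table(table$sequence, ci, cb, attr(table, "design"),
                attr(table, "round_id"))
  })
}

#' Reads-per-unique-sequence histogram of one column
#'
#' @param table a [count_table()].
#' @param column `"input"` or `"bound"`.
#' @return data.frame with `reads_per_sequence` and `n_sequences`; the total
#'   mass `sum(reads_per_sequence * n_sequences)` equals the column read
#'   total. Sequences absent from the column (count 0) are excluded.
#' @export
count_distribution <- function(table, column = c("input", "bound")) {
  column <- match.arg(column)
  counts <- if (column == "input") table$count_input else table$count_bound
  counts <- counts[counts > 0]
  h <- table(counts)
  data.frame(reads_per_sequence = as.numeric(names(h)),
             n_sequences = as.integer(h))
}

#' Cell-wise comparison of two matrices
#'
#' Squared Pearson correlation over unmasked cells of two equally shaped
#' matrices (log-enrichment matrices or specific-mode coefficient tables),
#' with the paired scatter data labelled by position and residue so that
#' individual residues (e.g. tyrosine) can be highlighted.
#'
#' @param m1,m2 `L x 20` matrices, [aa_log_enrichment()] results, or
#'   [energy_model()] objects (the specific coefficients are compared and
#'   frozen cells masked).
#' @return list with `r_squared`, `slope` (of m2 on m1), and `scatter`
#'   (data.frame: position, residue, x, y).
#' @export
compare_matrices <- function(m1, m2) {
  as_mat <- function(x) {
    if (inherits(x, "energy_model"))
      return(list(m = x$specific$coeffs, mask = x$specific$frozen))
    mask <- attr(x, "mask")
    if (is.null(mask)) mask <- matrix(FALSE, nrow(x), ncol(x))
    list(m = unclass(x), mask = mask)
  }
  a <- as_mat(m1); b <- as_mat(m2)
  if (!all(dim(a$m) == dim(b$m))) stop("matrices have different shapes")
  keep <- !(a$mask | b$mask)
  idx <- which(keep, arr.ind = TRUE)
  x <- a$m[keep]; y <- b$m[keep]
  fitl <- stats::lm.fit(cbind(1, x), y)
  list(r_squared = stats::cor(x, y)^2,
       slope = unname(fitl$coefficients[2L]),
       scatter = data.frame(position = idx[, 1L],
                            residue = AA_ALPHABET[idx[, 2L]],
                            x = x, y = y))
}
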