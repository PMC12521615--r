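#' Build a per-round selection count table
#'
#' A count table holds, for one selection round, the number of sequencing
#' reads observed for each unique peptide in the input (pre-selection) and
#' bound (post-selection) libraries.
#'
#' @param sequences character vector of unique peptides of the design length.
#' @param count_input,count_bound non-negative integer read counts.
#' @param design the [library_design()] the peptides belong to.
#' @param round_id 1-based selection round index.
#' @return object of class `count_table`: a data.frame with columns
#'   `sequence`, `count_input`, `count_bound` and attributes `design`,
#'   `round_id`, `k_total` (total reads over both columns) and `n_unique`.
#' @export
count_table <- function(sequences, count_input, count_bound, design,
                        round_id = 1L) {
  stopifnot(inherits(design, "library_design"))
  n <- length(sequences)
  if (length(count_input) != n || length(count_bound) != n)
    stop("sequence and count columns must have equal length")
  if (anyDuplicated(sequences)) stop("duplicate sequences in count table")
  count_input <- as.numeric(count_input)
  count_bound <- as.numeric(count_bound)
  if (any(count_input < 0) || any(count_bound < 0))
    stop("counts must be non-negative")
  keep <- count_input + count_bound > 0
  if (!any(keep)) stop("count table has no reads")
  sequences <- sequences[keep]
  count_input <- count_input[keep]
  count_bound <- count_bound[keep]
  validate_peptides_for_design(sequences, design)
  df <- data.frame(sequence = sequences,
                   count_input = count_input,
                   count_bound = count_bound,
                   stringsAsFactors = FALSE)
  structure(df,
            design = design,
            round_id = as.integer(round_id),
            k_total = sum(count_input) + sum(count_bound),
            n_unique = nrow(df),
            class = c("count_table", "data.frame"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "count_table: round %d, %d unique peptides, %s input + %s bound reads\n",
    attr(x, "round_id"), attr(x, "n_unique"),
    format(sum(x$count_input), big.mark = ","),
    format(sum(x$count_bound), big.mark = ",")))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Read / write count tables as TSV
#'
#' The on-disk format is a UTF-8 TSV with header
#' `sequence  count_input  count_bound`, one row per unique peptide.
#' A write followed by a read is the identity.
#'
#' @param path file path.
#' @param design the [library_design()] the peptides must satisfy.
#' @param round_id selection round recorded on the returned table.
#' @return `read_count_table` returns a [count_table()];
#'   `write_count_table` returns `path` invisibly.
#' @rdname count_table_io
#' @export
read_count_table <- function(path, design, round_id = 1L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  required <- c("sequence", "count_input", "count_bound")
  if (!identical(names(df)[1:3], required))
    stop("count table ", path, " must have header: ",
         paste(required, collapse = "  "))
  dup <- which(duplicated(df$sequence))
  if (length(dup))
    stop("duplicate sequence at line ", dup[1L] + 1L, " of ", path)
  bad <- which(df$count_input < 0 | df$count_bound < 0)
  if (length(bad))
    stop("negative count at line ", bad[1L] + 1L, " of ", path)
  badlen <- which(nchar(df$sequence) != design$length)
  if (length(badlen))
    stop("wrong-length peptide at line ", badlen[1L] + 1L, " of ", path)
  count_table(df$sequence, df$count_input, df$count_bound, design, round_id)
}

#' @param table a [count_table()].
#' @rdname count_table_io
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  utils::write.table(as.data.frame(table)[c("sequence", "count_input",
                                            "count_bound")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
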