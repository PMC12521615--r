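test_that("library designs validate their geometry", {
  d <- design_x5yx5()
  expect_equal(d$length, 11L)
  expect_equal(unname(d$fixed_positions["6"]), "Y")
  expect_equal(3L * d$length, 33L)
  expect_error(library_design("bad", 5, fixed_positions = c("9" = "Y")),
               "fixed_positions")
  expect_error(library_design("bad", 5, protein_flank_left = "GXZ"),
               "alphabet")
})

test_that("merge_pairs reconstructs a template from overlapping reads", {
  withr::with_seed(7, {
    template <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  })
  r1 <- read_record(substr(template, 1, 30), rep(35L, 30))
  # r2 is the reverse-strand read of the last 30 nt
  r2_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(template, 11, 40))))
  r2 <- read_record(r2_seq, rep(38L, 30))
  merged <- merge_pairs(r1, r2, min_overlap = 10)
  expect_equal(merged$sequence, template)
  expect_length(merged$quality, 40)

  # full self-overlap returns the read itself
  self_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r1$sequence)))
  m2 <- merge_pairs(r1, read_record(self_rc, rep(30L, 30)), min_overlap = 10)
  expect_equal(m2$sequence, r1$sequence)

  # disjoint sequences do not merge
  r3 <- read_record(strrep("A", 20), rep(30L, 20))
  r4 <- read_record(strrep("C", 20), rep(30L, 20))
  expect_null(merge_pairs(r3, r4, min_overlap = 10))

  # disagreements resolved toward the higher-quality base
  a <- read_record("ACGTACGTACGT", rep(10L, 12))
  b_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ACGTACGTACGA")))   # differs at last base
  b <- read_record(b_seq, rep(40L, 12))
  m3 <- merge_pairs(a, b, min_overlap = 10)
  expect_equal(substr(m3$sequence, 12, 12), "A")

  expect_error(read_record("ACGT", c(30L, 30L)), "equal length")
})

test_that("locate_variable_region honours the mismatch budget", {
  d <- design_x5yx5()
  withr::with_seed(11, {
    region <- paste(sample(c("A", "C", "G", "T"), 33, TRUE), collapse = "")
  })
  read <- paste0("AT", d$dna_left_anchor, region, d$dna_right_anchor, "GG")
  loc <- locate_variable_region(read, d, max_mismatches = 5)
  expect_equal(loc$region, region)

  mutate_at <- function(s, pos) {
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  la5 <- mutate_at(d$dna_left_anchor, c(1, 5, 9, 13, 17))
  la6 <- mutate_at(d$dna_left_anchor, c(1, 5, 9, 13, 17, 21))
  read5 <- paste0(la5, region, d$dna_right_anchor)
  read6 <- paste0(la6, region, d$dna_right_anchor)
  expect_equal(locate_variable_region(read5, d, 5)$region, region)
  expect_null(locate_variable_region(read6, d, 5))

  expect_null(locate_variable_region("ACGT", d, 5))
})

test_that("locate_variable_region agrees with the exhaustive oracle", {
  d <- design_x5yx5()
  bases <- c("A", "C", "G", "T")
  withr::with_seed(23, {
    for (i in 1:300) {
      # random read, sometimes with a planted noisy cassette
      if (i %% 2 == 0) {
        pad1 <- paste(sample(bases, sample(0:8, 1), TRUE), collapse = "")
        pad2 <- paste(sample(bases, sample(0:8, 1), TRUE), collapse = "")
        region <- paste(sample(bases, 33, TRUE), collapse = "")
        la <- strsplit(d$dna_left_anchor, "")[[1]]
        nmm <- sample(0:7, 1)
        pos <- sample(seq_along(la), nmm)
        for (p in pos) la[p] <- sample(setdiff(bases, la[p]), 1)
        read <- paste0(pad1, paste(la, collapse = ""), region,
                       d$dna_right_anchor, pad2)
      } else {
        read <- paste(sample(bases, sample(70:90, 1), TRUE), collapse = "")
      }
      got <- locate_variable_region(read, d, 5)
      want <- oracle_locate(read, d, 5)
      expect_equal(if (is.null(got)) NULL else got$region, want)
    }
  })
})

test_that("quality_pass implements the at-every-position threshold", {
  expect_true(quality_pass(rep(40L, 33)))
  q <- rep(40L, 33); q[17] <- 19L
  expect_false(quality_pass(q))
  expect_true(quality_pass(rep(20L, 33)))
  expect_error(quality_pass(integer()), "empty")
})

test_that("match_and_translate enforces NNS, stops, and fixed residues", {
  d <- design_x5yx5()
  # NNS codons for an X5YX5 11-mer with central TAC (Tyr)
  pep <- "ACDEFYIKLMN"
  codons <- c("GCC", "TGC", "GAC", "GAG", "TTC", "TAC", "ATC", "AAG",
              "CTG", "ATG", "AAC")
  region <- paste(codons, collapse = "")
  expect_equal(match_and_translate(region, d), pep)

  # amber stop TAG satisfies NNS but cannot be displayed
  stopped <- region
  substr(stopped, 1, 3) <- "TAG"
  expect_null(match_and_translate(stopped, d))

  # third base A or T violates NNS
  nns_bad <- region
  substr(nns_bad, 3, 3) <- "A"
  expect_null(match_and_translate(nns_bad, d))

  # fixed central position must translate to Y
  wrong_fix <- region
  substr(wrong_fix, 16, 18) <- "GCC"    # codon 6 -> Ala
  expect_null(match_and_translate(wrong_fix, d))

  expect_error(match_and_translate("ACGT", d), "multiple of 3")
})

test_that("build_count_table tallies reads and conserves totals", {
  d <- design_x5yx5()
  tab <- count_table(c("ACDEFYIKLMN", "WWWWWYWWWWW"), c(3, 2), c(2, 5), d)
  gr <- gen_reads(tab, d, out_dir = file.path(tempdir(), "bct"),
                  error_rate = 0, corrupt_fraction = 0, seed = 5)
  res <- build_count_table(gr$input, gr$bound, d)
  got <- as.data.frame(res$table)
  got <- got[order(got$sequence), ]
  want <- as.data.frame(tab)[order(tab$sequence), ]
  expect_equal(got$sequence, want$sequence)
  expect_equal(got$count_input, want$count_input)
  expect_equal(got$count_bound, want$count_bound)
  # conservation: per-stage discards plus kept equals total
  rep <- res$report
  for (col in c("input", "bound")) {
    expect_equal(sum(rep[col, c("unlocated", "low_quality",
                                "design_mismatch", "kept")]),
                 rep[col, "total"])
  }
})

test_that("count table TSV round-trips and rejects malformed files", {
  d <- design_x5yx5()
  tab <- random_table(d, seed = 3, n = 10)
  path <- tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read_count_table(path, d, round_id = attr(tab, "round_id"))
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "k_total"), attr(tab, "k_total"))

  lines <- readLines(path)
  dup <- c(lines, lines[2])
  f1 <- tempfile(); writeLines(dup, f1)
  expect_error(read_count_table(f1, d), "duplicate")

  neg <- lines
  neg[2] <- sub("\t\\d+$", "\t-1", neg[2])
  f2 <- tempfile(); writeLines(neg, f2)
  expect_error(read_count_table(f2, d), "negative")

  short <- lines
  short[2] <- sub("^\\w{11}", "AAA", short[2])
  f3 <- tempfile(); writeLines(short, f3)
  expect_error(read_count_table(f3, d), "wrong-length")
})

test_that("count_table enforces its invariants", {
  d <- design_x5yx5()
  expect_error(count_table("ACDEFYIKLMN", -1, 2, d), "non-negative")
  expect_error(count_table(rep("ACDEFYIKLMN", 2), c(1, 1), c(1, 1), d),
               "duplicate")
  expect_error(count_table("ACDEFGIKLMN", 1, 1, d), "fixed position")
  expect_error(count_table("ACDEFYIKLMN", 0, 0, d), "no reads")
})
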