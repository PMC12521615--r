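#' Simulation settings for synthetic selection experiments
#'
#' The defaults state the standard parameter-recovery scenario: 1e5 unique
#' NNS-sampled peptides with log-normally skewed abundances, three selection
#' rounds, 5e5 input and bound reads per round, and a random ground-truth
#' energy matrix with coefficient scale 1. Selection is
#' enrichment-proportional with a non-specific carry-over floor.
#'
#' @param design a [library_design()].
#' @param truth optional ground-truth [energy_model()]; if `NULL` one is
#'   drawn with [random_truth_model()] using `truth_sigma` and `seed`.
#' @param truth_sigma coefficient scale of a random truth matrix.
#' @param n_unique unique peptides in the initial library.
#' @param abundance_lognormal_sigma log-normal sd of initial abundances
#'   (0 = uniform; default 1.5, a visibly skewed display library).
#' @param rounds number of selection rounds.
#' @param reads_per_round_input,reads_per_round_bound sequencing depths.
#' @param capture_fraction probability scale mapping enrichment to capture.
#'   Selection is strictly enrichment-proportional (bound law proportional to
#'   `composition * kappa`), so this scale cancels in the sampling law; it is
#'   kept as an explicit scenario knob because per-round capture
#'   efficiencies are not an observable of the count data.
#' @param phospho_efficiency probability scale applied to tyrosine-containing
#'   specific-mode windows (default 1).
#' @param resample if TRUE the next round's composition is resampled from the
#'   finite bound reads instead of the expected bound law.
#' @param seed mandatory RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(design = design_x11(),
                       truth = NULL,
                       truth_sigma = 1,
                       n_unique = 1e5,
                       abundance_lognormal_sigma = 1.5,
                       rounds = 3L,
                       reads_per_round_input = 5e5,
                       reads_per_round_bound = 5e5,
                       capture_fraction = 0.01,
                       phospho_efficiency = 1,
                       resample = FALSE,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  stopifnot(n_unique >= 1, rounds >= 1L,
            reads_per_round_input >= 1, reads_per_round_bound >= 1,
            phospho_efficiency >= 0, phospho_efficiency <= 1,
            abundance_lognormal_sigma >= 0)
  structure(list(design = design, truth = truth, truth_sigma = truth_sigma,
                 n_unique = as.integer(n_unique),
                 abundance_lognormal_sigma = abundance_lognormal_sigma,
                 rounds = as.integer(rounds),
                 reads_per_round_input = reads_per_round_input,
                 reads_per_round_bound = reads_per_round_bound,
                 capture_fraction = capture_fraction,
                 phospho_efficiency = phospho_efficiency,
                 resample = resample,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw a random ground-truth energy model
#'
#' Specific coefficients are N(0, sigma^2); when `constrained` the central
#' column is frozen to the tyrosine constraint (0 for Y, -10 otherwise), the
#' situation of a phosphotyrosine-dependent domain. The non-specific mode is
#' flat, so `alpha_ns` sets a uniform carry-over floor; the default floor
#' (alpha_ns times the number of non-specific offsets, about 0.9) is
#' comparable to the median specific signal so both modes shape the data.
#'
#' @param design a [library_design()].
#' @param sigma coefficient scale.
#' @param seed RNG seed.
#' @param rounds number of per-round parameter sets to carry.
#' @param constrained apply the central-tyrosine constraint.
#' @param w_ns non-specific width.
#' @param alpha_ns,alpha_s linear activity weights shared by every round.
#' @return an [energy_model()].
#' @export
random_truth_model <- function(design, sigma = 1, seed = 1L, rounds = 1L,
                               constrained = TRUE, w_ns = 3L,
                               alpha_ns = 0.1, alpha_s = 1) {
  L <- design$length
  coeffs <- with_seed(seed, matrix(stats::rnorm(L * 20L, 0, sigma), L, 20L))
  f <- min(5L, nchar(design$protein_flank_left),
           nchar(design$protein_flank_right))
  spec <- binding_mode(L, coeffs, flank_depth = f)
  if (constrained) spec <- constrain_central(spec)
  nonspec <- binding_mode(w_ns)
  per_round <- replicate(rounds,
                         round_params(log(alpha_ns), log(alpha_s), 0),
                         simplify = FALSE)
  energy_model(spec, nonspec, per_round, design,
               metadata = list(truth_seed = seed, sigma = sigma))
}

#' Generate a synthetic peptide library
#'
#' Samples `n_unique` distinct peptides residue-wise from the NNS-induced
#' amino-acid distribution (stops excluded, fixed design positions honoured)
#' and attaches log-normal abundances. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `peptides` (character) and `abundance` (normalized).
#' @export
gen_library <- function(config) {
  design <- config$design
  with_seed(config$seed, {
    p <- nns_aa_frequencies()
    L <- design$length
    n <- config$n_unique
    draw <- function(n) {
      m <- matrix(sample.int(20L, n * L, replace = TRUE, prob = p), n, L)
      for (ps in names(design$fixed_positions))
        m[, as.integer(ps)] <- match(design$fixed_positions[[ps]],
                                     AA_ALPHABET)
      unique(decode_peptides(m))
    }
    peptides <- draw(n)
    while (length(peptides) < n)
      peptides <- unique(c(peptides, draw(n - length(peptides) + 100L)))
    peptides <- peptides[seq_len(n)]
    ab <- if (config$abundance_lognormal_sigma == 0) rep(1, n)
          else stats::rlnorm(n, 0, config$abundance_lognormal_sigma)
    list(peptides = peptides, abundance = ab / sum(ab))
  })
}

# Enrichment kappa of the truth model for a peptide set, via the C++ kernel;
# applies the phospho-efficiency multiplier to tyrosine-containing specific
# windows when it is below 1.
#' @keywords internal
kappa_truth <- function(peptides, truth, config = NULL, round_index = 1L) {
  pe <- if (is.null(config)) 1 else config$phospho_efficiency
  pep <- encode_peptides(peptides)
  ext <- extend_with_flanks(pep, truth$design, truth$specific$flank_depth)
  rp <- truth$per_round[[round_index]]
  if (pe >= 1) {
    parts <- kappa_parts_cpp(ext, pep, truth$specific$coeffs,
                             truth$nonspecific$coeffs,
                             truth$nonspecific$position_bias)
    spec <- parts$specific
  } else {
    E <- window_exp(ext, truth$specific$coeffs)
    w <- truth$specific$width
    ycode <- match("Y", AA_ALPHABET)
    for (x in seq_len(ncol(E))) {
      hasY <- rowSums(ext[, x:(x + w - 1L), drop = FALSE] == ycode) > 0L
      E[hasY, x] <- E[hasY, x] * pe
    }
    spec <- rowSums(E)
    parts <- list(nonspecific = nonspecific_sum(peptides,
                                                truth$nonspecific))
  }
  exp(rp$log_alpha_ns) * parts$nonspecific + exp(rp$log_alpha_s) * spec
}

#' Simulate one selection round
#'
#' The input column is a multinomial draw from the current composition; each
#' displayed molecule is captured with probability
#' `min(1, capture_fraction * kappa)`, so the bound column is a multinomial
#' draw from the law proportional to `composition * capture`; the next
#' round's composition is that law itself (expected re-amplification of the
#' bound fraction) or, with `resample`, the normalized bound counts.
#'
#' @param peptides library peptides.
#' @param composition current normalized composition.
#' @param kappa per-peptide truth enrichment (see [random_truth_model()]).
#' @param config a [sim_config()].
#' @param round_id selection round index.
#' @return list with `table` (a [count_table()]) and `composition` (next
#'   round). Uses the current RNG stream; seed management is done by
#'   [simulate_experiment()].
#' @export
simulate_round <- function(peptides, composition, kappa, config, round_id) {
  if (any(composition < 0) || sum(composition) <= 0)
    stop("degenerate composition")
  composition <- composition / sum(composition)
  bound_law <- composition * config$capture_fraction * kappa
  if (sum(bound_law) <= 0) stop("degenerate bound law")
  bound_law <- bound_law / sum(bound_law)
  ci <- as.vector(stats::rmultinom(1L, config$reads_per_round_input,
                                   composition))
  cb <- as.vector(stats::rmultinom(1L, config$reads_per_round_bound,
                                   bound_law))
  keep <- ci + cb > 0
  tab <- count_table(peptides[keep], ci[keep], cb[keep], config$design,
                     round_id)
  nxt <- if (config$resample) {
    if (sum(cb) == 0) stop("no bound reads to resample")
    cb / sum(cb)
  } else bound_law
  list(table = tab, composition = nxt)
}

#' Simulate a full multi-round selection experiment
#'
#' Generates the library, then chains [simulate_round()] for the configured
#' number of rounds, sequencing input and bound each round. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_result`: list with `tables` (per-round
#'   [count_table()]s), `truth` (the ground-truth [energy_model()] with one
#'   per-round parameter set per table), `compositions` (per-round starting
#'   compositions), `peptides`, and `config`.
#' @export
simulate_experiment <- function(config) {
  truth <- config$truth
  if (is.null(truth))
    truth <- random_truth_model(config$design, sigma = config$truth_sigma,
                                seed = config$seed, rounds = config$rounds)
  if (length(truth$per_round) < config$rounds)
    truth$per_round <- rep(truth$per_round[1L], config$rounds)
  lib <- gen_library(config)
  kappa <- kappa_truth(lib$peptides, truth, config)
  tables <- vector("list", config$rounds)
  compositions <- vector("list", config$rounds)
  comp <- lib$abundance
  with_seed(config$seed + 1L, {
    for (r in seq_len(config$rounds)) {
      compositions[[r]] <- comp
      res <- simulate_round(lib$peptides, comp, kappa, config, r)
      tables[[r]] <- res$table
      comp <- res$composition
    }
  })
  structure(list(tables = tables, truth = truth,
                 compositions = compositions,
                 peptides = lib$peptides, config = config),
            class = "sim_result")
}

#' Write synthetic FASTQ reads realizing a count table
#'
#' Back-translates each peptide through random NNS codons, wraps it in the
#' design's DNA anchors (with a short random pad on each side), assigns
#' constant PHRED 37 qualities, and optionally plants seeded substitution
#' errors plus a labelled fraction of deliberately corrupt reads: anchors
#' with 6 mismatches (fail to locate), one region base at PHRED 10 (fail the
#' quality filter), and an amber stop codon (fail the design match). The
#' planted counts are returned so read-processing bookkeeping can be checked
#' exactly.
#'
#' @param table a [count_table()].
#' @param design the [library_design()].
#' @param out_dir directory receiving `input.fastq` and `bound.fastq`.
#' @param error_rate per-base substitution probability in `[0, 0.1]`.
#' @param corrupt_fraction fraction of extra corrupt reads planted per
#'   column (default 0.05 when corrupting, split over the three kinds).
#' @param seed RNG seed.
#' @return list with `input`, `bound` (paths) and `planted`, a per-column
#'   matrix of corrupt-read counts by kind.
#' @export
gen_reads <- function(table, design, out_dir, error_rate = 0,
                      corrupt_fraction = 0, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 0.1, corrupt_fraction >= 0,
            corrupt_fraction < 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  codon_map <- lapply(AA_ALPHABET, codons_for_aa)
  bases <- c("A", "C", "G", "T")
  la <- design$dna_left_anchor
  ra <- design$dna_right_anchor
  L <- design$length
  good_q <- 37L

  back_translate <- function(peptides) {
    m <- encode_peptides(peptides)
    out <- character(nrow(m))
    for (i in seq_len(nrow(m))) {
      cods <- vapply(m[i, ], function(a) {
        cs <- codon_map[[a]]
        cs[sample.int(length(cs), 1L)]
      }, character(1))
      out[i] <- paste(cods, collapse = "")
    }
    out
  }

  mutate_anchor <- function(anchor, n_mm) {
    ch <- strsplit(anchor, "")[[1]]
    pos <- sample(seq_along(ch), n_mm)
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    paste(ch, collapse = "")
  }

  make_column <- function(counts, path) {
    peptides <- rep.int(table$sequence, counts)
    n <- length(peptides)
    regions <- back_translate(peptides)
    if (error_rate > 0) {
      for (i in seq_len(n)) {
        ch <- strsplit(regions[i], "")[[1]]
        hit <- which(stats::runif(length(ch)) < error_rate)
        for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
        regions[i] <- paste(ch, collapse = "")
      }
    }
    pads <- vapply(sample.int(6L, n, replace = TRUE) - 1L,
                   function(k) paste(sample(bases, k, replace = TRUE),
                                     collapse = ""), character(1))
    seqs <- paste0(pads, la, regions, ra)
    quals <- lapply(nchar(seqs), function(len) rep(good_q, len))
    kinds <- c("bad_anchor", "low_quality", "stop_codon")
    n_corrupt <- if (corrupt_fraction > 0)
      max(3L, round(corrupt_fraction * n)) else 0L
    planted <- stats::setNames(integer(3L), kinds)
    if (n_corrupt > 0L) {
      src <- sample.int(n, n_corrupt, replace = TRUE)
      kind <- rep(kinds, length.out = n_corrupt)
      extra_seq <- character(n_corrupt)
      extra_q <- vector("list", n_corrupt)
      for (i in seq_len(n_corrupt)) {
        region <- back_translate(peptides[src[i]])
        if (kind[i] == "bad_anchor") {
          sq <- paste0(mutate_anchor(la, 6L), region, ra)
          qv <- rep(good_q, nchar(sq))
        } else if (kind[i] == "low_quality") {
          sq <- paste0(la, region, ra)
          qv <- rep(good_q, nchar(sq))
          qv[nchar(la) + sample.int(3L * L, 1L)] <- 10L
        } else {
          codon_i <- sample.int(L, 1L)
          substr(region, 3L * codon_i - 2L, 3L * codon_i) <- "TAG"
          sq <- paste0(la, region, ra)
          qv <- rep(good_q, nchar(sq))
        }
        extra_seq[i] <- sq
        extra_q[[i]] <- qv
        planted[kind[i]] <- planted[kind[i]] + 1L
      }
      seqs <- c(seqs, extra_seq)
      quals <- c(quals, extra_q)
    }
    write_fastq(path, paste0("read", seq_along(seqs)), seqs, quals)
    planted
  }

  with_seed(seed, {
    p_in <- make_column(table$count_input, file.path(out_dir, "input.fastq"))
    p_bd <- make_column(table$count_bound, file.path(out_dir, "bound.fastq"))
    list(input = file.path(out_dir, "input.fastq"),
         bound = file.path(out_dir, "bound.fastq"),
         planted = rbind(input = p_in, bound = p_bd))
  })
}
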