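# Independent brute-force oracles, deliberately written as naive
# character-level loops so they share no code with the package internals.

ALPH <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Sum over offsets of exp(window score) on flankL+peptide+flankR, scoring a
# w x 20 coefficient table by direct substring lookup.
oracle_specific_sum <- function(peptide, coeffs, flank_left, flank_right, f) {
  left <- if (f > 0) substr(flank_left, nchar(flank_left) - f + 1,
                            nchar(flank_left)) else ""
  right <- if (f > 0) substr(flank_right, 1, f) else ""
  s <- paste0(left, peptide, right)
  w <- nrow(coeffs)
  total <- 0
  for (x in 1:(nchar(s) - w + 1)) {
    sc <- 0
    for (j in 1:w) {
      aa <- substr(s, x + j - 1, x + j - 1)
      sc <- sc + coeffs[j, match(aa, ALPH)]
    }
    total <- total + exp(sc)
  }
  total
}

oracle_nonspecific_sum <- function(peptide, coeffs, gamma) {
  w <- nrow(coeffs)
  total <- 0
  for (x in 1:(nchar(peptide) - w + 1)) {
    sc <- gamma[x]
    for (j in 1:w) {
      aa <- substr(peptide, x + j - 1, x + j - 1)
      sc <- sc + coeffs[j, match(aa, ALPH)]
    }
    total <- total + exp(sc)
  }
  total
}

oracle_kappa <- function(peptide, model, round_index) {
  rp <- model$per_round[[round_index]]
  exp(rp$log_alpha_ns) *
    oracle_nonspecific_sum(peptide, model$nonspecific$coeffs,
                           model$nonspecific$position_bias) +
    exp(rp$log_alpha_s) *
      oracle_specific_sum(peptide, model$specific$coeffs,
                          model$design$protein_flank_left,
                          model$design$protein_flank_right,
                          model$specific$flank_depth)
}

# Scaled binomial log-likelihood evaluated read by read: each input read
# contributes log P(input) = log(1/(1+rho*kappa)), each bound read
# log P(bound) = log(rho*kappa/(1+rho*kappa)).
oracle_log_likelihood <- function(tables, model) {
  if (inherits(tables, "count_table")) tables <- list(tables)
  total <- 0
  for (ci in seq_along(tables)) {
    tab <- tables[[ci]]
    rho <- exp(model$per_round[[ci]]$depth_log_ratio)
    kc <- sum(tab$count_input) + sum(tab$count_bound)
    contrib <- 0
    for (i in seq_len(nrow(tab))) {
      t_ <- rho * oracle_kappa(tab$sequence[i], model, ci)
      for (r in seq_len(tab$count_input[i])) contrib <- contrib + log(1 / (1 + t_))
      for (r in seq_len(tab$count_bound[i])) contrib <- contrib + log(t_ / (1 + t_))
    }
    total <- total + contrib / kc
  }
  total
}

# Exhaustive anchored-placement scan used to cross-check
# locate_variable_region.
oracle_locate <- function(read, design, max_mismatches) {
  la <- design$dna_left_anchor
  ra <- design$dna_right_anchor
  reg <- 3 * design$length
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  best <- NULL
  n <- nchar(read)
  span <- nchar(la) + reg + nchar(ra)
  if (n < span) return(NULL)
  for (s in 1:(n - span + 1)) {
    mml <- hamming(substr(read, s, s + nchar(la) - 1), la)
    rs <- s + nchar(la) + reg
    mmr <- hamming(substr(read, rs, rs + nchar(ra) - 1), ra)
    if (mml <= max_mismatches && mmr <= max_mismatches) {
      if (is.null(best) || mml + mmr < best$mm) {
        best <- list(mm = mml + mmr,
                     region = substr(read, s + nchar(la),
                                     s + nchar(la) + reg - 1))
      }
    }
  }
  if (is.null(best)) NULL else best$region
}

random_peptides <- function(n, L, fixed = NULL) {
  m <- matrix(sample(ALPH, n * L, replace = TRUE), n, L)
  for (p in names(fixed)) m[, as.integer(p)] <- fixed[[p]]
  apply(m, 1, paste, collapse = "")
}

random_model <- function(design, seed, w_ns = 3L, sigma = 0.5,
                         n_rounds = 1L, constrained = FALSE) {
  withr::with_seed(seed, {
    L <- design$length
    f <- min(5L, nchar(design$protein_flank_left),
             nchar(design$protein_flank_right))
    spec <- binding_mode(L, matrix(rnorm(L * 20, 0, sigma), L, 20),
                         flank_depth = f)
    if (constrained) spec <- constrain_central(spec)
    ns <- binding_mode(w_ns, matrix(rnorm(w_ns * 20, 0, sigma), w_ns, 20),
                       position_bias = rnorm(L - w_ns + 1, 0, 0.3))
    per_round <- replicate(n_rounds,
                           round_params(rnorm(1, 0, 0.5), rnorm(1, 0, 0.5),
                                        rnorm(1, 0, 0.5)),
                           simplify = FALSE)
    energy_model(spec, ns, per_round, design)
  })
}

random_table <- function(design, seed, n = 30L, max_count = 20L,
                         round_id = 1L) {
  withr::with_seed(seed, {
    seqs <- unique(random_peptides(n, design$length,
                                   as.list(design$fixed_positions)))
    count_table(seqs,
                sample.int(max_count, length(seqs), replace = TRUE),
                sample.int(max_count, length(seqs), replace = TRUE),
                design, round_id)
  })
}

# A tiny design with short flanks, cheap for brute-force work.
tiny_design <- function(L = 5L) {
  library_design("tiny", length = L,
                 dna_left_anchor = "ACGTACGTAC",
                 dna_right_anchor = "TTGGCCAATT",
                 protein_flank_left = "GQS",
                 protein_flank_right = "GGS")
}
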