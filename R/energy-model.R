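#' An additive binding free-energy model
#'
#' Couples a specific binding mode (the -ddG/RT matrix), a non-specific
#' background mode, and per-round activity/depth parameters. The predicted
#' enrichment of a peptide in round `c` is
#' `kappa = alpha_NS * nonspecific_sum + alpha_S * specific_sum`,
#' summing over all binding offsets of both modes.
#'
#' @param specific,nonspecific [binding_mode()] objects.
#' @param per_round list of [round_params()], one per count table.
#' @param design the [library_design()] the model was trained on.
#' @param metadata free-form list (domain name, rounds used, seed, ...).
#' @param normalized whether the specific mode is gauge-normalized
#'   (per-column maximum zero), see [normalize_model()].
#' @return object of class `energy_model`.
#' @export
energy_model <- function(specific, nonspecific, per_round, design,
                         metadata = list(), normalized = FALSE) {
  stopifnot(inherits(specific, "binding_mode"),
            inherits(nonspecific, "binding_mode"),
            inherits(design, "library_design"))
  if (!length(per_round)) stop("at least one round_params is required")
  if (inherits(per_round, "round_params")) per_round <- list(per_round)
  gL <- design$length - nonspecific$width + 1L
  if (is.null(nonspecific$position_bias))
    nonspecific$position_bias <- numeric(gL)
  if (length(nonspecific$position_bias) != gL)
    stop("non-specific position bias must have length L - w + 1 = ", gL)
  structure(list(specific = specific,
                 nonspecific = nonspecific,
                 per_round = per_round,
                 design = design,
                 metadata = metadata,
                 normalized = normalized),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(
    "energy_model: specific w=%d (flank depth %d), non-specific w=%d, %d round(s)%s\n",
    x$specific$width, x$specific$flank_depth, x$nonspecific$width,
    length(x$per_round), if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

# Flank residues (up to depth f) added on each side of the variable region
# when scoring the specific mode.
#' @keywords internal
flank_codes <- function(design, f) {
  if (f == 0L) return(list(left = integer(), right = integer()))
  fl <- design$protein_flank_left
  fr <- design$protein_flank_right
  if (f > nchar(fl) || f > nchar(fr))
    stop("flank depth exceeds the constant protein flanks")
  left <- substr(fl, nchar(fl) - f + 1L, nchar(fl))
  right <- substr(fr, 1L, f)
  list(left = encode_peptides(left)[1L, ],
       right = encode_peptides(right)[1L, ])
}

# Per-offset exp(window score) for an integer-coded sequence matrix.
# mat: N x Lx codes in 1..20; coeffs: w x 20; gamma: per-offset bias or NULL.
#' @keywords internal
window_exp <- function(mat, coeffs, gamma = NULL) {
  w <- nrow(coeffs)
  noff <- ncol(mat) - w + 1L
  if (noff < 1L) stop("sequence shorter than the binding-mode width")
  E <- matrix(0, nrow(mat), noff)
  for (x in seq_len(noff)) {
    sc <- numeric(nrow(mat))
    for (j in seq_len(w)) sc <- sc + coeffs[(mat[, x + j - 1L] - 1L) * w + j]
    if (!is.null(gamma)) sc <- sc + gamma[x]
    E[, x] <- exp(sc)
  }
  E
}

#' @keywords internal
extend_with_flanks <- function(pepmat, design, f) {
  if (f == 0L) return(pepmat)
  fc <- flank_codes(design, f)
  n <- nrow(pepmat)
  cbind(matrix(rep(fc$left, each = n), n),
        pepmat,
        matrix(rep(fc$right, each = n), n))
}

#' Specific-mode offset sum
#'
#' Total specific binding signal of a peptide: the sum over all offsets
#' `x = 1-f .. L+f-w+1` of `exp(window score)` on the concatenation
#' `flank_left + peptide + flank_right`, where `f` is the mode's flank
#' overlap depth. Strictly positive.
#'
#' @param peptide peptide string(s) of the design length.
#' @param mode the specific [binding_mode()].
#' @param design [library_design()] providing the constant flanks.
#' @return numeric vector of offset sums.
#' @export
specific_sum <- function(peptide, mode, design) {
  m <- encode_peptides(peptide)
  ext <- extend_with_flanks(m, design, mode$flank_depth)
  rowSums(window_exp(ext, mode$coeffs))
}

#' Non-specific-mode offset sum
#'
#' Sum over offsets `x = 1 .. L-w+1` of `exp(window score + gamma_x)` on the
#' variable region only (no flank overlap). Strictly positive.
#'
#' @param peptide peptide string(s).
#' @param mode the non-specific [binding_mode()].
#' @param position_bias per-offset bias; defaults to the mode's own.
#' @return numeric vector of offset sums.
#' @export
nonspecific_sum <- function(peptide, mode, position_bias = NULL) {
  m <- encode_peptides(peptide)
  gamma <- if (is.null(position_bias)) mode$position_bias else position_bias
  noff <- ncol(m) - mode$width + 1L
  if (is.null(gamma)) gamma <- numeric(noff)
  if (length(gamma) != noff)
    stop("position bias must have one entry per offset")
  rowSums(window_exp(m, mode$coeffs, gamma))
}

#' Predicted enrichment of a peptide in one selection round
#'
#' `kappa = alpha_NS * nonspecific_sum + alpha_S * specific_sum`, with the
#' activities of the requested round. All binding offsets of both modes are
#' summed over.
#'
#' @param peptide peptide string(s).
#' @param model an [energy_model()].
#' @param round_index 1-based index into the model's per-round parameters.
#' @return positive numeric vector.
#' @export
enrichment <- function(peptide, model, round_index = 1L) {
  rp <- model$per_round[[round_index]]
  exp(rp$log_alpha_ns) * nonspecific_sum(peptide, model$nonspecific) +
    exp(rp$log_alpha_s) * specific_sum(peptide, model$specific, model$design)
}

# kappa for every row of a count table (vectorized; used by the likelihood
# and the enrichment baseline).
#' @keywords internal
kappa_table <- function(table, model, round_index) {
  enrichment(table$sequence, model, round_index)
}

#' Scaled binomial log-likelihood of count tables under a model
#'
#' For each table `c` with total reads `k_c`, the contribution is
#' `(1/k_c) * sum_i [ k_I ln(1/(1+rho*kappa)) + k_B ln(rho*kappa/(1+rho*kappa)) ]`
#' where `rho` is the table's fitted depth ratio; tables contribute
#' independently and are summed.
#'
#' @param tables a [count_table()] or list of them, aligned with the model's
#'   per-round parameters.
#' @param model an [energy_model()].
#' @return the log-likelihood (a real number, typically negative).
#' @export
log_likelihood <- function(tables, model) {
  if (inherits(tables, "count_table")) tables <- list(tables)
  if (length(tables) != length(model$per_round))
    stop("number of tables does not match the model's per-round parameters")
  total <- 0
  for (ci in seq_along(tables)) {
    tab <- tables[[ci]]
    rho <- exp(model$per_round[[ci]]$depth_log_ratio)
    t_ <- rho * kappa_table(tab, model, ci)
    l1pt <- log1p(t_)
    contrib <- tab$count_bound * (log(t_) - l1pt) - tab$count_input * l1pt
    total <- total + sum(contrib) / attr(tab, "k_total")
  }
  total
}

#' @keywords internal
free_coefficients <- function(model) {
  c(model$specific$coeffs[!model$specific$frozen],
    model$nonspecific$coeffs[!model$nonspecific$frozen],
    model$nonspecific$position_bias)
}

#' Regularization penalty of a model
#'
#' `l_reg` = L2 term + symmetric exponential barrier over all free
#' coefficients of both modes and the position bias, plus (when `tables` are
#' supplied) a Dirichlet pseudo-count term
#' `-(count/|S_c|) * sum_i [ln p_I + ln p_B]` on the predicted column
#' probabilities. Frozen cells are excluded.
#'
#' @param model an [energy_model()].
#' @param config a [regularization_config()].
#' @param tables optional count tables for the Dirichlet term.
#' @return penalty value (non-negative).
#' @export
penalty <- function(model, config, tables = NULL) {
  stopifnot(inherits(config, "regularization_config"))
  beta <- free_coefficients(model)
  p <- config$lambda_l2 * sum(beta^2) +
    config$barrier_weight *
      sum(exp(beta - config$barrier_cap) + exp(-beta - config$barrier_cap))
  if (!is.null(tables) && config$dirichlet_count > 0) {
    if (inherits(tables, "count_table")) tables <- list(tables)
    for (ci in seq_along(tables)) {
      tab <- tables[[ci]]
      rho <- exp(model$per_round[[ci]]$depth_log_ratio)
      t_ <- rho * kappa_table(tab, model, ci)
      l1pt <- log1p(t_)
      # ln p_I = -ln(1+t), ln p_B = ln t - ln(1+t)
      p <- p - config$dirichlet_count / attr(tab, "n_unique") *
        sum(log(t_) - 2 * l1pt)
    }
  }
  p
}

# Per-column value lookup for a (possibly padded) encoded window; pad cells
# score at the column mean over unfrozen cells.
#' @keywords internal
window_values <- function(mat, mode) {
  w <- mode$width
  if (ncol(mat) != w) stop("peptide length must equal the model width ", w)
  colmean <- vapply(seq_len(w), function(j) {
    free <- !mode$frozen[j, ]
    if (any(free)) mean(mode$coeffs[j, free]) else mean(mode$coeffs[j, ])
  }, numeric(1))
  v <- matrix(0, nrow(mat), w)
  for (j in seq_len(w)) {
    col <- mat[, j]
    pad <- col == PAD_CODE
    vj <- numeric(length(col))
    vj[!pad] <- mode$coeffs[(col[!pad] - 1L) * w + j]
    vj[pad] <- colmean[j]
    v[, j] <- vj
  }
  v
}

#' Binding free energy and relative affinity of peptides
#'
#' `ddg()` scores the single central (phosphosite-aligned) register:
#' `ddG/RT = sum_j max(column j) - sum_j coeff[j, residue_j]`, which is zero
#' exactly for the per-position-argmax peptide. `relative_affinity()` is
#' `exp(-ddG/RT)`, in `(0, 1]`, and is inversely proportional to the
#' dissociation constant K_D. Requires a gauge-normalized model (see
#' [normalize_model()]); terminus placeholders `-` score at the column mean.
#'
#' @param peptide peptide string(s) whose length equals the specific width.
#' @param model a normalized [energy_model()].
#' @return numeric vector (`ddg`: non-negative; `relative_affinity`: in
#'   `(0, 1]`).
#' @rdname ddg
#' @export
ddg <- function(peptide, model) {
  if (!isTRUE(model$normalized))
    stop("model is not gauge-normalized; call normalize_model() first")
  mode <- model$specific
  m <- encode_peptides(peptide, allow_pad = TRUE)
  v <- window_values(m, mode)
  colmax <- apply(mode$coeffs, 1L, max)
  sum(colmax) - rowSums(v)
}

#' @rdname ddg
#' @export
relative_affinity <- function(peptide, model) {
  exp(-ddg(peptide, model))
}
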