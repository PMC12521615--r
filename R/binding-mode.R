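#' A binding mode: an additive log-linear window score
#'
#' A binding mode scores fixed-width windows of a peptide with a `w x 20`
#' coefficient table of log-scale contributions. For the specific mode these
#' coefficients are the entries of the free-energy matrix -ddG/RT; for the
#' non-specific mode they absorb background selection and sequence biases and
#' may be accompanied by a per-offset position bias. The specific mode may
#' extend its windows into the constant displayed flanks by `flank_depth`
#' residues.
#'
#' @param width window width in residues.
#' @param coeffs `width x 20` numeric matrix in [AA_ALPHABET] column order
#'   (default all zero).
#' @param position_bias optional per-offset additive bias (non-specific mode
#'   only); length must be `L - width + 1` for the design length `L` scored.
#' @param flank_depth residues of constant-flank overlap allowed (specific
#'   mode; 0 for non-specific).
#' @param frozen optional `width x 20` logical matrix marking cells held
#'   fixed during fitting (e.g. the central-tyrosine constraint).
#' @param central 1-based index of the reference (phosphosite-aligned)
#'   column; defaults to the middle column.
#' @return object of class `binding_mode`.
#' @export
binding_mode <- function(width, coeffs = NULL, position_bias = NULL,
                         flank_depth = 0L, frozen = NULL, central = NULL) {
  width <- as.integer(width)
  stopifnot(width >= 1L)
  if (is.null(coeffs)) coeffs <- matrix(0, width, 20L)
  coeffs <- as.matrix(coeffs)
  if (!all(dim(coeffs) == c(width, 20L)))
    stop("coeffs must be a ", width, " x 20 matrix")
  if (!all(is.finite(coeffs))) stop("coeffs must be finite")
  dimnames(coeffs) <- list(seq_len(width), AA_ALPHABET)
  if (!is.null(position_bias) && flank_depth > 0L)
    stop("position bias is only supported without flank overlap")
  if (is.null(frozen)) frozen <- matrix(FALSE, width, 20L)
  if (is.null(central)) central <- as.integer(ceiling(width / 2))
  structure(list(width = width,
                 coeffs = coeffs,
                 position_bias = position_bias,
                 flank_depth = as.integer(flank_depth),
                 frozen = frozen,
                 central = as.integer(central)),
            class = "binding_mode")
}

#' Central-tyrosine constraint for a specific binding mode
#'
#' Freezes the central column of a specific mode to recognise tyrosine:
#' weight 0 for Y and `value` (default -10) for every other residue. Frozen
#' cells are excluded from regularization and from the fitted gradient.
#'
#' @param mode a [binding_mode()].
#' @param residue constrained residue (default `"Y"`).
#' @param value weight assigned to all other residues (default -10).
#' @return the constrained mode.
#' @export
constrain_central <- function(mode, residue = "Y", value = -10) {
  stopifnot(inherits(mode, "binding_mode"))
  j <- mode$central
  mode$coeffs[j, ] <- value
  mode$coeffs[j, residue] <- 0
  mode$frozen[j, ] <- TRUE
  mode
}

#' Regularization settings for model fitting
#'
#' The fitted loss adds to the negative scaled-binomial log-likelihood an L2
#' term on all free coefficients, a symmetric exponential barrier
#' `exp(b - B) + exp(-b - B)` keeping coefficients in a numerically safe
#' range, and a Dirichlet pseudo-count term on the predicted input/bound
#' column probabilities.
#'
#' @param lambda_l2 L2 weight per coefficient (default 1e-6).
#' @param barrier_cap soft cap `B` (default 8).
#' @param barrier_weight barrier weight (default 1e-6).
#' @param dirichlet_count pseudo-count (default 5).
#' @return object of class `regularization_config`.
#' @export
regularization_config <- function(lambda_l2 = 1e-6, barrier_cap = 8,
                                  barrier_weight = 1e-6,
                                  dirichlet_count = 5) {
  if (lambda_l2 < 0 || barrier_weight < 0 || dirichlet_count < 0)
    stop("regularization weights must be non-negative")
  structure(list(lambda_l2 = lambda_l2, barrier_cap = barrier_cap,
                 barrier_weight = barrier_weight,
                 dirichlet_count = dirichlet_count),
            class = "regularization_config")
}

#' Per-round activity and depth parameters
#'
#' Each count table has its own activity weights for the non-specific and
#' specific modes and a depth log-ratio: the sequencing-depth parameters of
#' the input and bound columns enter the likelihood only through their ratio,
#' so a single free log-ratio per table is fitted.
#'
#' @param log_alpha_ns,log_alpha_s log activity weights.
#' @param depth_log_ratio log of (bound depth / input depth).
#' @return object of class `round_params`.
#' @export
round_params <- function(log_alpha_ns = 0, log_alpha_s = 0,
                         depth_log_ratio = 0) {
  structure(list(log_alpha_ns = log_alpha_ns,
                 log_alpha_s = log_alpha_s,
                 depth_log_ratio = depth_log_ratio),
            class = "round_params")
}
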