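#' Write / read an energy model as JSON
#'
#' Models are serialized with full (17 significant digit) precision so that a
#' write/read round trip reproduces every parameter bit-exactly. Coefficient
#' tables are stored row-major (`width x 20`, alphabet column order);
#' activities and depths are stored on the log scale, as fitted.
#'
#' @param model an [energy_model()].
#' @param path output / input JSON path.
#' @return `read_model_json` returns the [energy_model()];
#'   `write_model_json` returns `path` invisibly.
#' @rdname model_json
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "energy_model"))
  des <- model$design
  frozen_cells <- function(mode) {
    idx <- which(mode$frozen, arr.ind = TRUE)
    if (!nrow(idx)) return(list())
    lapply(seq_len(nrow(idx)), function(i) {
      list(position = unname(idx[i, 1L]),
           residue = AA_ALPHABET[idx[i, 2L]],
           value = unname(mode$coeffs[idx[i, 1L], idx[i, 2L]]))
    })
  }
  obj <- list(
    format_version = 1L,
    alphabet = AA_STRING,
    design = list(name = des$name,
                  L = des$length,
                  fixed_positions = as.list(des$fixed_positions),
                  dna_left_anchor = des$dna_left_anchor,
                  dna_right_anchor = des$dna_right_anchor,
                  protein_flank_left = des$protein_flank_left,
                  protein_flank_right = des$protein_flank_right),
    specific = list(width = model$specific$width,
                    f = model$specific$flank_depth,
                    central = model$specific$central,
                    coeffs = as.vector(t(model$specific$coeffs)),
                    constrained_cells = frozen_cells(model$specific)),
    nonspecific = list(width = model$nonspecific$width,
                       coeffs = as.vector(t(model$nonspecific$coeffs)),
                       gamma = model$nonspecific$position_bias),
    per_round = lapply(model$per_round, function(rp) {
      list(log_alpha_NS = rp$log_alpha_ns,
           log_alpha_S = rp$log_alpha_s,
           depth_log_ratio = rp$depth_log_ratio)
    }),
    normalized = isTRUE(model$normalized),
    metadata = model$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$alphabet, AA_STRING))
    stop("model file uses an unexpected alphabet")
  d <- obj$design
  design <- library_design(d$name, d$L,
                           fixed_positions = unlist(d$fixed_positions),
                           dna_left_anchor = d$dna_left_anchor,
                           dna_right_anchor = d$dna_right_anchor,
                           protein_flank_left = d$protein_flank_left,
                           protein_flank_right = d$protein_flank_right)
  unpack <- function(v, w) matrix(unlist(v), nrow = w, byrow = TRUE)
  sp <- obj$specific
  spec <- binding_mode(sp$width, unpack(sp$coeffs, sp$width),
                       flank_depth = sp$f, central = sp$central)
  for (cell in sp$constrained_cells) {
    i <- cell$position; j <- match(cell$residue, AA_ALPHABET)
    spec$coeffs[i, j] <- cell$value
    spec$frozen[i, j] <- TRUE
  }
  ns <- obj$nonspecific
  nonspec <- binding_mode(ns$width, unpack(ns$coeffs, ns$width),
                          position_bias = unlist(ns$gamma))
  per_round <- lapply(obj$per_round, function(rp) {
    round_params(rp$log_alpha_NS, rp$log_alpha_S, rp$depth_log_ratio)
  })
  energy_model(spec, nonspec, per_round, design,
               metadata = obj$metadata,
               normalized = isTRUE(obj$normalized))
}
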