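#' Extract the scoring window around a tyrosine phosphosite
#'
#' Returns the model-width window centred on the site. Sites closer to a
#' protein terminus than the half-width are padded with the neutral
#' placeholder `-`, which [ddg()] scores at the column mean; pass
#' `skip_truncated = TRUE` to drop such sites instead.
#'
#' @param protein_sequence full protein sequence.
#' @param site_position 1-based residue index of the phosphorylated tyrosine.
#' @param model an [energy_model()] (provides width and central offset).
#' @param protein_id identifier carried through to the record.
#' @param skip_truncated drop sites whose window runs past a terminus.
#' @return list with `protein_id`, `site_position`, `window`, or `NULL` if
#'   the site residue is not `Y` (or the window is truncated and
#'   `skip_truncated` is set).
#' @export
extract_window <- function(protein_sequence, site_position, model,
                           protein_id = NA_character_,
                           skip_truncated = FALSE) {
  n <- nchar(protein_sequence)
  if (site_position < 1L || site_position > n)
    stop("site position out of range")
  if (substr(protein_sequence, site_position, site_position) != "Y")
    return(NULL)
  w <- model$specific$width
  central <- model$specific$central
  left <- central - 1L
  right <- w - central
  lo <- site_position - left
  hi <- site_position + right
  if (skip_truncated && (lo < 1L || hi > n)) return(NULL)
  pre <- strrep(PAD_CHAR, max(0L, 1L - lo))
  post <- strrep(PAD_CHAR, max(0L, hi - n))
  core <- substr(protein_sequence, max(1L, lo), min(n, hi))
  list(protein_id = protein_id,
       site_position = site_position,
       window = paste0(pre, core, post))
}

#' Score and rank phosphosite windows by relative affinity
#'
#' Computes `relative_affinity()` for each record and returns the table
#' sorted by descending score (stable: ties keep input order). When a
#' protein-pair allow-list is given (e.g. co-expressed pairs for a given
#' domain), only records whose `protein_id` appears in it are kept.
#'
#' @param records data.frame with columns `protein_id`, `site_position`,
#'   `window` (as produced by [extract_window()]), or a list of such records.
#' @param model a normalized [energy_model()].
#' @param allow_pairs optional character vector of allowed `protein_id`s.
#'   An empty vector filters everything out.
#' @return the records data.frame with a `relative_affinity` column, ranked.
#' @export
score_sites <- function(records, model, allow_pairs = NULL) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  if (!is.null(allow_pairs))
    records <- records[records$protein_id %in% allow_pairs, , drop = FALSE]
  if (!nrow(records)) {
    records$relative_affinity <- numeric(0)
    return(records)
  }
  records$relative_affinity <- relative_affinity(records$window, model)
  ord <- order(-records$relative_affinity)   # stable in R
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predicted affinity ratio between two alleles of a binding site
#'
#' For a wild-type/variant window pair differing at exactly one non-central
#' position, returns the ratio of predicted relative affinities
#' (variant / wild-type) together with the larger of the two affinities
#' (the quantity against which variant effects are usually plotted). A ratio
#' of 1 means the model predicts no affinity change. Pairs substituting the
#' central tyrosine itself are rejected.
#'
#' @param wt_window,var_window model-width peptide windows.
#' @param model a normalized [energy_model()].
#' @return list with `ratio`, `max_affinity`, `wt_affinity`, `var_affinity`.
#' @export
variant_ratio <- function(wt_window, var_window, model) {
  w <- model$specific$width
  if (nchar(wt_window) != w || nchar(var_window) != w)
    stop("windows must have the model width ", w)
  diff_pos <- which(strsplit(wt_window, "")[[1]] !=
                    strsplit(var_window, "")[[1]])
  if (length(diff_pos) > 1L)
    stop("windows differ at more than one position")
  if (length(diff_pos) == 1L && diff_pos == model$specific$central)
    stop("substitution of the central tyrosine itself is not scored")
  aw <- relative_affinity(wt_window, model)
  av <- relative_affinity(var_window, model)
  list(ratio = av / aw,
       max_affinity = max(aw, av),
       wt_affinity = aw,
       var_affinity = av)
}

#' Truncate a specific-mode matrix to a narrower window
#'
#' Drops outer columns of the specific mode, keeping `keep_left` positions to
#' the left and `keep_right` to the right of the central column (e.g.
#' `keep_left = keep_right = 4` aligns an 11-wide model with 9-residue
#' peptides). Constraint cells are preserved and the result renormalized.
#'
#' @param model an [energy_model()].
#' @param keep_left,keep_right retained positions on each side of the
#'   central column.
#' @return the truncated, normalized [energy_model()].
#' @export
truncate_model <- function(model, keep_left, keep_right) {
  central <- model$specific$central
  w <- model$specific$width
  if (keep_left < 0L || keep_right < 0L)
    stop("truncation must keep the central column")
  lo <- central - keep_left
  hi <- central + keep_right
  if (lo < 1L || hi > w)
    stop("cannot keep more positions than the model has")
  keep <- lo:hi
  spec <- binding_mode(length(keep),
                       model$specific$coeffs[keep, , drop = FALSE],
                       flank_depth = 0L,
                       frozen = model$specific$frozen[keep, , drop = FALSE],
                       central = keep_left + 1L)
  model$specific <- spec
  normalize_model(model)
}

#' Regress measured log dissociation constants on predicted energies
#'
#' Ordinary least squares of `ln(K_D)` on predicted `ddG/RT`; under the model
#' contract the two are linearly related with unit slope up to an additive
#' constant.
#'
#' @param predictions predicted ddG/RT values.
#' @param measured_kd measured dissociation constants (positive, length
#'   matched, at least 3).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
validate_against_kd <- function(predictions, measured_kd) {
  if (length(predictions) != length(measured_kd) || length(predictions) < 3L)
    stop("need at least 3 matched prediction/K_D pairs")
  if (any(measured_kd <= 0)) stop("K_D values must be positive")
  y <- log(measured_kd)
  f <- stats::lm(y ~ predictions)
  list(slope = unname(stats::coef(f)[2L]),
       intercept = unname(stats::coef(f)[1L]),
       r_squared = stats::cor(predictions, y)^2)
}

#' One-sided exact binomial sign test
#'
#' `P(X >= n_concordant)` for `X ~ Binomial(n_total, 1/2)`, by exact
#' summation. Used to test whether predicted variant-effect directions agree
#' with measured ones more often than chance.
#'
#' @param n_concordant number of concordant pairs.
#' @param n_total total pairs.
#' @return one-sided p-value.
#' @export
sign_test <- function(n_concordant, n_total) {
  stopifnot(n_concordant >= 0L, n_concordant <= n_total)
  if (n_total == 0L) return(1)
  sum(choose(n_total, n_concordant:n_total)) / 2^n_total
}

#' Render an energy or enrichment logo
#'
#' Draws, per position, residue letters with signed heights equal to the
#' coefficient minus the position mean (frozen constraint cells are excluded
#' from the mean and drawn as gray rectangles). The plotted numeric matrix is
#' also written as a TSV next to the figure, so the rendering is fully
#' reproducible.
#'
#' @param x an [energy_model()], [aa_log_enrichment()] matrix, or plain
#'   `L x 20` matrix.
#' @param out_path output PDF path; the matrix TSV is written alongside with
#'   extension `.tsv`.
#' @return invisibly, the centered height matrix that was drawn.
#' @export
energy_logo <- function(x, out_path) {
  if (inherits(x, "energy_model")) {
    m <- x$specific$coeffs
    mask <- x$specific$frozen
  } else {
    m <- unclass(x)
    mask <- attr(x, "mask")
    if (is.null(mask)) mask <- matrix(FALSE, nrow(m), ncol(m))
  }
  L <- nrow(m)
  heights <- m
  for (p in seq_len(L)) {
    free <- !mask[p, ]
    mu <- if (any(free)) mean(m[p, free]) else 0
    heights[p, free] <- m[p, free] - mu
    heights[p, !free] <- 0
  }
  dimnames(heights) <- list(seq_len(L), AA_ALPHABET)
  tsv <- paste0(tools::file_path_sans_ext(out_path), ".tsv")
  utils::write.table(data.frame(position = seq_len(L), heights,
                                check.names = FALSE),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  grDevices::pdf(out_path, width = max(4, L * 0.8), height = 4)
  on.exit(grDevices::dev.off())
  ylim <- range(c(heights, -heights)) * 1.1
  if (diff(ylim) == 0) ylim <- c(-1, 1)
  plot(NA, xlim = c(0.5, L + 0.5), ylim = ylim, xlab = "position",
       ylab = "contribution (centered)", xaxt = "n", bty = "n")
  graphics::axis(1, at = seq_len(L))
  graphics::abline(h = 0, col = "gray60")
  for (p in seq_len(L)) {
    if (all(mask[p, ])) {
      graphics::rect(p - 0.4, ylim[1] * 0.5, p + 0.4, ylim[2] * 0.5,
                     col = "gray85", border = NA)
      graphics::text(p, 0, "Y", cex = 1.2)
      next
    }
    h <- heights[p, ]
    up <- sort(h[h > 0], decreasing = FALSE)
    dn <- sort(h[h < 0], decreasing = TRUE)
    y0 <- 0
    for (a in names(up)) {
      graphics::text(p, y0 + up[a] / 2, a,
                     cex = 0.4 + 2.2 * up[a] / max(abs(ylim)),
                     col = "firebrick")
      y0 <- y0 + up[a]
    }
    y0 <- 0
    for (a in names(dn)) {
      graphics::text(p, y0 + dn[a] / 2, a,
                     cex = 0.4 + 2.2 * abs(dn[a]) / max(abs(ylim)),
                     col = "steelblue")
      y0 <- y0 + dn[a]
    }
  }
  invisible(heights)
}

#' Hierarchically cluster binding models
#'
#' Average-linkage clustering of specific-mode coefficient tables on the
#' distance `1 - r` (Pearson over cells unfrozen in all models), after
#' truncating every model to the narrowest common width around its central
#' column. Deterministic leaf order.
#'
#' @param models named list of at least two [energy_model()] objects.
#' @return an [stats::hclust] object.
#' @export
cluster_models <- function(models) {
  stopifnot(length(models) >= 2L)
  lefts <- vapply(models, function(m) m$specific$central - 1L, integer(1))
  rights <- vapply(models,
                   function(m) m$specific$width - m$specific$central,
                   integer(1))
  kl <- min(lefts); kr <- min(rights)
  mats <- lapply(models, function(m) {
    keep <- (m$specific$central - kl):(m$specific$central + kr)
    list(m = m$specific$coeffs[keep, , drop = FALSE],
         frozen = m$specific$frozen[keep, , drop = FALSE])
  })
  free <- Reduce(`&`, lapply(mats, function(x) !x$frozen))
  n <- length(models)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- stats::cor(mats[[i]]$m[free], mats[[j]]$m[free])
      d[i, j] <- d[j, i] <- 1 - r
    }
  }
  labs <- names(models)
  if (is.null(labs)) labs <- paste0("model", seq_len(n))
  stats::hclust(stats::as.dist(`dimnames<-`(d, list(labs, labs))),
                method = "average")
}
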