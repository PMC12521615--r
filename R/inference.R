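#' Fitting configuration
#'
#' @param constrained_central freeze the central specific-mode column to
#'   recognise `constrained_residue` (default TRUE).
#' @param constrained_residue residue recognised at the central position
#'   (default `"Y"`).
#' @param constrained_value frozen weight for all other residues at the
#'   central position (default -10).
#' @param w_ns non-specific window width (3 by default; 1 suppresses the
#'   non-specific mode's ability to absorb short motifs, as used for domains
#'   whose motif is itself short).
#' @param flank_depth specific-mode constant-flank overlap (default 5).
#' @param max_iterations optimizer iteration cap.
#' @param convergence_tol relative tolerance on the total loss (default 1e-9).
#' @param seed RNG seed for initialization; recorded in model metadata.
#' @param regularization a [regularization_config()].
#' @param optimizer_name only `"L-BFGS-B"` is supported.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(constrained_central = TRUE,
                       constrained_residue = "Y",
                       constrained_value = -10,
                       w_ns = 3L,
                       flank_depth = 5L,
                       max_iterations = 500L,
                       convergence_tol = 1e-9,
                       seed = 1L,
                       regularization = regularization_config(),
                       optimizer_name = "L-BFGS-B") {
  stopifnot(convergence_tol > 0, max_iterations >= 1L,
            optimizer_name == "L-BFGS-B")
  structure(list(constrained_central = constrained_central,
                 constrained_residue = constrained_residue,
                 constrained_value = constrained_value,
                 w_ns = as.integer(w_ns),
                 flank_depth = as.integer(flank_depth),
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 seed = as.integer(seed),
                 regularization = regularization,
                 optimizer_name = optimizer_name),
            class = "fit_config")
}

# Evaluate .Random.seed-safe seeded code.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @keywords internal
check_same_design <- function(tables) {
  d1 <- attr(tables[[1L]], "design")
  for (tab in tables[-1L]) {
    d <- attr(tab, "design")
    if (!identical(d$name, d1$name) || d$length != d1$length ||
        !identical(d$fixed_positions, d1$fixed_positions))
      stop("all count tables must share one library design")
  }
  d1
}

# Internal optimization state shared by fit(): encoded tables, parameter
# packing, and the cached loss/gradient closure over the C++ kernel.
#' @keywords internal
make_loss <- function(tables, design, config) {
  L <- design$length
  w_s <- L
  f <- min(config$flank_depth,
           nchar(design$protein_flank_left),
           nchar(design$protein_flank_right))
  w_ns <- config$w_ns
  n_gamma <- L - w_ns + 1L
  enc <- lapply(tables, function(tab) {
    pep <- encode_peptides(tab$sequence)
    list(pep = pep,
         ext = extend_with_flanks(pep, design, f),
         kI = tab$count_input, kB = tab$count_bound,
         kc = attr(tab, "k_total"),
         dirw = config$regularization$dirichlet_count / attr(tab, "n_unique"),
         log_rho0 = log(sum(tab$count_bound) / sum(tab$count_input)))
  })
  frozen <- matrix(FALSE, w_s, 20L)
  frozen_vals <- matrix(0, w_s, 20L)
  central <- as.integer(ceiling(w_s / 2))
  if (isTRUE(config$constrained_central)) {
    frozen[central, ] <- TRUE
    frozen_vals[central, ] <- config$constrained_value
    frozen_vals[central, match(config$constrained_residue, AA_ALPHABET)] <- 0
  }
  free_idx <- which(!frozen)
  n_spec <- length(free_idx)
  n_ns <- w_ns * 20L
  nc <- length(tables)
  npar <- n_spec + n_ns + n_gamma + 3L * nc
  reg <- config$regularization
  ncoef <- n_spec + n_ns + n_gamma   # regularized leading block

  unpack <- function(theta) {
    Cs <- frozen_vals
    Cs[free_idx] <- theta[seq_len(n_spec)]
    Cns <- matrix(theta[n_spec + seq_len(n_ns)], w_ns, 20L)
    gamma <- theta[n_spec + n_ns + seq_len(n_gamma)]
    rounds <- matrix(theta[ncoef + seq_len(3L * nc)], nrow = 3L)
    list(Cs = Cs, Cns = Cns, gamma = gamma, rounds = rounds)
  }

  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$res)
    p <- unpack(theta)
    value <- 0
    gCs <- matrix(0, w_s, 20L)
    gCns <- matrix(0, w_ns, 20L)
    gGamma <- numeric(n_gamma)
    gRounds <- matrix(0, 3L, nc)
    for (ci in seq_len(nc)) {
      e <- enc[[ci]]
      r <- table_loss_grad_cpp(e$ext, e$pep, e$kI, e$kB,
                               p$Cs, p$Cns, p$gamma,
                               p$rounds[1L, ci], p$rounds[2L, ci],
                               p$rounds[3L, ci], e$kc, e$dirw)
      value <- value + r$value
      gCs <- gCs + r$grad_specific
      gCns <- gCns + r$grad_nonspecific
      gGamma <- gGamma + r$grad_gamma
      gRounds[, ci] <- c(r$grad_log_alpha_ns, r$grad_log_alpha_s,
                         r$grad_depth_log_ratio)
    }
    coef <- theta[seq_len(ncoef)]
    value <- value + reg$lambda_l2 * sum(coef^2) +
      reg$barrier_weight * sum(exp(coef - reg$barrier_cap) +
                               exp(-coef - reg$barrier_cap))
    gcoef <- c(gCs[free_idx], as.vector(gCns), gGamma) +
      2 * reg$lambda_l2 * coef +
      reg$barrier_weight * (exp(coef - reg$barrier_cap) -
                            exp(-coef - reg$barrier_cap))
    res <- list(value = value, grad = c(gcoef, as.vector(gRounds)))
    cache$theta <- theta
    cache$res <- res
    res
  }

  init <- function() {
    theta <- numeric(npar)
    theta[seq_len(n_spec + n_ns)] <-
      stats::rnorm(n_spec + n_ns, 0, 0.01)
    for (ci in seq_len(nc))
      theta[ncoef + 3L * (ci - 1L) + 3L] <- enc[[ci]]$log_rho0
    theta
  }

  build_model <- function(theta, metadata) {
    p <- unpack(theta)
    spec <- binding_mode(w_s, p$Cs, flank_depth = f, frozen = frozen,
                         central = central)
    nonspec <- binding_mode(w_ns, p$Cns, position_bias = p$gamma)
    per_round <- lapply(seq_len(nc), function(ci) {
      round_params(p$rounds[1L, ci], p$rounds[2L, ci], p$rounds[3L, ci])
    })
    energy_model(spec, nonspec, per_round, design, metadata = metadata)
  }

  list(evaluate = evaluate, init = init, build_model = build_model,
       npar = npar)
}

#' Fit an energy model to one or more count tables by maximum likelihood
#'
#' Minimizes `l_total = -l_data + l_reg` over all free parameters jointly
#' (coefficients on the linear scale, activities and depth ratios on the log
#' scale) with L-BFGS-B using the analytic gradient. One shared coefficient
#' set is fitted across all tables; activity and depth parameters are
#' independent per table. Constrained central-column cells are held at their
#' frozen values exactly and excluded from the gradient and regularization.
#'
#' @param tables a [count_table()] or list of them sharing one design.
#' @param config a [fit_config()].
#' @return list with `model` (the fitted [energy_model()]) and `report`
#'   (initial/final loss, best-so-far loss trajectory, optimizer
#'   diagnostics).
#' @export
fit <- function(tables, config = fit_config()) {
  if (inherits(tables, "count_table")) tables <- list(tables)
  if (!length(tables)) stop("at least one count table is required")
  design <- check_same_design(tables)
  ls <- make_loss(tables, design, config)
  theta0 <- with_seed(config$seed, ls$init())
  e0 <- ls$evaluate(theta0)
  if (!is.finite(e0$value))
    stop("loss is not finite at initialization (value = ", e0$value, ")")
  trace <- new.env(parent = emptyenv())
  trace$values <- numeric()
  fn <- function(theta) {
    v <- ls$evaluate(theta)$value
    trace$values <- c(trace$values, v)
    v
  }
  gr <- function(theta) ls$evaluate(theta)$grad
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(
                        maxit = config$max_iterations,
                        factr = config$convergence_tol / .Machine$double.eps))
  metadata <- list(seed = config$seed,
                   n_tables = length(tables),
                   round_ids = vapply(tables, attr, integer(1), "round_id"),
                   constrained_central = config$constrained_central,
                   w_ns = config$w_ns,
                   loss = opt$value)
  model <- ls$build_model(opt$par, metadata)
  report <- list(loss_init = e0$value,
                 loss_final = opt$value,
                 trajectory = cummin(trace$values),
                 n_evaluations = length(trace$values),
                 convergence = opt$convergence,
                 message = opt$message)
  list(model = model, report = report)
}

#' Gauge-normalize an energy model
#'
#' Shifts every specific-mode column so that its maximum is zero and absorbs
#' the compensating factor `exp(sum of shifts)` into every round's specific
#' activity. All predicted enrichments are unchanged; the per-position-argmax
#' peptide then has relative affinity exactly 1. Idempotent.
#'
#' @param model an [energy_model()].
#' @return the normalized model (with `normalized = TRUE`).
#' @export
normalize_model <- function(model) {
  shifts <- apply(model$specific$coeffs, 1L, max)
  model$specific$coeffs <- model$specific$coeffs - shifts
  total <- sum(shifts)
  model$per_round <- lapply(model$per_round, function(rp) {
    rp$log_alpha_s <- rp$log_alpha_s + total
    rp
  })
  model$normalized <- TRUE
  model
}

#' Best-of-n-starts fitting
#'
#' Runs [fit()] from `n_starts` seeded initializations (seeds derived from
#' `config$seed`) and returns the run with the best final loss.
#'
#' @param tables count tables, as for [fit()].
#' @param config a [fit_config()].
#' @param n_starts number of starts (default 3).
#' @return as [fit()], with `report$per_start_losses` added.
#' @export
fit_multistart <- function(tables, config = fit_config(), n_starts = 3L) {
  stopifnot(n_starts >= 1L)
  runs <- vector("list", n_starts)
  losses <- rep(NA_real_, n_starts)
  for (i in seq_len(n_starts)) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1L) * 1009L
    runs[[i]] <- tryCatch(fit(tables, cfg), error = function(e) e)
    if (!inherits(runs[[i]], "error"))
      losses[i] <- runs[[i]]$report$loss_final
  }
  if (all(is.na(losses))) {
    msgs <- vapply(runs, conditionMessage, character(1))
    stop("all starts failed: ", paste(unique(msgs), collapse = "; "))
  }
  best <- runs[[which.min(losses)]]
  best$report$per_start_losses <- losses
  best
}

#' Gauge-aligned squared correlation between two specific-mode matrices
#'
#' Centers each position (row) of both coefficient tables over the unfrozen
#' cells, removing the per-column shift freedom that the activity weights
#' absorb, then returns the squared Pearson correlation over unfrozen cells.
#' Used to compare a fitted model against a simulation ground truth.
#'
#' @param fitted,truth [energy_model()] or `binding_mode` objects.
#' @return squared Pearson correlation.
#' @export
recovery_r2 <- function(fitted, truth) {
  get_mode <- function(x) if (inherits(x, "energy_model")) x$specific else x
  mf <- get_mode(fitted); mt <- get_mode(truth)
  if (!all(dim(mf$coeffs) == dim(mt$coeffs)))
    stop("models have different specific-mode shapes")
  free <- !(mf$frozen | mt$frozen)
  center <- function(m) {
    for (j in seq_len(nrow(m))) {
      idx <- free[j, ]
      if (any(idx)) m[j, idx] <- m[j, idx] - mean(m[j, idx])
    }
    m
  }
  a <- center(mf$coeffs)[free]
  b <- center(mt$coeffs)[free]
  stats::cor(a, b)^2
}
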