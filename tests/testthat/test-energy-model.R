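test_that("specific_sum counts offsets and matches the loop oracle", {
  d <- design_x5yx5()
  # all-zero coefficients, no flank overlap, w = L: single offset, exp(0)
  m0 <- binding_mode(11)
  expect_equal(specific_sum("ACDEFYIKLMN", m0, d), 1.0)
  # with f = 5 flank overlap there are L + 2f - w + 1 = 11 offsets
  mf <- binding_mode(11, flank_depth = 5)
  expect_equal(specific_sum("ACDEFYIKLMN", mf, d), 11.0)

  # random 3x20 table on a short design equals a hand-rolled window loop
  td <- tiny_design()
  withr::with_seed(4, {
    coeffs <- matrix(rnorm(60), 3, 20)
    mode <- binding_mode(3, coeffs, flank_depth = 0)
    for (pep in random_peptides(20, 5)) {
      expect_equal(specific_sum(pep, mode, td),
                   oracle_specific_sum(pep, coeffs, td$protein_flank_left,
                                       td$protein_flank_right, 0),
                   tolerance = 1e-12)
    }
  })
})

test_that("nonspecific_sum matches its printed offset bounds and oracle", {
  ns <- binding_mode(3)
  expect_equal(nonspecific_sum("ACDEFYIKLMN", ns, rep(0, 9)), 9.0)
  ns1 <- binding_mode(1)
  expect_equal(nonspecific_sum("ACDEFYIKLMN", ns1, rep(log(2), 11)), 22.0)
  withr::with_seed(9, {
    coeffs <- matrix(rnorm(60), 3, 20)
    gamma <- rnorm(9)
    mode <- binding_mode(3, coeffs, position_bias = gamma)
    for (pep in random_peptides(20, 11)) {
      expect_equal(nonspecific_sum(pep, mode),
                   oracle_nonspecific_sum(pep, coeffs, gamma),
                   tolerance = 1e-12)
    }
  })
})

test_that("enrichment is the activity-weighted sum of the two modes", {
  d <- design_x5yx5()
  model <- random_model(d, seed = 21)
  pep <- random_peptides(10, 11)
  rp <- model$per_round[[1]]

  zero_ns <- model
  zero_ns$per_round[[1]]$log_alpha_ns <- -Inf
  expect_equal(enrichment(pep, zero_ns),
               exp(rp$log_alpha_s) * specific_sum(pep, model$specific, d))

  zero_s <- random_model(d, seed = 22)
  zero_s$per_round[[1]]$log_alpha_s <- -Inf
  zero_s$nonspecific$coeffs[] <- 0
  zero_s$nonspecific$position_bias[] <- 0
  expect_equal(length(unique(enrichment(pep, zero_s))), 1L)

  for (p in pep[1:5]) {
    expect_equal(enrichment(p, model), oracle_kappa(p, model, 1),
                 tolerance = 1e-12)
  }
})

test_that("log_likelihood matches closed forms and the per-read oracle", {
  d <- tiny_design()
  # single sequence, counts (1, 1), rho*kappa = 1 -> log(1/2)
  tab <- count_table("AAAAA", 1, 1, d)
  m <- random_model(d, seed = 1, w_ns = 2L)
  kap <- enrichment("AAAAA", m)
  m$per_round[[1]]$depth_log_ratio <- -log(kap)   # rho*kappa = 1
  expect_equal(log_likelihood(tab, m), log(0.5), tolerance = 1e-12)

  # counts (k, 0): contribution vanishes as rho*kappa -> 0
  tab2 <- count_table("CCCCC", 7, 0, d)
  m2 <- m
  m2$per_round[[1]]$depth_log_ratio <- -40
  expect_lt(abs(log_likelihood(tab2, m2)), 1e-10)

  # brute-force per-read binomial evaluation on a random table
  tabr <- random_table(d, seed = 12, n = 8, max_count = 6)
  mr <- random_model(d, seed = 13, w_ns = 2L)
  expect_equal(log_likelihood(tabr, mr), oracle_log_likelihood(tabr, mr),
               tolerance = 1e-10)
})

test_that("log_likelihood is invariant to row and table order", {
  d <- tiny_design()
  t1 <- random_table(d, seed = 31, n = 12, round_id = 1L)
  t2 <- random_table(d, seed = 32, n = 15, round_id = 2L)
  m <- random_model(d, seed = 33, w_ns = 2L, n_rounds = 2L)
  base <- log_likelihood(list(t1, t2), m)

  perm <- withr::with_seed(5, sample(nrow(t1)))
  t1p <- count_table(t1$sequence[perm], t1$count_input[perm],
                     t1$count_bound[perm], d, 1L)
  expect_equal(log_likelihood(list(t1p, t2), m), base, tolerance = 1e-12)

  m_swapped <- m
  m_swapped$per_round <- m$per_round[c(2, 1)]
  expect_equal(log_likelihood(list(t2, t1), m_swapped), base,
               tolerance = 1e-12)
})

test_that("penalty implements L2, barrier, and Dirichlet terms", {
  d <- tiny_design()
  m <- random_model(d, seed = 41, w_ns = 2L)
  zero <- m
  zero$specific$coeffs[] <- 0
  zero$nonspecific$coeffs[] <- 0
  zero$nonspecific$position_bias[] <- 0
  cfg <- regularization_config(lambda_l2 = 1, barrier_weight = 0,
                               dirichlet_count = 0)
  expect_equal(penalty(zero, cfg), 0)

  # a single coefficient at the cap contributes exp(0) = 1 (plus the tiny
  # exp(-2B) mirror term), scaled by the weight
  one <- zero
  one$specific$coeffs[1, 1] <- 8
  cfgb <- regularization_config(lambda_l2 = 0, barrier_weight = 0.5,
                                barrier_cap = 8, dirichlet_count = 0)
  n_other <- length(slimfit:::free_coefficients(one)) - 1L
  expected <- 0.5 * (exp(0) + exp(-16) + n_other * 2 * exp(-8))
  expect_equal(penalty(one, cfgb), expected, tolerance = 1e-12)

  cfg0 <- regularization_config(lambda_l2 = 0, barrier_weight = 0,
                                dirichlet_count = 0)
  expect_equal(penalty(m, cfg0), 0)
  expect_error(regularization_config(lambda_l2 = -1), "non-negative")

  # Dirichlet term matches its definition on a small table
  tab <- random_table(d, seed = 42, n = 6)
  cfgd <- regularization_config(lambda_l2 = 0, barrier_weight = 0,
                                dirichlet_count = 5)
  rho <- exp(m$per_round[[1]]$depth_log_ratio)
  t_ <- rho * enrichment(tab$sequence, m)
  want <- -5 / nrow(tab) * sum(log(1 / (1 + t_)) + log(t_ / (1 + t_)))
  expect_equal(penalty(m, cfgd, tab), want, tolerance = 1e-12)
})

test_that("per-column gauge shifts are absorbed by the specific activity", {
  d <- design_x5yx5()
  m <- random_model(d, seed = 51)
  pep <- random_peptides(25, 11)
  kap <- enrichment(pep, m)
  shifted <- m
  shifted$specific$coeffs[4, ] <- shifted$specific$coeffs[4, ] + 1.3
  shifted$per_round[[1]]$log_alpha_s <-
    shifted$per_round[[1]]$log_alpha_s - 1.3
  expect_equal(enrichment(pep, shifted), kap, tolerance = 1e-10)
})

test_that("ddg and relative_affinity obey the max gauge", {
  d <- design_x5yx5()
  m <- normalize_model(random_model(d, seed = 61, constrained = TRUE))
  best <- paste(AA_ALPHABET[apply(m$specific$coeffs, 1, which.max)],
                collapse = "")
  expect_equal(ddg(best, m), 0)
  expect_equal(relative_affinity(best, m), 1.0)

  # one substitution away: affinity changes by exp(coefficient difference)
  sub <- best
  old <- substr(best, 2, 2)
  new <- setdiff(AA_ALPHABET, old)[1]
  substr(sub, 2, 2) <- new
  dd <- m$specific$coeffs[2, old] - m$specific$coeffs[2, new]
  expect_equal(relative_affinity(sub, m), exp(-dd), tolerance = 1e-12)

  withr::with_seed(6, {
    peps <- random_peptides(200, 11)
    expect_true(all(relative_affinity(peps, m) <= 1 + 1e-12))
    expect_true(all(relative_affinity(peps, m) > 0))
  })

  unnorm <- random_model(d, seed = 62)
  expect_error(ddg("ACDEFYIKLMN", unnorm), "normalize")
  expect_error(specific_sum("ACDEFYIKLMB", m$specific, d), "alphabet")
})

test_that("model JSON serialization round-trips bit-exactly", {
  d <- design_x5yx5()
  m <- random_model(d, seed = 71, constrained = TRUE, n_rounds = 3L)
  m$metadata <- list(domain = "synthetic", seed = 71L)
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_identical(back$specific$coeffs, m$specific$coeffs)
  expect_identical(back$nonspecific$coeffs, m$nonspecific$coeffs)
  expect_identical(back$nonspecific$position_bias,
                   m$nonspecific$position_bias)
  expect_identical(back$specific$frozen, m$specific$frozen)
  for (i in seq_along(m$per_round)) {
    expect_identical(back$per_round[[i]]$log_alpha_ns,
                     m$per_round[[i]]$log_alpha_ns)
    expect_identical(back$per_round[[i]]$depth_log_ratio,
                     m$per_round[[i]]$depth_log_ratio)
  }
  expect_equal(back$design$fixed_positions, d$fixed_positions)
})
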