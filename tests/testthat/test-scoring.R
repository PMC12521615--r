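norm_model <- function(seed = 201, constrained = TRUE) {
  normalize_model(random_model(design_x5yx5(), seed = seed,
                               constrained = constrained))
}

test_that("extract_window centers, pads, and rejects non-tyrosine sites", {
  m <- norm_model()
  prot <- paste(rep("ACDEFGHIKL", 20), collapse = "")   # 200-mer, no Y
  substr(prot, 100, 100) <- "Y"
  rec <- extract_window(prot, 100, m, protein_id = "P1")
  expect_equal(nchar(rec$window), 11L)
  expect_equal(substr(rec$window, 6, 6), "Y")
  expect_equal(rec$window, substr(prot, 95, 105))

  substr(prot, 3, 3) <- "Y"
  rec2 <- extract_window(prot, 3, m)
  expect_equal(substr(rec2$window, 1, 3), "---")
  expect_equal(substr(rec2$window, 6, 6), "Y")
  expect_null(extract_window(prot, 3, m, skip_truncated = TRUE))

  expect_null(extract_window(prot, 4, m))     # not a tyrosine
  expect_error(extract_window(prot, 999, m), "out of range")
})

test_that("score_sites ranks stably and honours the allow-list", {
  m <- norm_model()
  best <- paste(AA_ALPHABET[apply(m$specific$coeffs, 1, which.max)],
                collapse = "")
  wins <- c(best, withr::with_seed(8,
    random_peptides(99, 11, fixed = list("6" = "Y"))))
  recs <- data.frame(protein_id = paste0("P", seq_along(wins)),
                     site_position = seq_along(wins),
                     window = wins, stringsAsFactors = FALSE)
  ranked <- score_sites(recs, m)
  expect_equal(ranked$window[1], best)
  expect_equal(ranked$relative_affinity[1], 1.0)
  expect_equal(ranked$relative_affinity,
               sort(relative_affinity(wins, m), decreasing = TRUE))
  # scores equal a direct per-window computation, order preserved
  direct <- relative_affinity(ranked$window, m)
  expect_equal(ranked$relative_affinity, direct)

  expect_equal(nrow(score_sites(recs, m, allow_pairs = character())), 0L)
  sub <- score_sites(recs, m, allow_pairs = c("P1", "P7"))
  expect_setequal(sub$protein_id, c("P1", "P7"))

  # batch order invariance (stable sort contract)
  perm <- withr::with_seed(3, sample(nrow(recs)))
  ranked2 <- score_sites(recs[perm, ], m)
  expect_equal(ranked2$relative_affinity, ranked$relative_affinity)
})

test_that("variant_ratio follows single-substitution additivity", {
  m <- norm_model()
  wt <- withr::with_seed(9, random_peptides(1, 11, fixed = list("6" = "Y")))
  var <- wt
  old <- substr(wt, 3, 3)
  new <- setdiff(AA_ALPHABET, c(old, "A"))[5]
  substr(var, 3, 3) <- new
  res <- variant_ratio(wt, var, m)
  expect_equal(res$ratio,
               exp(m$specific$coeffs[3, new] - m$specific$coeffs[3, old]),
               tolerance = 1e-12)
  expect_equal(res$max_affinity, max(res$wt_affinity, res$var_affinity))

  expect_equal(variant_ratio(wt, wt, m)$ratio, 1.0)
  swapped <- variant_ratio(var, wt, m)
  expect_equal(res$ratio * swapped$ratio, 1, tolerance = 1e-12)

  bad <- wt; substr(bad, 6, 6) <- "F"
  expect_error(variant_ratio(wt, bad, m), "central tyrosine")
  twice <- var
  substr(twice, 9, 9) <- if (substr(var, 9, 9) == "A") "C" else "A"
  expect_error(variant_ratio(wt, twice, m),
               "more than one position")
})

test_that("truncate_model drops outer columns and preserves constraints", {
  m <- norm_model()
  t9 <- truncate_model(m, 4, 4)
  expect_equal(t9$specific$width, 9L)
  expect_equal(t9$specific$central, 5L)
  expect_true(all(t9$specific$frozen[5, ]))
  pep9 <- random_peptides(1, 9, fixed = list("5" = "Y"))
  # scoring a 9-mer equals the 9 central columns' contribution
  v <- vapply(1:9, function(j) {
    t9$specific$coeffs[j, substr(pep9, j, j)]
  }, numeric(1))
  expect_equal(ddg(pep9, t9), -sum(v), tolerance = 1e-12)

  ident <- truncate_model(m, 5, 5)
  expect_equal(ident$specific$coeffs, m$specific$coeffs)

  t1 <- truncate_model(m, 0, 0)
  expect_equal(t1$specific$width, 1L)
  expect_equal(relative_affinity("Y", t1), 1.0)

  expect_error(truncate_model(m, -1, 4), "central")
  expect_error(truncate_model(m, 6, 4), "more positions")
})

test_that("validate_against_kd regresses ln K_D on predicted energies", {
  ddg_pred <- c(0.5, 1.5, 2.5, 4.0, 6.0)
  kd <- exp(1.2 * ddg_pred - 3)
  res <- validate_against_kd(ddg_pred, kd)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$slope, 1.2, tolerance = 1e-10)
  expect_equal(res$intercept, -3, tolerance = 1e-10)

  # 3-point case against the normal equations
  x <- c(0, 1, 3); kd3 <- c(1, 4, 6)
  y <- log(kd3)
  b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
  res3 <- validate_against_kd(x, kd3)
  expect_equal(res3$slope, b, tolerance = 1e-12)
  expect_equal(res3$intercept, a, tolerance = 1e-12)
  expect_equal(res3$r_squared, cor(x, y)^2, tolerance = 1e-12)

  expect_error(validate_against_kd(c(1, 2, 3), c(1, -1, 2)), "positive")
  expect_error(validate_against_kd(c(1, 2), c(1, 2)), "at least 3")
})

test_that("sign_test is the exact one-sided binomial tail", {
  expect_equal(round(sign_test(7, 7), 4), 0.0078)
  expect_equal(sign_test(0, 0), 1.0)
  expect_equal(sign_test(2, 3), 0.5)    # 4 of 8 equally likely outcomes
  expect_equal(sign_test(0, 5), 1.0)
  expect_equal(sign_test(3, 10), sum(dbinom(3:10, 10, 0.5)),
               tolerance = 1e-12)
})

test_that("energy_logo centers heights and writes the numeric matrix", {
  m <- norm_model()
  out <- file.path(tempdir(), "logo.pdf")
  h <- energy_logo(m, out)
  expect_true(file.exists(out))
  tsv <- file.path(tempdir(), "logo.tsv")
  expect_true(file.exists(tsv))
  # per-position heights sum to zero over free cells; frozen rows are zero
  free_rows <- which(!apply(m$specific$frozen, 1, any))
  expect_true(all(abs(rowSums(h[free_rows, ])) < 1e-9))
  expect_true(all(h[6, ] == 0))
  got <- read.delim(tsv, check.names = FALSE)
  expect_equal(as.matrix(got[, -1]), unname(h), ignore_attr = TRUE)

  # constant column draws all letters at height zero
  flat <- matrix(1, 2, 20)
  h2 <- energy_logo(flat, file.path(tempdir(), "flat.pdf"))
  expect_true(all(h2 == 0))
})

test_that("cluster_models groups copies before strangers", {
  a <- random_model(design_x5yx5(), seed = 301, constrained = TRUE)
  b <- random_model(design_x5yx5(), seed = 302, constrained = TRUE)
  a2 <- a
  a2$specific$coeffs <- a$specific$coeffs +
    matrix(rnorm(220, 0, 0.05), 11, 20) * !a$specific$frozen
  hc <- cluster_models(list(srcA = a, srcA_rep = a2, other = b))
  merged_first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(merged_first, c("srcA", "srcA_rep"))

  # four models from two truths cluster by identity
  b2 <- b
  b2$specific$coeffs <- b$specific$coeffs +
    matrix(rnorm(220, 0, 0.05), 11, 20) * !b$specific$frozen
  hc4 <- cluster_models(list(a = a, b = b, a2 = a2, b2 = b2))
  groups <- cutree(hc4, k = 2)
  expect_equal(groups[["a"]], groups[["a2"]])
  expect_equal(groups[["b"]], groups[["b2"]])
  expect_true(groups[["a"]] != groups[["b"]])
})
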