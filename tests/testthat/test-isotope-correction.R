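test_that("a bare-carbon fragment needs no correction", {
  f <- fragment_formula(C = 3, n = 3)
  M <- build_correction_matrix(f, window = 3)
  expect_equal(unclass(M), diag(4), ignore_attr = TRUE)
})

test_that("one extra natural carbon gives the single-atom binomial column", {
  a <- isotope_abundances()$C[2]
  f <- fragment_formula(C = 4, n = 3)
  M <- build_correction_matrix(f, window = 4)
  expect_equal(unname(M[1:2, 1]), c(1 - a, a), tolerance = 1e-12)
  expect_equal(unname(M[2:3, 2]), c(1 - a, a), tolerance = 1e-12)
})

test_that("correction matrix columns match a polynomial-multiplication oracle", {
  f <- fragment_formula(C = 6, H = 15, O = 1, Si = 1, n = 3)
  M <- build_correction_matrix(f, window = 4)
  # independent oracle: expand the generating polynomial by brute force
  ab <- isotope_abundances()
  poly_mul <- function(p, q) {
    out <- numeric(length(p) + length(q) - 1)
    for (i in seq_along(p)) for (j in seq_along(q)) {
      out[i + j - 1] <- out[i + j - 1] + p[i] * q[j]
    }
    out
  }
  base <- 1
  for (i in seq_len(3)) base <- poly_mul(base, ab$C)   # 6 - 3 labeled carbons
  for (i in seq_len(15)) base <- poly_mul(base, ab$H)
  base <- poly_mul(base, ab$O)
  base <- poly_mul(base, ab$Si)
  for (j in 0:3) {
    col <- c(rep(0, j), base)[1:5]
    expect_equal(unname(M[, j + 1]), col, tolerance = 1e-12)
  }
  # untruncated columns sum to 1
  M_full <- build_correction_matrix(f, window = 40)
  expect_true(all(abs(colSums(M_full) - 1) < 1e-12))
})

test_that("correction inverts the forward model exactly for clean data", {
  f <- fragment_formula(C = 11, H = 25, O = 3, Si = 2, n = 3)
  M <- build_correction_matrix(f)
  raw <- drop(unclass(M) %*% c(1, 0, 0, 0))
  expect_equal(as.vector(correct_mid(raw, M)), c(1, 0, 0, 0), tolerance = 1e-10)
})

test_that("round trip recovers random MIDs across all study formulas", {
  set.seed(99)
  worst <- 0
  for (f in mef_fragment_formulas()) {
    M <- build_correction_matrix(f)
    for (i in 1:40) {
      x <- stats::rexp(f$n + 1)
      x <- x / sum(x)
      raw <- drop(unclass(M) %*% x)
      worst <- max(worst, max(abs(as.vector(correct_mid(raw, M)) - x)))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("noisy input still yields a valid MID and errors are informative", {
  f <- fragment_formula(C = 6, H = 12, N = 1, O = 3, Si = 1, n = 3)
  M <- build_correction_matrix(f)
  set.seed(5)
  raw <- pmax(drop(unclass(M) %*% c(0.6, 0.3, 0.1, 0)) +
                rnorm(nrow(M), 0, 0.01), 0)
  out <- correct_mid(raw, M)
  expect_true(all(out >= 0))
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_error(correct_mid(rep(0, nrow(M)), M), "all-zero")
  expect_error(correct_mid(raw[-1], M), "expects")
  expect_error(build_correction_matrix(f, window = 1), "at least")
})

test_that("the tabular corrector round-trips a small two-fragment table", {
  forms <- mef_fragment_formulas()[c("pyr", "lac")]
  set.seed(2)
  tab <- do.call(rbind, lapply(names(forms), function(fr) {
    f <- forms[[fr]]
    x <- stats::rexp(f$n + 1); x <- x / sum(x)
    M <- build_correction_matrix(f)
    data.frame(fragment = fr, mass_shift = 0:(nrow(M) - 1),
               intensity = drop(unclass(M) %*% x) * 5e6, true = c(x, rep(NA, nrow(M) - f$n - 1)))
  }))
  out <- correct_mid_table(tab[, 1:3], forms)
  merged <- merge(as.data.frame(out), tab, by = c("fragment", "mass_shift"))
  keep <- !is.na(merged$true)
  expect_lt(max(abs(merged$fraction[keep] - merged$true[keep])), 1e-8)
})
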