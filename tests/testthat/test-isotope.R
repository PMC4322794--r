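light_only <- function() {
  list(C = 1, H = 1, N = 1, O = 1, P = 1, S = 1)
}

test_that("formula parsing counts atoms and bounds tracer positions", {
  f <- elemental_formula("C3H4O3")
  expect_equal(f$counts[["C"]], 3)
  expect_equal(f$counts[["H"]], 4)
  expect_equal(f$counts[["O"]], 3)
  expect_equal(f$n_tracer, 3)
  expect_equal(elemental_formula("C6H12O6", n_tracer = 4)$n_tracer, 4)
  expect_error(elemental_formula("C2", n_tracer = 3), "exceeds")
  expect_error(elemental_formula("C2Xe3"), "unsupported",
               class = "reportermet_format_error")
  expect_error(elemental_formula("not a formula"),
               class = "reportermet_format_error")
})

test_that("correction matrix reduces to identity with light-only isotopes", {
  A <- correction_matrix(elemental_formula("C3H4O3"),
                         abundances = light_only())
  expect_equal(A, diag(4))
})

test_that("one tracer carbon with 13C abundance p gives the binomial matrix", {
  p <- 0.05
  ab <- light_only()
  ab$C <- c(1 - p, p)
  A <- correction_matrix(elemental_formula("C1", 1), abundances = ab)
  expect_equal(A, matrix(c(1 - p, p, 0, 1), 2, 2))
})

test_that("column sums are at most 1, deficit being truncated heavy mass", {
  A <- correction_matrix(elemental_formula("C6H12O6"))
  sums <- colSums(A)
  expect_true(all(sums <= 1 + 1e-12))
  # an unlabeled molecule can exceed M+6 only through >6 heavy atoms;
  # check the deficit equals the mass beyond the window explicitly for M+0
  ab <- natural_abundance()
  full <- 1
  for (e in c("C", "H", "O")) {
    m <- c(C = 6, H = 12, O = 6)[[e]]
    single <- ab[[e]]
    pw <- 1
    for (i in seq_len(m)) pw <- reportermet:::conv_pmf(pw, single)
    full <- reportermet:::conv_pmf(full, pw)
  }
  expect_equal(sums[[1]], sum(full[1:7]))
})

test_that("correcting a column of the matrix returns the unit vector", {
  f <- elemental_formula("C4H4O4")
  A <- correction_matrix(f)
  for (j in c(1, 3, 5)) {
    measured <- mid_vector(A[, j], f, "col")
    fit <- correct_mid(measured)
    truth <- numeric(5)
    truth[j] <- 1
    expect_equal(fit$corrected$fractions, truth, tolerance = 1e-8)
    expect_lt(fit$residual, 1e-10)
  }
})

test_that("convolve-then-correct is the identity on noise-free MIDs", {
  truth <- mid_vector(c(1, 0, 0), "C2H4O2", "x")
  fit <- correct_mid(convolve_mid(truth))
  expect_equal(fit$corrected$fractions, truth$fractions, tolerance = 1e-8)
  # light-only abundances make correction the identity
  measured <- mid_vector(c(0.2, 0.5, 0.3), "C2H4O2", "x")
  fit2 <- correct_mid(measured, abundances = light_only())
  expect_equal(fit2$corrected$fractions, measured$fractions,
               tolerance = 1e-12)
})

test_that("correction never produces negative fractions, flags bad fits", {
  withr::local_seed(5)
  f <- elemental_formula("C5H8NO4")
  for (i in 1:20) {
    truth <- mid_vector(runif(6), f)
    meas <- convolve_mid(truth)$fractions
    noisy <- pmax(meas * (1 + rnorm(6, 0, 0.05)), 0)
    fit <- suppressWarnings(correct_mid(mid_vector(noisy, f)))
    expect_true(all(fit$corrected$fractions >= 0))
  }
  # inconsistent measurement (M+0 mass with no natural M+1 shoulder):
  # flagged, not an error
  expect_warning(
    fit <- correct_mid(mid_vector(c(0.9, 0, 0, 0, 0, 0.1), "C5H8NO4")),
    "residual")
  expect_true(fit$flagged)
})

test_that("tracer purity below 1 shifts label mass down and round-trips", {
  f <- elemental_formula("C3", 3)
  A <- correction_matrix(f, purity = 0.99, abundances = light_only())
  # a fully labeled molecule at purity p: M+3 observed with prob p^3
  expect_equal(A[4, 4], 0.99^3)
  truth <- mid_vector(c(0.1, 0.2, 0.3, 0.4), f)
  fit <- correct_mid(convolve_mid(truth, purity = 0.99), purity = 0.99)
  expect_equal(fit$corrected$fractions, truth$fractions, tolerance = 1e-8)
})

test_that("carbon-only correction ignores the other elements", {
  f <- elemental_formula("C2H10S2")
  A <- correction_matrix(f, elements = "C")
  ab <- light_only()
  ab$C <- natural_abundance()$C
  expect_equal(A, correction_matrix(f, abundances = ab))
})

test_that("fractional labeling averages label positions", {
  expect_equal(fractional_labeling(mid_vector(c(1, 0, 0), "C2")), 0)
  expect_equal(fractional_labeling(mid_vector(c(0, 0, 1), "C2")), 1)
  expect_equal(fractional_labeling(mid_vector(c(0.5, 0.5), "C1")), 0.5)
})

test_that("batch correction preserves rows and reports malformed formulas", {
  mids <- sim_mids(sim_config(seed = 2))
  out <- correct_mid_table(mids)
  expect_equal(out$metabolite_id, mids$metabolite_id)
  expect_true(all(out$residual < 1e-8))
  bad <- mids
  bad$formula[2] <- "??"
  expect_error(correct_mid_table(bad), "row 2",
               class = "reportermet_format_error")
})
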