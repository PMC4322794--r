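#' Standard terrestrial natural isotope abundances
#'
#' Per-element vectors of isotope abundance by mass shift (+0, +1, +2 ...)
#' for the elements supported in fragment formulas. These are the defaults
#' used by [correction_matrix()] and can be edited by passing a modified
#' copy of this list.
#'
#' @return named list of numeric abundance vectors (each summing to 1)
#' @export
natural_abundance <- function() {
  list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    P = c(1.0),
    S = c(0.9499, 0.0075, 0.0425, 0.0001))
}

#' Parse an elemental formula for isotope correction
#'
#' @param formula a string such as `"C3H4O3"` (elements C, H, N, O, P, S)
#' @param n_tracer number of carbon positions eligible for the 13C tracer;
#'   defaults to the carbon count
#' @return an `elemental_formula`: list with integer `counts` and
#'   `n_tracer`
#' @examples
#' elemental_formula("C3H4O3")            # pyruvate fragment, 3 tracer carbons
#' elemental_formula("C6H12O6", n_tracer = 6)
#' @export
elemental_formula <- function(formula, n_tracer = NULL) {
  if (inherits(formula, "elemental_formula")) return(formula)
  stopifnot(is.character(formula), length(formula) == 1)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(tokens) || paste(tokens, collapse = "") != formula) {
    abort(sprintf("cannot parse formula '%s'.", formula),
          class = "reportermet_format_error")
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unsupported <- setdiff(elements, names(natural_abundance()))
  if (length(unsupported)) {
    abort(sprintf("unsupported element(s) in '%s': %s", formula,
                  paste(unsupported, collapse = ", ")),
          class = "reportermet_format_error")
  }
  counts <- tapply(counts, elements, sum)
  counts <- setNames(as.integer(counts), names(counts))
  n_c <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (is.null(n_tracer)) n_tracer <- n_c
  n_tracer <- assert_count(n_tracer, "n_tracer", min = 0)
  if (n_tracer > n_c) {
    abort(sprintf("n_tracer (%d) exceeds the carbon count (%d) of '%s'.",
                  n_tracer, n_c, formula))
  }
  structure(list(counts = counts, n_tracer = n_tracer, formula = formula),
            class = "elemental_formula")
}

#' Mass-isotopomer distribution vector
#'
#' Fractional abundances M+0 ... M+n of a metabolite fragment's mass shifts,
#' where n is the number of tracer-eligible carbon positions. Fractions are
#' renormalised to sum to 1 at construction.
#'
#' @param fractions numeric vector of length `n_tracer + 1`, non-negative
#' @param formula an [elemental_formula()] or formula string
#' @param metabolite_id identifier carried through corrections
#' @return a `mid_vector`
#' @export
mid_vector <- function(fractions, formula, metabolite_id = "metabolite") {
  formula <- elemental_formula(formula)
  fractions <- as.numeric(fractions)
  if (length(fractions) != formula$n_tracer + 1) {
    abort(sprintf(
      "expected %d fractions (M+0..M+%d) for '%s', got %d.",
      formula$n_tracer + 1, formula$n_tracer, formula$formula,
      length(fractions)))
  }
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    abort("MID fractions must be finite and non-negative.")
  }
  total <- sum(fractions)
  if (total <= 0) abort("MID fractions must not all be zero.")
  structure(list(fractions = fractions / total, formula = formula,
                 metabolite_id = metabolite_id),
            class = "mid_vector")
}

#' @export
print.mid_vector <- function(x, ...) {
  cat(sprintf("<mid_vector> %s (%s, %d tracer C): %s\n", x$metabolite_id,
              x$formula$formula, x$formula$n_tracer,
              paste(sprintf("M+%d=%.4f", seq_along(x$fractions) - 1,
                            x$fractions), collapse = " ")))
  invisible(x)
}

# replace abundances of elements outside `elements` by light-isotope-only
restrict_abundances <- function(abundances, elements) {
  if (is.null(elements)) return(abundances)
  for (e in setdiff(names(abundances), elements)) abundances[[e]] <- 1
  abundances
}

#' Natural-abundance correction matrix for a fragment
#'
#' Column `j + 1` is the expected measured mass-shift distribution
#' (truncated to M+0 ... M+n) of a molecule carrying exactly `j`
#' tracer-derived labels: the `j` labeled positions are 13C with probability
#' `purity` each, while every other atom — the remaining tracer-eligible
#' carbons, the non-tracer carbons, and all other elements — contributes
#' mass shifts at natural isotope abundance. Column sums may fall below 1;
#' the deficit is the probability mass beyond M+n lost to truncation.
#'
#' @param formula an [elemental_formula()] or formula string
#' @param abundances per-element isotope abundance vectors
#'   (default [natural_abundance()])
#' @param purity isotopic enrichment of the tracer (fraction of labeled
#'   positions actually 13C), default 1
#' @param elements correct only these elements (others treated as
#'   monoisotopic); `NULL` (default) corrects the full formula
#' @return numeric matrix of dimension `(n + 1) x (n + 1)`
#' @export
correction_matrix <- function(formula, abundances = natural_abundance(),
                              purity = 1, elements = NULL) {
  formula <- elemental_formula(formula)
  n <- formula$n_tracer
  if (n == 0) abort("formula has zero tracer positions; nothing to correct.")
  assert_scalar_number(purity, "purity")
  if (purity <= 0 || purity > 1) abort("`purity` must be in (0, 1].")
  abundances <- restrict_abundances(abundances, elements)
  for (e in names(abundances)) {
    a <- abundances[[e]]
    if (any(a < 0) || abs(sum(a) - 1) > 1e-6) {
      abort(sprintf("abundance vector for %s must be non-negative and sum to 1.", e))
    }
  }

  counts <- formula$counts
  # shift pmf of everything except the tracer-eligible carbons
  base <- 1
  for (e in names(counts)) {
    m <- counts[[e]] - if (e == "C") n else 0L
    if (m > 0) base <- conv_pmf(base, conv_pmf_power(abundances[[e]], m))
  }
  carbon <- abundances[["C"]]
  # powers of the single-carbon pmf for the unlabeled tracer positions
  cpow <- vector("list", n + 1)
  cpow[[1]] <- 1
  for (m in seq_len(n)) cpow[[m + 1]] <- conv_pmf(cpow[[m]], carbon)

  A <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    dist <- conv_pmf(base, cpow[[n - j + 1]])
    label_shift <- stats::dbinom(0:j, j, purity)
    dist <- conv_pmf(dist, label_shift)
    take <- seq_len(min(length(dist), n + 1))
    A[take, j + 1] <- dist[take]
  }
  A
}

#' Correct a measured MID for natural isotope abundance
#'
#' Solves `measured ~ A %*% corrected` by non-negative least squares, where
#' `A` is the fragment's [correction_matrix()], and renormalises the
#' corrected fractions to sum to 1. Non-negativity is enforced by the
#' solver, so noisy measurements never produce negative fractions (a plain
#' matrix inversion can). The residual norm of the fit is attached; when it
#' exceeds `warn_tol` the result is flagged rather than rejected.
#'
#' @param measured a [mid_vector()] of measured fractions
#' @param abundances,purity,elements passed to [correction_matrix()]
#' @param warn_tol residual norm above which the fit is flagged
#' @return a `mid_correction`: list with `corrected` (a [mid_vector()]),
#'   `measured`, `residual` and `flagged`
#' @export
correct_mid <- function(measured, abundances = natural_abundance(),
                        purity = 1, elements = NULL, warn_tol = 0.01) {
  stopifnot(inherits(measured, "mid_vector"))
  A <- correction_matrix(measured$formula, abundances, purity, elements)
  fit <- pracma::lsqnonneg(A, measured$fractions)
  x <- fit$x
  residual <- sqrt(sum((A %*% x - measured$fractions)^2))
  if (sum(x) <= 0) {
    abort("degenerate correction: all corrected fractions are zero.")
  }
  corrected <- mid_vector(x / sum(x), measured$formula,
                          measured$metabolite_id)
  flagged <- residual > warn_tol
  if (flagged) {
    warn(sprintf("correct_mid: residual norm %.3g exceeds %.3g for '%s'.",
                 residual, warn_tol, measured$metabolite_id))
  }
  structure(list(corrected = corrected, measured = measured,
                 residual = residual, flagged = flagged),
            class = "mid_correction")
}

#' @export
print.mid_correction <- function(x, ...) {
  cat(sprintf("<mid_correction> %s, residual %.3g%s\n",
              x$corrected$metabolite_id, x$residual,
              if (x$flagged) " [FLAGGED]" else ""))
  print(x$corrected)
  invisible(x)
}

#' Plot a MID correction
#'
#' Side-by-side bars of measured and natural-abundance-corrected
#' mass-isotopomer fractions.
#'
#' @param object a `mid_correction`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.mid_correction <- function(object, ...) {
  n <- length(object$measured$fractions)
  df <- tibble(
    isotopomer = factor(rep(paste0("M+", 0:(n - 1)), 2),
                        levels = paste0("M+", 0:(n - 1))),
    fraction = c(object$measured$fractions, object$corrected$fractions),
    which = rep(c("measured", "corrected"), each = n))
  ggplot2::ggplot(df, ggplot2::aes(.data$isotopomer, .data$fraction,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(title = object$corrected$metabolite_id, x = NULL,
                  y = "fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Forward natural-abundance convolution of a true MID
#'
#' Computes the measured distribution a mass spectrometer would observe for
#' a known tracer-labeling pattern: `A %*% truth`, renormalised. The inverse
#' operation is [correct_mid()]; the pair forms the round-trip used to
#' validate the correction.
#'
#' @param truth a [mid_vector()] of true labeling fractions
#' @inheritParams correct_mid
#' @return a [mid_vector()] of expected measured fractions
#' @export
convolve_mid <- function(truth, abundances = natural_abundance(),
                         purity = 1, elements = NULL) {
  stopifnot(inherits(truth, "mid_vector"))
  A <- correction_matrix(truth$formula, abundances, purity, elements)
  mid_vector(as.numeric(A %*% truth$fractions), truth$formula,
             truth$metabolite_id)
}

#' Fractional labeling of a MID
#'
#' The average fraction of tracer-eligible positions carrying a label:
#' `sum(i * fraction_i) / n`. Equals 0 for a fully unlabeled and 1 for a
#' fully labeled fragment.
#'
#' @param mid a [mid_vector()]
#' @return a number in `[0, 1]`
#' @export
fractional_labeling <- function(mid) {
  stopifnot(inherits(mid, "mid_vector"))
  n <- mid$formula$n_tracer
  if (n == 0) return(0)
  sum((seq_along(mid$fractions) - 1) * mid$fractions) / n
}

#' Batch-correct a table of measured MIDs
#'
#' Tidy interface over [correct_mid()]: one row per fragment with columns
#' `metabolite_id`, `formula`, optional `n_tracer`, and measured intensity
#' columns `M0`, `M1`, ... (trailing columns beyond a fragment's
#' `n_tracer + 1` slots may be `NA`). Intensities need not be normalised.
#'
#' @param mids tibble of measured MIDs
#' @inheritParams correct_mid
#' @return tibble mirroring the input with corrected fractions in the `M*`
#'   columns plus `residual`, `flagged` and `fractional_labeling`
#' @export
correct_mid_table <- function(mids, abundances = natural_abundance(),
                              purity = 1, elements = NULL,
                              warn_tol = 0.01) {
  mids <- as_tibble(mids)
  mcols <- grep("^M[0-9]+$", names(mids), value = TRUE)
  mcols <- mcols[order(as.integer(sub("^M", "", mcols)))]
  if (!all(c("metabolite_id", "formula") %in% names(mids)) || !length(mcols)) {
    abort("`mids` needs columns metabolite_id, formula and M0, M1, ...")
  }
  out <- purrr::map(seq_len(nrow(mids)), function(i) {
    row <- mids[i, ]
    nt <- if ("n_tracer" %in% names(row) && !is.na(row$n_tracer))
      as.integer(row$n_tracer) else NULL
    f <- tryCatch(elemental_formula(row$formula, nt), error = function(e) {
      abort(sprintf("row %d: %s", i, conditionMessage(e)),
            class = "reportermet_format_error")
    })
    vals <- as.numeric(row[mcols])[seq_len(f$n_tracer + 1)]
    if (any(is.na(vals))) {
      abort(sprintf("row %d ('%s'): missing intensity among M0..M%d.",
                    i, row$metabolite_id, f$n_tracer))
    }
    fit <- correct_mid(mid_vector(vals, f, row$metabolite_id), abundances,
                       purity, elements, warn_tol)
    corr <- rep(NA_real_, length(mcols))
    corr[seq_len(f$n_tracer + 1)] <- fit$corrected$fractions
    bind_cols(row[setdiff(names(row), mcols)],
              as_tibble(setNames(as.list(corr), mcols)),
              tibble(residual = fit$residual, flagged = fit$flagged,
                     fractional_labeling = fractional_labeling(fit$corrected)))
  })
  purrr::list_rbind(out)
}
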