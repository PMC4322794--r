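#' Filter an expression table on a minimum FPKM
#'
#' Lowly expressed genes make log-ratio statistics unstable, so genes below
#' an FPKM floor are discarded before computing fold changes (a floor of 5
#' is the pipeline default). `mode = "all"` keeps genes at or above the
#' threshold in every sample; `mode = "any"` keeps genes passing in at least
#' one sample.
#'
#' @param expr tibble: column `gene_id` plus one numeric FPKM column per
#'   sample
#' @param threshold FPKM floor (>= 0); 0 retains everything
#' @param mode `"all"` (default) or `"any"`
#' @param quiet suppress the retained-count message
#' @return the filtered tibble
#' @export
filter_expression <- function(expr, threshold = 5, mode = c("all", "any"),
                              quiet = FALSE) {
  mode <- match.arg(mode)
  expr <- as_tibble(expr)
  if (!"gene_id" %in% names(expr)) abort("`expr` must have a `gene_id` column.")
  if (anyDuplicated(expr$gene_id)) abort("`gene_id` values must be unique.")
  assert_scalar_number(threshold, "threshold")
  if (threshold < 0) abort("`threshold` must be >= 0.")
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0)) {
    abort("FPKM values must be finite and >= 0.")
  }
  keep <- if (mode == "all") rowSums(m >= threshold) == ncol(m)
          else rowSums(m >= threshold) >= 1
  if (!any(keep)) {
    abort(sprintf(
      "no genes pass FPKM >= %g in mode '%s'; lower the threshold.",
      threshold, mode))
  }
  if (!quiet) {
    inform(sprintf("filter_expression: %d of %d genes retained (FPKM >= %g, %s samples).",
                   sum(keep), nrow(expr), threshold,
                   if (mode == "all") "all" else "any"))
  }
  expr[keep, ]
}

#' Per-gene log2 fold change between two conditions
#'
#' The gene-level statistic of the reporter pipeline: log2 of the FPKM ratio
#' of condition `condition_b` over `condition_a`. When a condition has
#' replicate samples they are summarised by their arithmetic mean before the
#' ratio (with one profile per condition, the statistic is simply the log2
#' ratio of the two profiles).
#'
#' @param expr filtered expression tibble (see [filter_expression()])
#' @param design tibble with columns `sample`, `condition` assigning each
#'   expression column to a condition
#' @param condition_a,condition_b the contrast: `log2(mean_b / mean_a)`
#' @return tibble with columns `gene_id`, `log2fc`
#' @export
gene_log2fc <- function(expr, design, condition_a, condition_b) {
  expr <- as_tibble(expr)
  design <- as_tibble(design)
  if (!all(c("sample", "condition") %in% names(design))) {
    abort("`design` must have columns `sample` and `condition`.")
  }
  sa <- design$sample[design$condition == condition_a]
  sb <- design$sample[design$condition == condition_b]
  if (!length(sa) || !length(sb)) {
    abort(sprintf("conditions '%s' and '%s' must both appear in `design`.",
                  condition_a, condition_b))
  }
  missing <- setdiff(c(sa, sb), names(expr))
  if (length(missing)) {
    abort(sprintf("expression table lacks sample column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  mean_a <- rowMeans(as.matrix(expr[sa]))
  mean_b <- rowMeans(as.matrix(expr[sb]))
  zero <- which(mean_a <= 0 | mean_b <= 0)
  if (length(zero)) {
    abort(sprintf(
      "zero condition mean for gene '%s'; filter the table before computing ratios.",
      expr$gene_id[[zero[[1]]]]))
  }
  tibble(gene_id = expr$gene_id, log2fc = log2(mean_b / mean_a))
}
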