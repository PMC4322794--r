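#' Median gene-set statistic
#'
#' The set-level statistic of the pipeline: the median of the member genes'
#' statistics (for an even number of members, the mean of the two central
#' values). Members absent from the universe are ignored; their count is
#' attached as attribute `n_ignored`.
#'
#' @param stats tibble with columns `gene_id` and a numeric statistic
#'   (second column), e.g. the output of [gene_log2fc()]
#' @param members character vector of member gene ids
#' @return the median statistic (length-1 numeric, attribute `n_ignored`)
#' @export
gene_set_median <- function(stats, members) {
  v <- stat_vector(stats)
  present <- members[members %in% names(v)]
  if (!length(present)) {
    abort("no set member is present in the gene universe.")
  }
  out <- median(v[present])
  attr(out, "n_ignored") <- length(members) - length(present)
  out
}

# named statistic vector from a two-column tibble, validated
stat_vector <- function(stats) {
  stats <- as_tibble(stats)
  if (!"gene_id" %in% names(stats) || ncol(stats) < 2) {
    abort("`stats` must have a `gene_id` column and one statistic column.")
  }
  value_col <- setdiff(names(stats), "gene_id")[[1]]
  v <- stats[[value_col]]
  if (!is.numeric(v) || any(!is.finite(v))) {
    abort("gene statistics must be finite numbers.")
  }
  if (anyDuplicated(stats$gene_id)) abort("`gene_id` values must be unique.")
  setNames(v, stats$gene_id)
}

#' Directional gene-set analysis by gene permutation
#'
#' Scores every set of a collection with the median of its members' signed
#' statistics and computes permutation p-values for five directionality
#' classes. The null for a set of effective size `k` is the distribution of
#' medians of `k` genes drawn without replacement from the universe (a fresh
#' draw per permutation, i.e. gene-label permutation):
#'
#' * *distinct-directional up/down* — the observed median of signed
#'   statistics against the right/left tail of null medians of signed
#'   statistics; detects sets coordinately shifted as a whole.
#' * *mixed-directional up/down* — the median of the positive (negative)
#'   member statistics only, against medians of equal-count draws from the
#'   positive (negative) sub-universe; detects significant partial up- or
#'   down-regulation.
#' * *non-directional* — the median of absolute statistics against null
#'   medians of absolute statistics (right tail); detects regulation
#'   regardless of direction.
#'
#' p-values are estimated as `(b + 1) / (n_perm + 1)` where `b` counts null
#' values at least as extreme as the observed one (ties count as extreme, so
#' fully degenerate data yields p = 1, and p is never 0). With
#' `exhaustive = TRUE` all `choose(n, k)` subsets are enumerated instead and
#' the exact proportion is reported; this is only feasible for small
#' universes and is the oracle against which sampling is validated.
#' Benjamini-Hochberg adjustment is applied within each class across sets.
#'
#' Sets with no member in the universe are skipped and listed in the
#' `skipped` attribute of the result.
#'
#' @param stats tibble with columns `gene_id`, statistic
#'   (see [gene_log2fc()])
#' @param collection a [gene_set_collection()]
#' @param n_perm number of gene permutations (ignored when exhaustive)
#' @param seed integer seed governing the permutation draws
#' @param exhaustive enumerate all subsets instead of sampling
#' @param exhaustive_cap refuse enumeration when any `choose(n, k)` exceeds
#'   this
#' @param quiet suppress progress messages
#' @return a `gsa_result`: use [tidy()] for the per-set table, [glance()]
#'   for a one-row summary, [write_gsa_table()] to export
#' @export
run_gsa <- function(stats, collection, n_perm = 10000, seed = 1L,
                    exhaustive = FALSE, exhaustive_cap = 2e6,
                    quiet = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  assert_count(n_perm, "n_perm", min = 1)
  assert_count(seed, "seed", min = -.Machine$integer.max)
  s <- stat_vector(stats)
  universe <- names(s)

  members <- lapply(collection$genes, function(g) intersect(g, universe))
  k_all <- lengths(members)
  skipped <- tibble(set_id = collection$set_id[k_all == 0],
                    reason = "no member in gene universe")
  if (nrow(skipped) > 0 && !quiet) {
    inform(sprintf("run_gsa: %d set(s) skipped (no member in universe).",
                   nrow(skipped)))
  }
  keep <- which(k_all > 0)
  coll <- collection[keep, ]
  members <- members[keep]
  k_all <- k_all[keep]

  pos <- s[s > 0]
  neg <- s[s < 0]

  obs <- purrr::map(members, function(m) {
    v <- s[m]
    up <- v[v > 0]
    dn <- v[v < 0]
    list(med = median(v),
         med_up = if (length(up)) median(up) else NA_real_,
         med_dn = if (length(dn)) median(dn) else NA_real_,
         med_abs = median(abs(v)),
         k_up = length(up), k_dn = length(dn))
  })
  k_up_all <- vapply(obs, `[[`, integer(1), "k_up")
  k_dn_all <- vapply(obs, `[[`, integer(1), "k_dn")

  if (exhaustive) {
    nulls <- exhaustive_nulls(s, pos, neg, k_all, k_up_all, k_dn_all,
                              exhaustive_cap)
    p_fun <- function(null, observed, tail) {
      if (is.null(null) || is.na(observed)) return(NA_real_)
      b <- if (tail == "right") sum(null >= observed) else sum(null <= observed)
      b / length(null)
    }
  } else {
    nulls <- sampled_nulls(s, pos, neg, k_all, k_up_all, k_dn_all,
                           n_perm, seed)
    p_fun <- function(null, observed, tail) {
      if (is.null(null) || is.na(observed)) return(NA_real_)
      b <- if (tail == "right") sum(null >= observed) else sum(null <= observed)
      (b + 1) / (length(null) + 1)
    }
  }

  res <- purrr::map2(obs, seq_along(obs), function(o, i) {
    k <- k_all[[i]]
    tibble(
      stat_median = o$med,
      stat_median_up = o$med_up,
      stat_median_down = o$med_dn,
      stat_median_abs = o$med_abs,
      n_up = o$k_up, n_down = o$k_dn,
      p_distinct_up = p_fun(nulls$signed[[as.character(k)]], o$med, "right"),
      p_distinct_down = p_fun(nulls$signed[[as.character(k)]], o$med, "left"),
      p_mixed_up = if (o$k_up > 0)
        p_fun(nulls$up[[as.character(o$k_up)]], o$med_up, "right")
        else NA_real_,
      p_mixed_down = if (o$k_dn > 0)
        p_fun(nulls$down[[as.character(o$k_dn)]], o$med_dn, "left")
        else NA_real_,
      p_nondirectional = p_fun(nulls$absolute[[as.character(k)]], o$med_abs,
                               "right"))
  }) |> purrr::list_rbind()

  result <- bind_cols(
    tibble(set_id = coll$set_id, name = coll$name,
           provenance = coll$provenance, n_genes = coll$n_genes,
           n_universe = k_all, n_outside = coll$n_genes - k_all),
    res)
  for (cls in c("p_distinct_up", "p_distinct_down", "p_mixed_up",
                "p_mixed_down", "p_nondirectional")) {
    result[[sub("^p_", "padj_", cls)]] <- p.adjust(result[[cls]],
                                                   method = "BH")
  }

  structure(
    list(result = result, skipped = skipped,
         n_perm = if (exhaustive) NA_integer_ else as.integer(n_perm),
         seed = as.integer(seed), exhaustive = exhaustive,
         universe_size = length(s),
         n_universe_up = length(pos), n_universe_down = length(neg)),
    class = "gsa_result")
}

# Sampled permutation nulls, cached per draw size. RNG consumption order is
# fixed (signed/absolute nulls for all sizes first, then positive-subset,
# then negative-subset nulls) so that the distinct-directional and
# non-directional nulls are identical across runs that differ only in the
# sign structure of the statistics.
sampled_nulls <- function(s, pos, neg, k_all, k_up_all, k_dn_all,
                          n_perm, seed) {
  set.seed(as.integer(seed))
  signed <- list()
  absolute <- list()
  for (k in sort(unique(k_all))) {
    m <- perm_null_medians_signed_abs(unname(s), as.integer(k),
                                      as.integer(n_perm))
    signed[[as.character(k)]] <- m[, 1]
    absolute[[as.character(k)]] <- m[, 2]
  }
  up <- list()
  for (k in sort(unique(k_up_all[k_up_all > 0]))) {
    up[[as.character(k)]] <- perm_null_medians(unname(pos), as.integer(k),
                                               as.integer(n_perm))
  }
  down <- list()
  for (k in sort(unique(k_dn_all[k_dn_all > 0]))) {
    down[[as.character(k)]] <- perm_null_medians(unname(neg), as.integer(k),
                                                 as.integer(n_perm))
  }
  list(signed = signed, absolute = absolute, up = up, down = down)
}

# Exact nulls by enumeration of all k-subsets (the sampling oracle).
exhaustive_nulls <- function(s, pos, neg, k_all, k_up_all, k_dn_all, cap) {
  enum <- function(v, k) {
    if (choose(length(v), k) > cap) {
      abort(sprintf(
        "exhaustive enumeration of choose(%d, %d) subsets exceeds the cap (%g).",
        length(v), k, cap))
    }
    utils::combn(length(v), k, FUN = function(ix) median(v[ix]))
  }
  signed <- list(); absolute <- list()
  for (k in sort(unique(k_all))) {
    signed[[as.character(k)]] <- enum(unname(s), k)
    absolute[[as.character(k)]] <- enum(abs(unname(s)), k)
  }
  up <- list()
  for (k in sort(unique(k_up_all[k_up_all > 0]))) {
    up[[as.character(k)]] <- enum(unname(pos), k)
  }
  down <- list()
  for (k in sort(unique(k_dn_all[k_dn_all > 0]))) {
    down[[as.character(k)]] <- enum(unname(neg), k)
  }
  list(signed = signed, absolute = absolute, up = up, down = down)
}

#' @export
print.gsa_result <- function(x, ...) {
  cat(sprintf(
    "<gsa_result> %d sets scored over %d genes (%s), seed %d\n",
    nrow(x$result), x$universe_size,
    if (x$exhaustive) "exhaustive enumeration"
    else sprintf("%d permutations", x$n_perm),
    x$seed))
  top <- x$result |> arrange(.data$p_distinct_up, .data$set_id) |> head(5)
  print(top[, c("set_id", "n_universe", "stat_median", "p_distinct_up",
                "p_distinct_down", "p_nondirectional")])
  invisible(x)
}

#' Tidy a gene-set analysis result
#'
#' @param x a `gsa_result` from [run_gsa()]
#' @param ... unused
#' @return the per-set tibble (one row per scored set, all statistics,
#'   p-values and BH-adjusted p-values)
#' @export
tidy.gsa_result <- function(x, ...) x$result

#' One-row summary of a gene-set analysis
#'
#' @param x a `gsa_result`
#' @param ... unused
#' @return a one-row tibble: numbers of sets scored and skipped, universe
#'   size and sign split, permutation settings, and the smallest
#'   distinct-directional p-value
#' @export
glance.gsa_result <- function(x, ...) {
  tibble(
    n_sets = nrow(x$result),
    n_skipped = nrow(x$skipped),
    universe_size = x$universe_size,
    n_universe_up = x$n_universe_up,
    n_universe_down = x$n_universe_down,
    n_perm = x$n_perm,
    seed = x$seed,
    exhaustive = x$exhaustive,
    min_p_distinct = suppressWarnings(min(x$result$p_distinct_up,
                                          x$result$p_distinct_down,
                                          na.rm = TRUE)))
}

#' Plot the top gene sets of a GSA result
#'
#' Lollipop chart of `-log10` distinct-directional p-values for the
#' strongest sets, signed by direction of regulation (up positive, down
#' negative).
#'
#' @param object a `gsa_result`
#' @param n_top number of sets shown
#' @param alpha significance level drawn as a reference line
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.gsa_result <- function(object, n_top = 20, alpha = 0.005, ...) {
  df <- object$result |>
    mutate(p_best = pmin(.data$p_distinct_up, .data$p_distinct_down),
           direction = ifelse(.data$p_distinct_up <= .data$p_distinct_down,
                              "up", "down"),
           signed_score = ifelse(.data$direction == "up", 1, -1) *
             -log10(.data$p_best)) |>
    arrange(.data$p_best, .data$set_id) |>
    head(n_top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$name, abs(.data$signed_score)),
    y = .data$signed_score, colour = .data$direction)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$name, yend = 0)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * -log10(alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(signed ~ -log[10] ~ p),
                  colour = "direction",
                  title = "Top gene sets (distinct-directional)") +
    ggplot2::theme_minimal()
}

#' Write a GSA result table to TSV
#'
#' One row per scored set with all statistics, p-values, adjusted p-values
#' and set sizes, ordered by `p_distinct_up` with `set_id` breaking ties, so
#' repeated runs with the same seed produce byte-identical files.
#'
#' @param x a `gsa_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gsa_table <- function(x, path) {
  stopifnot(inherits(x, "gsa_result"))
  out <- x$result |> arrange(.data$p_distinct_up, .data$set_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
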