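#' Read a pipeline configuration file
#'
#' Configurations are YAML mappings; every key has a counterpart argument in
#' [run_reporter_pipeline()], [run_mid_correction()] or [run_rates()].
#' Passing a list directly to those functions is equivalent.
#'
#' @param path YAML file
#' @return named list
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)

default_pipeline_config <- function() {
  list(threshold = 5, filter_mode = "all", n_perm = 10000, seed = 1,
       min_size = 5, max_size = 500, blacklist = character(),
       collapse_compartments = FALSE,
       condition_a = "A", condition_b = "B",
       sig_metabolite = 0.005, sig_go = 0.05)
}

config_merge <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  modifyList(default_pipeline_config(), config)
}

file_digests <- function(paths) {
  paths <- unlist(paths)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  existing <- paths[file.exists(paths)]
  as.list(tools::md5sum(existing))
}

run_stage <- function(stage, cleanup, code) {
  tryCatch(force(code), error = function(e) {
    for (f in cleanup()) if (file.exists(f)) unlink(f)
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "reportermet_pipeline_error")
  })
}

#' Run the reporter-metabolite analysis pipeline
#'
#' Orchestrates the full analysis: read and filter the expression table,
#' compute per-gene log2 fold changes, build metabolite and pathway gene
#' sets from the network (plus any GMT collections, e.g. GO terms),
#' optionally translate sets through an ortholog map, score each collection
#' independently by permutation GSA, and write one result table per
#' collection together with a JSON run manifest (config snapshot, input
#' digests, per-stage counts, output paths). Reruns with the same inputs
#' and seed produce byte-identical result tables.
#'
#' Config keys: `expression`, `design` (TSV paths or tibbles), `network`
#' (path or [metabolic_network()]), `gmt` (named list of GMT paths),
#' `ortholog_map` (optional path or tibble), `condition_a`, `condition_b`,
#' `threshold`, `filter_mode`, `n_perm`, `seed`, `min_size`, `max_size`,
#' `blacklist`, `collapse_compartments`, `out_dir`.
#'
#' @param config a named list or a YAML path (see
#'   [read_pipeline_config()])
#' @param quiet suppress stage messages
#' @return invisibly, a list with `results` (named `gsa_result`s),
#'   `tables` (output paths) and `manifest`
#' @export
run_reporter_pipeline <- function(config, quiet = FALSE) {
  cfg <- config_merge(config)
  if (is.null(cfg$out_dir)) abort("config must name `out_dir`.")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  made <- character()
  cleanup <- function() made

  say <- function(...) if (!quiet) inform(sprintf(...))

  expr <- run_stage("read-expression", cleanup, {
    if (is.character(cfg$expression))
      readr::read_tsv(cfg$expression, col_types = readr::cols(
        gene_id = "c", .default = "d"), progress = FALSE)
    else as_tibble(cfg$expression)
  })
  design <- run_stage("read-design", cleanup, {
    if (is.character(cfg$design))
      readr::read_tsv(cfg$design, col_types = "cc", progress = FALSE)
    else as_tibble(cfg$design)
  })
  n_before <- nrow(expr)
  expr <- run_stage("filter", cleanup,
    filter_expression(expr, cfg$threshold, cfg$filter_mode, quiet = TRUE))
  say("filter: %d of %d genes retained (FPKM >= %g).", nrow(expr), n_before,
      cfg$threshold)
  stats <- run_stage("log2fc", cleanup,
    gene_log2fc(expr, design, cfg$condition_a, cfg$condition_b))

  collections <- run_stage("build-sets", cleanup, {
    out <- list()
    if (!is.null(cfg$network)) {
      network <- if (inherits(cfg$network, "metabolic_network")) cfg$network
                 else parse_network(cfg$network)
      out$metabolite <- build_metabolite_gene_sets(
        network, cfg$min_size, cfg$max_size, cfg$blacklist %||% character(),
        isTRUE(cfg$collapse_compartments))
      out$pathway <- build_pathway_gene_sets(network, cfg$min_size, Inf)
    }
    for (nm in names(cfg$gmt %||% list())) {
      out[[nm]] <- read_gmt(cfg$gmt[[nm]], provenance = nm)
    }
    if (!length(out)) abort("config names neither `network` nor `gmt` inputs.")
    out
  })
  if (!is.null(cfg$ortholog_map)) {
    collections <- run_stage("ortholog-map", cleanup, {
      map <- if (is.character(cfg$ortholog_map))
        read_ortholog_map(cfg$ortholog_map) else as_tibble(cfg$ortholog_map)
      lapply(collections, map_gene_sets, map = map)
    })
  }
  for (nm in names(collections)) {
    say("build-sets: %d %s set(s).", nrow(collections[[nm]]), nm)
  }

  results <- list()
  tables <- list()
  counts <- list()
  for (nm in names(collections)) {
    results[[nm]] <- run_stage(paste0("gsa-", nm), cleanup,
      run_gsa(stats, collections[[nm]], n_perm = cfg$n_perm,
              seed = cfg$seed, quiet = TRUE))
    path <- file.path(cfg$out_dir, sprintf("gsa_%s.tsv", nm))
    made <- c(made, path)
    run_stage(paste0("write-", nm), cleanup,
              write_gsa_table(results[[nm]], path))
    tables[[nm]] <- path
    counts[[nm]] <- list(built = nrow(collections[[nm]]),
                         scored = nrow(results[[nm]]$result),
                         skipped = nrow(results[[nm]]$skipped))
    say("gsa-%s: %d set(s) scored, %d skipped.", nm,
        counts[[nm]]$scored, counts[[nm]]$skipped)
  }

  manifest <- list(
    tool = "reportermet",
    version = as.character(packageVersion("reportermet")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("expression", "design", "network"))],
    inputs = file_digests(cfg[c("expression", "design", "network",
                                "ortholog_map")] |>
                            c(cfg$gmt %||% list())),
    genes_before_filter = n_before,
    genes_after_filter = nrow(expr),
    sets = counts,
    outputs = tables)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(results = results, tables = tables, manifest = manifest,
                 manifest_path = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch natural-abundance correction of a MID CSV
#'
#' Reads a CSV of measured mass-isotopomer intensities (columns
#' `metabolite_id`, `formula`, optional `n_tracer`, `M0`, `M1`, ...),
#' corrects every row with [correct_mid()] and writes the corrected
#' fractions, residual norms and fractional labeling next to the input
#' identifiers, preserving row order. An empty input produces a header-only
#' output with a warning.
#'
#' Config keys: `mids` (input CSV), `out_dir`, plus optional `purity`,
#' `elements`, `warn_tol`.
#'
#' @inheritParams run_reporter_pipeline
#' @return invisibly, the corrected tibble (with attribute `path`)
#' @export
run_mid_correction <- function(config, quiet = FALSE) {
  cfg <- config_merge(config)
  if (is.null(cfg$mids) || is.null(cfg$out_dir)) {
    abort("config must name `mids` and `out_dir`.")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  mids <- if (is.character(cfg$mids))
    readr::read_csv(cfg$mids, col_types = readr::cols(
      metabolite_id = "c", formula = "c", .default = "d"),
      progress = FALSE)
  else as_tibble(cfg$mids)
  path <- file.path(cfg$out_dir, "mids_corrected.csv")
  if (nrow(mids) == 0) {
    warn("run_mid_correction: empty input; writing header-only output.")
    out <- bind_cols(mids, tibble(residual = numeric(),
                                  flagged = logical(),
                                  fractional_labeling = numeric()))
  } else {
    out <- correct_mid_table(mids, purity = cfg$purity %||% 1,
                             elements = cfg$elements,
                             warn_tol = cfg$warn_tol %||% 0.01)
  }
  readr::write_csv(out, path, progress = FALSE, na = "")
  if (!quiet) inform(sprintf("run_mid_correction: %d row(s) -> %s",
                             nrow(out), path))
  attr(out, "path") <- path
  invisible(out)
}

#' Batch exchange-rate, OCR and SDH calculations
#'
#' Computes whichever of the three rate outputs the config names inputs
#' for: per-metabolite exchange rates from a growth-course CSV
#' (`metabolite_id`, `t_hours`, `cell_count`, `metabolite_nmol`),
#' respiratory parameters from an OCR CSV (`phase`, `ocr`), and SDH
#' activities from an assay CSV (`B`, `delta_t_min`, `volume_ul`,
#' optional `dilution`). One TSV per computed output.
#'
#' Config keys: `growth`, `ocr`, `sdh` (CSV paths or tibbles), `out_dir`,
#' optional `blank_correct`.
#'
#' @inheritParams run_reporter_pipeline
#' @return invisibly, a named list of result tibbles (attribute `paths`)
#' @export
run_rates <- function(config, quiet = FALSE) {
  cfg <- config_merge(config)
  if (is.null(cfg$out_dir)) abort("config must name `out_dir`.")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  read_in <- function(x, ct) {
    if (is.character(x)) readr::read_csv(x, col_types = ct, progress = FALSE)
    else as_tibble(x)
  }
  out <- list()
  paths <- list()
  if (!is.null(cfg$growth)) {
    growth <- read_in(cfg$growth, readr::cols(metabolite_id = "c",
                                              .default = "d"))
    out$exchange_rates <- growth |>
      group_by(metabolite_id = .data$metabolite_id) |>
      group_modify(~ tibble(alpha = exchange_rate(
        .x, blank_correct = isTRUE(cfg$blank_correct)))) |>
      ungroup()
    paths$exchange_rates <- file.path(cfg$out_dir, "exchange_rates.tsv")
    readr::write_tsv(out$exchange_rates, paths$exchange_rates,
                     progress = FALSE)
  }
  if (!is.null(cfg$ocr)) {
    trace <- read_in(cfg$ocr, readr::cols(phase = "c", .default = "d"))
    out$respiratory <- respiratory_params(trace)
    paths$respiratory <- file.path(cfg$out_dir, "respiratory_params.tsv")
    readr::write_tsv(out$respiratory, paths$respiratory, progress = FALSE)
  }
  if (!is.null(cfg$sdh)) {
    sdh <- read_in(cfg$sdh, readr::cols(.default = "d"))
    if (!"dilution" %in% names(sdh)) sdh$dilution <- 1
    out$sdh <- sdh |>
      mutate(activity = sdh_activity(.data$B, .data$delta_t_min,
                                     .data$volume_ul, .data$dilution))
    paths$sdh <- file.path(cfg$out_dir, "sdh_activity.tsv")
    readr::write_tsv(out$sdh, paths$sdh, progress = FALSE)
  }
  if (!length(out)) abort("config names none of `growth`, `ocr`, `sdh`.")
  if (!quiet) inform(sprintf("run_rates: wrote %s",
                             paste(unlist(paths), collapse = ", ")))
  attr(out, "paths") <- paths
  invisible(out)
}
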