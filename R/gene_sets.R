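#' Gene-set collections
#'
#' A gene-set collection is a tibble with one row per set and columns
#' `set_id`, `name` (display name), `provenance` (one of `"metabolite"`,
#' `"pathway"`, `"go"`, or `"custom"`), `genes` (list-column of character
#' member vectors) and `n_genes`. Members within a set are unique and empty
#' sets are removed at construction.
#'
#' @param sets tibble (or data frame) with at least `set_id` and `genes`
#' @param provenance default provenance for rows lacking one
#' @return a `gene_set_collection` (a tibble subclass)
#' @export
gene_set_collection <- function(sets, provenance = "custom") {
  sets <- as_tibble(sets)
  if (!all(c("set_id", "genes") %in% names(sets))) {
    abort("`sets` must have columns `set_id` and `genes`.")
  }
  if (!"name" %in% names(sets)) sets$name <- sets$set_id
  if (!"provenance" %in% names(sets)) sets$provenance <- provenance
  if (anyDuplicated(sets$set_id)) abort("duplicate `set_id` in collection.")
  sets$genes <- lapply(sets$genes, function(g) unique(as.character(g)))
  sets$n_genes <- lengths(sets$genes)
  sets <- sets[sets$n_genes > 0,
               c("set_id", "name", "provenance", "genes", "n_genes")]
  class(sets) <- c("gene_set_collection", class(tibble()))
  sets
}

size_filter <- function(collection, min_size, max_size) {
  keep <- collection$n_genes >= min_size &
    (is.infinite(max_size) | collection$n_genes <= max_size)
  collection[keep, ]
}

#' Build metabolite gene sets from a metabolic network
#'
#' For each metabolite, all genes associated with reactions in which the
#' metabolite takes part (in any role) are grouped into a gene set. A
#' significant set in the downstream analysis marks its metabolite as a
#' reporter metabolite: a hotspot of coordinated transcriptional change in
#' the network.
#'
#' Compartmentalised networks yield one candidate set per (metabolite,
#' compartment) by default; `collapse_compartments = TRUE` merges sets by
#' metabolite name instead. Currency metabolites (water, protons, cofactors)
#' produce very large uninformative sets; cap them with `max_size` or list
#' them in `blacklist`.
#'
#' @param network a [metabolic_network()]
#' @param min_size,max_size retain sets with `min_size <= n <= max_size`
#'   members (`max_size = Inf` disables the cap)
#' @param blacklist metabolite ids (or names, when collapsing) to exclude
#' @param collapse_compartments merge compartmentalised metabolites by name
#' @return a [gene_set_collection()] with provenance `"metabolite"`
#' @export
build_metabolite_gene_sets <- function(network, min_size = 5, max_size = 500,
                                       blacklist = character(),
                                       collapse_compartments = FALSE) {
  stopifnot(inherits(network, "metabolic_network"))
  assert_count(min_size, "min_size", min = 1)
  if (!identical(max_size, Inf)) assert_count(max_size, "max_size", min = 1)

  rx <- network$reactions
  if (nrow(rx) == 0) {
    return(gene_set_collection(
      tibble(set_id = character(), genes = list()), "metabolite"))
  }
  long <- tibble(
    metabolite_id = unlist(rx$metabolites),
    genes = rep(rx$genes, lengths(rx$metabolites)))
  key <- network$metabolites
  long <- left_join(long, key, by = "metabolite_id")
  if (collapse_compartments) {
    long$set_id <- long$name
    long$display <- long$name
  } else {
    long$set_id <- long$metabolite_id
    long$display <- ifelse(
      is.na(long$compartment_id), long$name,
      paste0(long$name, " [", long$compartment_id, "]"))
  }
  sets <- long |>
    group_by(set_id = .data$set_id) |>
    summarise(name = .data$display[[1]],
              genes = list(unique(unlist(.data$genes))),
              .groups = "drop") |>
    arrange(.data$set_id)
  sets$genes <- lapply(sets$genes, function(g) if (is.null(g)) character() else g)
  out <- gene_set_collection(sets, "metabolite")
  out <- out[!(out$set_id %in% blacklist), ]
  size_filter(out, min_size, max_size)
}

#' Build pathway gene sets from a metabolic network
#'
#' One set per distinct pathway annotation: the union of genes of the
#' reactions belonging to that pathway. Reactions without a pathway
#' annotation are ignored. Pathways are not a partition of the gene space; a
#' gene catalysing reactions in two pathways appears in both sets.
#'
#' @inheritParams build_metabolite_gene_sets
#' @return a [gene_set_collection()] with provenance `"pathway"`
#' @export
build_pathway_gene_sets <- function(network, min_size = 5, max_size = Inf) {
  stopifnot(inherits(network, "metabolic_network"))
  rx <- network$reactions
  rx <- rx[!is.na(rx$pathway) & nzchar(rx$pathway), ]
  if (nrow(rx) == 0) {
    return(gene_set_collection(
      tibble(set_id = character(), genes = list()), "pathway"))
  }
  sets <- rx |>
    group_by(set_id = .data$pathway) |>
    summarise(genes = list(unique(unlist(.data$genes))), .groups = "drop") |>
    arrange(.data$set_id)
  sets$genes <- lapply(sets$genes, function(g) if (is.null(g)) character() else g)
  size_filter(gene_set_collection(sets, "pathway"), min_size, max_size)
}

#' Translate a gene-set collection through an ortholog map
#'
#' Replaces every member by all of its targets in the map (one-to-many
#' mappings expand the set, many-to-one mappings merge with deduplication).
#' Typical use: translating human-network gene sets to mouse identifiers to
#' match a mouse expression table.
#'
#' @param collection a [gene_set_collection()]
#' @param map tibble with columns `source`, `target`
#'   (see [read_ortholog_map()])
#' @param drop_unmapped drop members absent from the map (default); if
#'   `FALSE` they are retained verbatim
#' @return a [gene_set_collection()]; sets emptied by the mapping are removed
#' @export
map_gene_sets <- function(collection, map, drop_unmapped = TRUE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  map <- distinct(as_tibble(map))
  if (!all(c("source", "target") %in% names(map))) {
    abort("`map` must have columns `source` and `target`.")
  }
  targets <- split(map$target, map$source)
  collection$genes <- lapply(collection$genes, function(g) {
    mapped <- lapply(g, function(gene) {
      hit <- targets[[gene]]
      if (!is.null(hit)) hit
      else if (drop_unmapped) character()
      else gene
    })
    unique(unlist(mapped))
  })
  gene_set_collection(
    collection[, c("set_id", "name", "provenance", "genes")])
}

#' Read and write gene-set collections in GMT format
#'
#' GMT holds one set per line: `set_id TAB description TAB member TAB
#' member ...`. Writing then reading a collection reproduces it exactly
#' (set order and member order preserved). Duplicated members on a line are
#' deduplicated with a warning.
#'
#' @param path file path
#' @param provenance provenance tag given to the sets read
#' @return `read_gmt()` returns a [gene_set_collection()];
#'   `write_gmt()` returns `path` invisibly
#' @export
read_gmt <- function(path, provenance = "go") {
  if (!file.exists(path)) {
    abort(sprintf("GMT file '%s' does not exist.", path),
          class = "reportermet_format_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(sprintf("GMT line %d of '%s' has fewer than 3 fields.",
                  bad[[1]], path),
          class = "reportermet_format_error")
  }
  sets <- tibble(
    set_id = vapply(parts, `[[`, character(1), 1),
    name = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) p[-(1:2)]))
  ndup <- sum(lengths(sets$genes) - vapply(sets$genes, function(g)
    length(unique(g)), integer(1)))
  if (ndup > 0) {
    warn(sprintf("GMT '%s': %d duplicated member(s) removed.", path, ndup))
  }
  gene_set_collection(sets, provenance)
}

#' @param collection a [gene_set_collection()]
#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_id[[i]], collection$name[[i]],
            collection$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
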