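#' Construct a metabolic network object
#'
#' A `metabolic_network` holds the metabolite-reaction-gene associations of a
#' genome-scale metabolic reconstruction (HMR2-style): metabolites with
#' compartment assignments, reactions with their participant metabolites and
#' associated genes, and optional pathway (subsystem) annotations per
#' reaction. It is the source of all metabolite and pathway gene sets.
#'
#' Gene-protein-reaction boolean rules are not represented: the gene list of
#' a reaction is the flat set of genes mentioned in its association, which is
#' all that gene-set construction needs. Duplicate genes within one reaction
#' are collapsed.
#'
#' @param metabolites tibble with columns `metabolite_id`, `name`,
#'   `compartment_id` (`name`/`compartment_id` may be `NA`)
#' @param reactions tibble with columns `reaction_id`, `pathway` (may be
#'   `NA`), and list-columns `metabolites` (character vectors of participant
#'   metabolite ids) and `genes` (character vectors of associated gene ids,
#'   possibly empty for spontaneous reactions)
#' @param compartments optional tibble with columns `compartment_id`, `name`
#' @return an object of class `metabolic_network`
#' @examples
#' net <- metabolic_network(
#'   metabolites = tibble::tibble(
#'     metabolite_id = c("A", "B"), name = c("A", "B"), compartment_id = "c"),
#'   reactions = tibble::tibble(
#'     reaction_id = "R1", pathway = "Glycolysis",
#'     metabolites = list(c("A", "B")), genes = list(c("g1", "g2"))))
#' net
#' @export
metabolic_network <- function(metabolites, reactions, compartments = NULL) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  for (col in c("metabolite_id")) {
    if (!col %in% names(metabolites)) {
      abort(sprintf("`metabolites` must have a `%s` column.", col))
    }
  }
  if (!"name" %in% names(metabolites)) {
    metabolites$name <- metabolites$metabolite_id
  }
  if (!"compartment_id" %in% names(metabolites)) {
    metabolites$compartment_id <- NA_character_
  }
  for (col in c("reaction_id", "metabolites", "genes")) {
    if (!col %in% names(reactions)) {
      abort(sprintf("`reactions` must have a `%s` column.", col))
    }
  }
  if (!"pathway" %in% names(reactions)) reactions$pathway <- NA_character_
  if (anyDuplicated(metabolites$metabolite_id)) {
    abort("duplicate `metabolite_id` in `metabolites`.")
  }
  if (anyDuplicated(reactions$reaction_id)) {
    abort("duplicate `reaction_id` in `reactions`.")
  }
  # reaction gene lists: character, deduplicated, original order kept
  reactions$genes <- lapply(reactions$genes, function(g) {
    g <- as.character(g)
    unique(g[!is.na(g) & nzchar(g)])
  })
  reactions$metabolites <- lapply(reactions$metabolites, as.character)
  # referential integrity: every participant must be a declared metabolite
  for (i in seq_len(nrow(reactions))) {
    missing <- setdiff(reactions$metabolites[[i]], metabolites$metabolite_id)
    if (length(missing)) {
      abort(sprintf(
        "reaction '%s' references undeclared metabolite(s): %s",
        reactions$reaction_id[[i]], paste(missing, collapse = ", ")),
        class = "reportermet_integrity_error")
    }
  }
  if (is.null(compartments)) {
    ids <- unique(metabolites$compartment_id)
    ids <- ids[!is.na(ids)]
    compartments <- tibble(compartment_id = ids, name = ids)
  }
  structure(
    list(metabolites = metabolites, reactions = reactions,
         compartments = as_tibble(compartments)),
    class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  n_genes <- length(unique(unlist(x$reactions$genes)))
  n_path <- length(unique(stats::na.omit(x$reactions$pathway)))
  cat(sprintf(
    "<metabolic_network> %d metabolites, %d reactions, %d genes, %d pathways, %d compartments\n",
    nrow(x$metabolites), nrow(x$reactions), n_genes, n_path,
    nrow(x$compartments)))
  invisible(x)
}

#' Read a metabolic network from a tabular reaction file
#'
#' The tabular dialect is a TSV with one row per (reaction, participant
#' metabolite): columns `reaction_id`, `metabolite_id`, `role`
#' (substrate/product, informational only), `genes` (semicolon-separated
#' gene ids, may be empty), `pathway` (may be empty). Optional columns
#' `metabolite_name` and `compartment_id` annotate the metabolites.
#'
#' @param path path to the TSV file
#' @return a [metabolic_network()]
#' @export
read_network_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("reaction_id", "metabolite_id", "role", "genes", "pathway")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("network TSV '%s' lacks column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "reportermet_format_error")
  }
  if (!"metabolite_name" %in% names(df)) df$metabolite_name <- df$metabolite_id
  if (!"compartment_id" %in% names(df)) df$compartment_id <- NA_character_

  mets <- df |>
    distinct(.data$metabolite_id, .keep_all = TRUE) |>
    transmute(metabolite_id = .data$metabolite_id,
              name = .data$metabolite_name,
              compartment_id = .data$compartment_id)
  rxns <- df |>
    group_by(reaction_id = .data$reaction_id) |>
    summarise(
      pathway = {
        p <- unique(.data$pathway[!is.na(.data$pathway) & nzchar(.data$pathway)])
        if (length(p)) p[[1]] else NA_character_
      },
      metabolites = list(unique(.data$metabolite_id)),
      genes = list(split_genes(.data$genes)),
      .groups = "drop")
  metabolic_network(mets, rxns)
}

split_genes <- function(x) {
  g <- unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE))
  unique(trimws(g[nzchar(trimws(g))]))
}

#' Read a metabolic network from an SBML file
#'
#' Parses the SBML Level 3 core subset needed for gene-set construction:
#' compartments, species, reactions with their speciesReference participants,
#' and `fbc` gene-product associations when present (the boolean structure of
#' the association is flattened to the set of gene products it mentions).
#' Reactions annotated with SBML `groups` members inherit the group name as
#' their pathway.
#'
#' @param path path to an SBML (.xml) file
#' @return a [metabolic_network()]
#' @export
read_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("cannot parse SBML file '%s': %s", path,
                  conditionMessage(e)),
          class = "reportermet_format_error")
  })
  # strip default namespaces so xpath stays readable across SBML levels
  xml2::xml_ns_strip(doc)
  # attribute accessor tolerant of package prefixes (fbc:id vs id)
  xattr <- function(nodes, name) {
    vapply(nodes, function(n) {
      at <- xml2::xml_attrs(n)
      hit <- at[names(at) == name |
                  grepl(paste0(":", name, "$"), names(at))]
      if (length(hit)) unname(hit[[1]]) else NA_character_
    }, character(1))
  }

  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  compartments <- tibble(
    compartment_id = xml2::xml_attr(comp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(comp_nodes, "name"),
                           xml2::xml_attr(comp_nodes, "id")))

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  metabolites <- tibble(
    metabolite_id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           xml2::xml_attr(sp_nodes, "id")),
    compartment_id = xml2::xml_attr(sp_nodes, "compartment"))

  # fbc gene products: id -> label (fall back to id)
  gp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- setNames(
    dplyr::coalesce(xattr(gp_nodes, "label"), xattr(gp_nodes, "id")),
    xattr(gp_nodes, "id"))

  # groups package: reaction id -> group (pathway) name
  grp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGroups']/*[local-name()='group']")
  rxn_pathway <- character()
  for (g in grp_nodes) {
    gname <- xattr(list(g), "name")
    if (is.na(gname)) gname <- xattr(list(g), "id")
    members <- xml2::xml_find_all(g, ".//*[local-name()='member']")
    ids <- xattr(members, "idRef")
    rxn_pathway[ids[!is.na(ids)]] <- gname
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- purrr::map(rx_nodes, function(rx) {
    rid <- xml2::xml_attr(rx, "id")
    refs <- xml2::xml_find_all(
      rx, "./listOfReactants/speciesReference | ./listOfProducts/speciesReference")
    mets <- unique(xml2::xml_attr(refs, "species"))
    gprs <- xml2::xml_find_all(rx, ".//*[local-name()='geneProductRef']")
    gids <- xattr(gprs, "geneProduct")
    genes <- unique(unname(ifelse(gids %in% names(gp_label),
                                  gp_label[gids], gids)))
    pathway <- if (rid %in% names(rxn_pathway)) rxn_pathway[[rid]] else NA_character_
    tibble(reaction_id = rid, pathway = pathway,
           metabolites = list(mets), genes = list(genes[!is.na(genes)]))
  }) |> purrr::list_rbind()
  if (nrow(rxns) == 0) {
    rxns <- tibble(reaction_id = character(), pathway = character(),
                   metabolites = list(), genes = list())
  }
  metabolic_network(metabolites, rxns, compartments)
}

#' Read a metabolic network, dispatching on dialect
#'
#' @param path input file
#' @param dialect `"tsv"` for the tabular reaction dialect, `"sbml"` for
#'   SBML; `"auto"` (default) decides from the file extension
#' @return a [metabolic_network()]
#' @export
parse_network <- function(path, dialect = c("auto", "tsv", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "tsv"
  }
  switch(dialect, tsv = read_network_tsv(path), sbml = read_network_sbml(path))
}

#' Read a two-column ortholog mapping table
#'
#' Headerless TSV mapping source gene ids (column 1) to target gene ids
#' (column 2), e.g. human to mouse Ensembl identifiers. The relation may be
#' one-to-many and many-to-one; duplicated pairs are dropped.
#'
#' @param path path to the TSV
#' @return tibble with columns `source`, `target`
#' @export
read_ortholog_map <- function(path) {
  df <- readr::read_tsv(path, col_names = c("source", "target"),
                        col_types = "cc", progress = FALSE)
  distinct(df)
}
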