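test_that("metabolite sets are unions over reactions containing the metabolite", {
  sets <- build_metabolite_gene_sets(toy_network(), min_size = 1)
  expect_equal(sets$set_id, c("A", "B", "C"))
  expect_setequal(sets$genes[[1]], c("g1", "g2"))
  expect_setequal(sets$genes[[2]], c("g1", "g2", "g3"))
  expect_equal(sets$genes[[3]], "g3")
  expect_true(all(sets$provenance == "metabolite"))
  # size filter
  expect_equal(build_metabolite_gene_sets(toy_network(), min_size = 3)$set_id,
               "B")
  # blacklist
  expect_false("B" %in% build_metabolite_gene_sets(
    toy_network(), min_size = 1, blacklist = "B")$set_id)
})

test_that("metabolites seen only in gene-less reactions yield no set", {
  net <- metabolic_network(
    tibble::tibble(metabolite_id = c("A", "W")),
    tibble::tibble(reaction_id = c("R1", "R2"),
                   metabolites = list("A", "W"),
                   genes = list("g1", character())))
  sets <- build_metabolite_gene_sets(net, min_size = 1)
  expect_equal(sets$set_id, "A")
})

test_that("compartment collapse merges sets by metabolite name", {
  net <- metabolic_network(
    tibble::tibble(metabolite_id = c("glc_c", "glc_m"),
                   name = c("glucose", "glucose"),
                   compartment_id = c("c", "m")),
    tibble::tibble(reaction_id = c("R1", "R2"),
                   metabolites = list("glc_c", "glc_m"),
                   genes = list("g1", "g2")))
  per_comp <- build_metabolite_gene_sets(net, min_size = 1)
  expect_equal(nrow(per_comp), 2)
  collapsed <- build_metabolite_gene_sets(net, min_size = 1,
                                          collapse_compartments = TRUE)
  expect_equal(collapsed$set_id, "glucose")
  expect_setequal(collapsed$genes[[1]], c("g1", "g2"))
})

test_that("pathway sets union their reactions' genes and are not a partition", {
  net <- metabolic_network(
    tibble::tibble(metabolite_id = c("A", "B", "C")),
    tibble::tibble(reaction_id = c("R1", "R2", "R3"),
                   pathway = c("P1", "P1", "P2"),
                   metabolites = list("A", "B", "C"),
                   genes = list(c("g1", "g2"), c("g2", "g3"), "g2")))
  sets <- build_pathway_gene_sets(net, min_size = 1)
  expect_setequal(sets$genes[[match("P1", sets$set_id)]],
                  c("g1", "g2", "g3"))
  expect_true(all(vapply(sets$genes, function(g) "g2" %in% g, logical(1))))
  # unannotated networks give an empty collection, not an error
  net2 <- toy_network()
  net2$reactions$pathway <- NA_character_
  expect_equal(nrow(build_pathway_gene_sets(net2, min_size = 1)), 0)
})

test_that("metabolite set construction is deterministic and consistent with the network", {
  net <- sim_network(sim_config(seed = 3, n_genes = 100, n_metabolites = 12,
                                n_reactions = 25))
  s1 <- build_metabolite_gene_sets(net, min_size = 1, max_size = Inf)
  s2 <- build_metabolite_gene_sets(net, min_size = 1, max_size = Inf)
  expect_identical(s1, s2)
  # every member of every set is associated with >= 1 reaction containing
  # that metabolite (re-scan of the network)
  for (i in seq_len(nrow(s1))) {
    met <- s1$set_id[[i]]
    rx_genes <- unlist(net$reactions$genes[
      vapply(net$reactions$metabolites, function(m) met %in% m, logical(1))])
    expect_true(all(s1$genes[[i]] %in% rx_genes))
  }
  # union of all sets is a subset of the union of reaction associations
  expect_true(all(unlist(s1$genes) %in% unlist(net$reactions$genes)))
})

test_that("GMT round-trip is an identity; short lines and duplicates are handled", {
  coll <- gene_set_collection(tibble::tibble(
    set_id = c("S1", "S2"),
    name = c("first set", "second set"),
    genes = list(c("g1", "g2"), c("g3", "g2", "g4"))), "go")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, provenance = "go")
  expect_identical(back$set_id, coll$set_id)
  expect_identical(back$genes, coll$genes)
  expect_identical(back$name, coll$name)
  # bit-exact file round trip
  path2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(back, path2)
  expect_identical(readLines(path), readLines(path2))

  writeLines("S1\tonly-two-fields", path)
  expect_error(read_gmt(path), "line 1", class = "reportermet_format_error")

  writeLines("S1\tdesc\tg1\tg1\tg2", path)
  expect_warning(b <- read_gmt(path), "duplicated")
  expect_equal(b$genes[[1]], c("g1", "g2"))
})

test_that("ortholog mapping expands, merges, drops and preserves identity", {
  coll <- one_set(c("hA", "hB"))
  map <- tibble::tibble(source = c("hA", "hA", "hB"),
                        target = c("mA", "mA2", "mB"))
  mapped <- map_gene_sets(coll, map)
  expect_setequal(mapped$genes[[1]], c("mA", "mA2", "mB"))

  # unmapped members: dropped by default, retained verbatim otherwise
  coll2 <- one_set(c("hA", "hC"))
  expect_equal(map_gene_sets(coll2, map)$genes[[1]], c("mA", "mA2"))
  expect_setequal(map_gene_sets(coll2, map, drop_unmapped = FALSE)$genes[[1]],
                  c("mA", "mA2", "hC"))

  # identity map leaves membership unchanged
  idmap <- tibble::tibble(source = c("hA", "hB"), target = c("hA", "hB"))
  expect_identical(map_gene_sets(coll, idmap)$genes, coll$genes)

  # many-to-one merges with deduplication; emptied sets are removed
  m21 <- tibble::tibble(source = c("hA", "hB"), target = c("mX", "mX"))
  expect_equal(map_gene_sets(coll, m21)$genes[[1]], "mX")
  nomap <- tibble::tibble(source = "zz", target = "mZ")
  expect_equal(nrow(map_gene_sets(coll, nomap)), 0)
})
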