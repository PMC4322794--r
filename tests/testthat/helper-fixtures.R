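# Shared in-code fixtures. Everything is built programmatically so tests
# carry no data files.

toy_network <- function() {
  metabolic_network(
    metabolites = tibble::tibble(
      metabolite_id = c("A", "B", "C"),
      name = c("A", "B", "C"),
      compartment_id = "c"),
    reactions = tibble::tibble(
      reaction_id = c("R1", "R2"),
      pathway = c("P1", "P1"),
      metabolites = list(c("A", "B"), c("B", "C")),
      genes = list(c("g1", "g2"), "g3")))
}

toy_stats <- function(values, genes = sprintf("g%d", seq_along(values))) {
  tibble::tibble(gene_id = genes, log2fc = values)
}

one_set <- function(genes, id = "S1") {
  gene_set_collection(tibble::tibble(set_id = id, genes = list(genes)))
}

# minimal SBML level-3 document with fbc gene products and a groups pathway
toy_sbml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    ' xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1"',
    ' level="3" version="1" fbc:required="false" groups:required="false">',
    '<model id="toy">',
    '<listOfCompartments><compartment id="c" name="cytosol" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A_c" name="metA" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>',
    '<species id="B_c" name="metB" compartment="c" constant="false" hasOnlySubstanceUnits="false" boundaryCondition="false"/>',
    '</listOfSpecies>',
    '<fbc:listOfGeneProducts>',
    '<fbc:geneProduct fbc:id="G_1" fbc:label="g1"/>',
    '<fbc:geneProduct fbc:id="G_2" fbc:label="g2"/>',
    '</fbc:listOfGeneProducts>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false" fast="false">',
    '<listOfReactants><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B_c" stoichiometry="1" constant="true"/></listOfProducts>',
    '<fbc:geneProductAssociation><fbc:or>',
    '<fbc:geneProductRef fbc:geneProduct="G_1"/>',
    '<fbc:geneProductRef fbc:geneProduct="G_2"/>',
    '</fbc:or></fbc:geneProductAssociation>',
    '</reaction>',
    '</listOfReactions>',
    '<groups:listOfGroups>',
    '<groups:group groups:id="grp1" groups:kind="partonomy" groups:name="Glycolysis">',
    '<groups:listOfMembers><groups:member groups:idRef="R1"/></groups:listOfMembers>',
    '</groups:group>',
    '</groups:listOfGroups>',
    '</model></sbml>'), path)
  path
}
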