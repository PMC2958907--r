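minimal_sbml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m1"><listOfSpecies>',
    '<species id="s1" name="lonely protein" compartment="cytoplasm"/>',
    "</listOfSpecies></model></sbml>"
  )
}

test_that("minimal SBML with one species and no reactions parses", {
  f <- tmpfile(".xml")
  writeLines(minimal_sbml(), f)
  m <- read_celldesigner_sbml(f)
  expect_equal(nrow(m$species), 1)
  expect_equal(nrow(m$interactions), 0)
  # no class annotation -> UNKNOWN
  expect_equal(m$species$entity_class, "UNKNOWN")
  cen <- census(m)
  expect_equal(cen$n_species, 1)
  expect_equal(cen$n_interactions, 0)
})

test_that("read errors are classed: missing file, bad XML, no model", {
  expect_error(read_celldesigner_sbml("no/such/file.xml"),
               class = "pathmotif_input_error")
  f <- tmpfile(".xml")
  writeLines("<sbml><model>", f)
  expect_error(read_celldesigner_sbml(f), class = "pathmotif_format_error")
  writeLines('<?xml version="1.0"?><notsbml/>', f)
  expect_error(read_celldesigner_sbml(f), class = "pathmotif_format_error")
})

test_that("dangling species reference raises an integrity error naming the reaction", {
  f <- tmpfile(".xml")
  writeLines(paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfSpecies>',
    '<species id="s1" compartment="cytoplasm"/></listOfSpecies>',
    '<listOfReactions><reaction id="re_bad">',
    '<listOfReactants><speciesReference species="s1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="ghost"/></listOfProducts>',
    "</reaction></listOfReactions></model></sbml>"
  ), f)
  err <- expect_error(read_celldesigner_sbml(f),
                      class = "pathmotif_integrity_error")
  expect_match(conditionMessage(err), "re_bad")
})

test_that("a foreign CellDesigner dialect parses with tolerant fallbacks", {
  f <- system.file("extdata", "toy_receptor_map.xml", package = "pathmotif")
  m <- read_celldesigner_sbml(f)
  cls <- setNames(m$species$entity_class, m$species$id)
  expect_equal(unname(cls[c("sp1", "sp2", "sp4", "sp5", "sp6", "sp7")]),
               c("RECEPTOR", "PROTEIN", "TRUNCATED_PROTEIN", "RNA",
                 "COMPLEX", "UNKNOWN"))
  kinds <- setNames(m$interactions$kind, m$interactions$id)
  expect_equal(unname(kinds[c("r1", "r2", "r3", "r4")]),
               c("HETERODIMER_ASSOCIATION", "STATE_TRANSITION",
                 "TRANSCRIPTIONAL_ACTIVATION", "UNKNOWN_TRANSITION"))
  # PMIDs from plain tokens and PubMed URLs; GeneIDs from token and URL
  sp <- m$species
  expect_equal(sp$pmids[[which(sp$id == "sp1")]], 11607032L)
  expect_setequal(sp$pmids[[which(sp$id == "sp2")]], c(9013863L, 9697844L))
  expect_equal(sp$gene_ids[[which(sp$id == "sp1")]], 7099L)
  expect_equal(sp$gene_ids[[which(sp$id == "sp2")]], 4615L)
  # activity, modifications, modifier roles, question-mark uncertainty
  expect_true(sp$active[sp$id == "sp2"])
  expect_equal(sp$modifications[[which(sp$id == "sp2")]], "PHOSPHORYLATED")
  mods <- m$interactions$modifiers[[which(m$interactions$id == "r2")]]
  expect_equal(mods$species_id, "sp6")
  expect_equal(mods$role, "CATALYSIS")
  expect_false(m$interactions$direct_known[m$interactions$id == "r4"])
  expect_true(all(m$interactions$direct_known[m$interactions$id != "r4"]))
})

test_that("write-then-read preserves the census of generated models", {
  for (seed in c(2, 7)) {
    m <- random_model(seed)
    f <- tmpfile(".xml")
    write_celldesigner_sbml(m, f)
    m2 <- read_celldesigner_sbml(f)
    expect_equal(unclass(census(m2)), unclass(census(m)))
    # modifier roles and uncertainty survive the round trip too
    expect_equal(m2$interactions$direct_known, m$interactions$direct_known)
    expect_equal(
      lapply(m2$interactions$modifiers, function(d) d[order(d$species_id), ]),
      lapply(m$interactions$modifiers, function(d) d[order(d$species_id), ]),
      ignore_attr = TRUE)
  }
})

test_that("empty model writes valid SBML and censuses to all zeros", {
  m <- pathway_model("empty", NULL, NULL)
  f <- tmpfile(".xml")
  write_celldesigner_sbml(m, f)
  m2 <- read_celldesigner_sbml(f)
  cen <- census(m2)
  expect_equal(cen$n_species, 0)
  expect_equal(cen$n_interactions, 0)
  expect_equal(cen$n_unique_pmids, 0)
  expect_true(all(unlist(cen$species_by_class) == 0))
})

test_that("census totals are partition sums and protein classes pool", {
  for (seed in c(3, 9)) {
    m <- random_model(seed)
    cen <- census(m)
    expect_equal(sum(unlist(cen$species_by_class)), cen$n_species)
    expect_equal(sum(unlist(cen$interactions_by_kind)), cen$n_interactions)
    expect_equal(cen$n_protein_species,
                 cen$species_by_class$PROTEIN +
                   cen$species_by_class$RECEPTOR +
                   cen$species_by_class$TRUNCATED_PROTEIN)
  }
})

test_that("parsing is insensitive to element order in the document", {
  m <- random_model(5)
  perm <- with_seed_helper(1, list(s = sample(nrow(m$species)),
                                   i = sample(nrow(m$interactions))))
  m_perm <- pathway_model(m$name, m$species[perm$s, ],
                          m$interactions[perm$i, ])
  f1 <- tmpfile(".xml")
  f2 <- tmpfile(".xml")
  write_celldesigner_sbml(m, f1)
  write_celldesigner_sbml(m_perm, f2)
  expect_false(identical(readLines(f1), readLines(f2)))
  expect_equal(unclass(census(read_celldesigner_sbml(f2))),
               unclass(census(read_celldesigner_sbml(f1))))
})

test_that("model invariants are enforced at construction", {
  s <- rbind(species_node("a"), species_node("a"))
  expect_error(pathway_model("dup", s, NULL),
               class = "pathmotif_integrity_error")
  s <- species_node("a")
  i <- interaction_record("r1", "STATE_TRANSITION")
  expect_error(pathway_model("empty-ends", s, i),
               class = "pathmotif_integrity_error")
  i <- interaction_record("r1", "NOT_A_KIND", reactant_ids = "a",
                          product_ids = "a")
  expect_error(pathway_model("bad-kind", s, i),
               class = "pathmotif_integrity_error")
  expect_error(
    pathway_model("dup-pmid",
                  species_node("a", pmids = c(5L, 5L)), NULL),
    class = "pathmotif_integrity_error")
})
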