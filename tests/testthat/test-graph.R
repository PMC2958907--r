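whole_rules <- projection_rules(drop_isolated = FALSE,
                                component_policy = "WHOLE")

test_that("projection collapses typed reactions into pairwise edges", {
  m <- pathway_model(
    "cat", rbind(species_node("A"), species_node("B"), species_node("C")),
    interaction_record("r1", "STATE_TRANSITION", "A", "B",
                       modifiers = data.frame(species_id = "C",
                                              role = "CATALYSIS")))
  net <- project_to_graph(m, whole_rules)
  expect_setequal(paste(net$edges$from, net$edges$to), c("A B", "C B"))

  m2 <- pathway_model(
    "pairs",
    rbind(species_node("A"), species_node("B"), species_node("C"),
          species_node("D")),
    interaction_record("r1", "STATE_TRANSITION", c("A", "B"), c("C", "D")))
  net2 <- project_to_graph(m2, whole_rules)
  expect_setequal(paste(net2$edges$from, net2$edges$to),
                  c("A C", "A D", "B C", "B D"))
})

test_that("modifier edges can target reactants instead of products", {
  m <- pathway_model(
    "cat", rbind(species_node("A"), species_node("B"), species_node("C")),
    interaction_record("r1", "STATE_TRANSITION", "A", "B",
                       modifiers = data.frame(species_id = "C",
                                              role = "INHIBITION")))
  net <- project_to_graph(m, projection_rules(
    modifier_targets = "REACTANTS", drop_isolated = FALSE,
    component_policy = "WHOLE"))
  expect_setequal(paste(net$edges$from, net$edges$to), c("A B", "C A"))
  expect_equal(net$edges$sign[net$edges$from == "C"], "INHIBITING")
})

test_that("projection matches the brute-force triple-loop oracle", {
  for (seed in c(1, 4, 8)) {
    m <- random_model(seed)
    for (mt in c("PRODUCTS", "REACTANTS")) {
      net <- project_to_graph(m, projection_rules(
        modifier_targets = mt, drop_isolated = FALSE,
        component_policy = "WHOLE"))
      expect_equal(edge_keys(net), oracle_projection(m, mt))
    }
  }
})

test_that("projection is deterministic under reaction reordering", {
  m <- random_model(6)
  perm <- with_seed_helper(2, sample(nrow(m$interactions)))
  m_perm <- pathway_model(m$name, m$species, m$interactions[perm, ])
  expect_identical(project_to_graph(m)$edges, project_to_graph(m_perm)$edges)
})

test_that("sign conflicts collapse to INHIBITING with a message", {
  m <- pathway_model(
    "conflict", rbind(species_node("A"), species_node("B")),
    rbind(interaction_record("r1", "STATE_TRANSITION", "A", "B"),
          interaction_record("r2", "INHIBITION", "A", "B")))
  expect_message(net <- project_to_graph(m, whole_rules), "INHIBITING")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sign, "INHIBITING")
})

test_that("edge count never exceeds the pairwise-expansion bound", {
  for (seed in c(2, 5)) {
    m <- random_model(seed)
    net <- project_to_graph(m, whole_rules)
    bound <- sum(vapply(seq_len(nrow(m$interactions)), function(i) {
      ia <- m$interactions[i, ]
      length(ia$reactant_ids[[1]]) * length(ia$product_ids[[1]]) +
        nrow(ia$modifiers[[1]]) * length(ia$product_ids[[1]])
    }, 0))
    expect_lte(nrow(net$edges), bound)
    expect_equal(nrow(net$edges), length(oracle_projection(m)))
  }
})

test_that("largest weak component selection honors size and tie-break", {
  conn <- directed_network(edges = data.frame(
    from = c("a", "b", "c"), to = c("b", "c", "a")))
  expect_identical(largest_weak_component(conn), conn)

  two <- directed_network(edges = data.frame(
    from = c("a", "b", "c", "d", "x", "y"),
    to = c("b", "c", "d", "e", "y", "z")))
  keep <- largest_weak_component(two)
  expect_setequal(keep$nodes, c("a", "b", "c", "d", "e"))

  tie <- directed_network(edges = data.frame(
    from = c("a", "b", "x", "y"), to = c("b", "c", "y", "z")))
  expect_setequal(largest_weak_component(tie)$nodes, c("a", "b", "c"))

  empty <- directed_network()
  expect_equal(length(largest_weak_component(empty)$nodes), 0)
})

test_that("largest weak component output is weakly connected (flood-fill oracle)", {
  for (seed in c(3, 11, 21)) {
    net <- generate_background(25, 28, seed = seed)
    comp <- largest_weak_component(net)
    expect_true(oracle_weakly_connected(comp$nodes, comp$edges))
  }
})

test_that("edge-list TSV round trips exactly, isolated nodes included", {
  net <- directed_network(
    nodes = c("iso", "a", "b", "c"),
    edges = data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"),
                       sign = c("ACTIVATING", "INHIBITING", "NEUTRAL")))
  f <- tmpfile(".tsv")
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_identical(back, net)
  expect_true("iso" %in% back$nodes)

  big <- generate_background(60, 1000, seed = 13)
  write_edge_list(big, f)
  expect_identical(read_edge_list(f), big)
})

test_that("malformed edge-list rows report the offending line", {
  f <- tmpfile(".tsv")
  writeLines(c("#node a", "#node b", "a\tb\tNEUTRAL", "brokenrow"), f)
  err <- expect_error(read_edge_list(f), class = "pathmotif_format_error")
  expect_match(conditionMessage(err), "line 4")
})

test_that("directed_network rejects self-loops, duplicates and bad signs", {
  expect_error(directed_network(edges = data.frame(from = "a", to = "a")),
               class = "pathmotif_integrity_error")
  expect_error(directed_network(edges = data.frame(from = c("a", "a"),
                                                   to = c("b", "b"))),
               class = "pathmotif_integrity_error")
  expect_error(directed_network(edges = data.frame(from = "a", to = "b",
                                                   sign = "UP")),
               class = "pathmotif_integrity_error")
})
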