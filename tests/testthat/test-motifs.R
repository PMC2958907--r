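# all 3-node labeled digraphs (64 off-diagonal patterns)
all_3node_digraphs <- function() {
  lapply(0:63, function(b) {
    m <- matrix(0L, 3, 3)
    m[which(diag(3) == 0)] <- as.integer(intToBits(b)[1:6])
    m
  })
}

test_that("canonical id is permutation-invariant (exhaustive k=3,4; sampled k=5,6)", {
  for (m in all_3node_digraphs()) {
    id <- canonical_id(m)
    for (p in all_perms(3)) expect_equal(canonical_id(m[p, p]), id)
  }
  for (seed in 1:40) {
    m <- random_adjacency(4, 0.4, seed)
    id <- canonical_id(m)
    for (p in all_perms(4)) expect_equal(canonical_id(m[p, p]), id)
  }
  for (k in 5:6) {
    for (seed in 1:15) {
      m <- random_adjacency(k, 0.3, 100 * k + seed)
      id <- canonical_id(m)
      p <- with_seed_helper(seed, sample(k))
      expect_equal(canonical_id(m[p, p]), id)
    }
  }
})

test_that("canonicalization induces exactly the isomorphism classes of connected 3-node digraphs", {
  is_conn <- function(m) oracle_weakly_connected(
    c("1", "2", "3"),
    data.frame(from = as.character(which(m == 1, arr.ind = TRUE)[, 1]),
               to = as.character(which(m == 1, arr.ind = TRUE)[, 2])))
  conn <- Filter(is_conn, all_3node_digraphs())
  expect_equal(length(conn), 54)  # labeled connected digraphs on 3 nodes
  # independent classing: partition by exhaustive permutation isomorphism
  reps <- list()
  for (m in conn) {
    if (!any(vapply(reps, oracle_isomorphic, TRUE, b = m))) {
      reps[[length(reps) + 1]] <- m
    }
  }
  ids <- unique(vapply(conn, canonical_id, 0))
  expect_equal(length(ids), length(reps))
  # and the partitions agree pairwise
  for (a in seq_along(reps)) {
    for (b in seq_along(reps)) {
      expect_equal(canonical_id(reps[[a]]) == canonical_id(reps[[b]]),
                   a == b)
    }
  }
})

test_that("canonical id rejects self-loops and distinguishes FFL from 3-cycle", {
  m <- diag(3)
  expect_error(canonical_id(m), class = "pathmotif_input_error")
  expect_false(canonical_id(motif_adjacency("FEEDFORWARD_LOOP")) ==
                 canonical_id(motif_adjacency("FEEDBACK_LOOP", 3)))
})

test_that("ESU enumeration matches brute-force subset enumeration", {
  # path and star base cases
  path <- directed_network(edges = data.frame(from = c("a", "b"),
                                              to = c("b", "c")))
  expect_equal(enumerate_connected_subgraphs(path, 3),
               list(c("a", "b", "c")))
  star <- directed_network(edges = data.frame(
    from = "hub", to = c("x", "y", "z")))
  expect_equal(length(enumerate_connected_subgraphs(star, 3)), 3)

  net <- generate_background(12, 30, seed = 17)
  subs <- enumerate_connected_subgraphs(net, 4)
  expect_equal(subset_keys(subs),
               subset_keys(oracle_connected_subsets(net, 4)))

  for (seed in c(1, 9)) {
    net <- generate_background(11, 22, seed = seed)
    for (k in 3:6) {
      expect_equal(
        subset_keys(enumerate_connected_subgraphs(net, k)),
        subset_keys(oracle_connected_subsets(net, k)),
        info = sprintf("seed %d k %d", seed, k))
    }
  }
})

test_that("enumeration size limits behave as documented", {
  net <- generate_background(4, 6, seed = 1)
  expect_error(enumerate_connected_subgraphs(net, 2),
               class = "pathmotif_parameter_error")
  expect_error(enumerate_connected_subgraphs(net, 7),
               class = "pathmotif_parameter_error")
  expect_equal(enumerate_connected_subgraphs(net, 5), list())
})

test_that("motif census identifies named families on canonical examples", {
  ffl <- directed_network(edges = data.frame(from = c("A", "A", "B"),
                                             to = c("B", "C", "C")))
  cen <- motif_census(ffl, 3)
  expect_equal(nrow(cen), 1)
  expect_equal(cen$family, "FEEDFORWARD_LOOP")
  expect_equal(cen$count, 1)
  expect_equal(attr(cen, "total"), 1)

  bifan <- directed_network(edges = data.frame(
    from = c("A", "A", "B", "B"), to = c("C", "D", "C", "D")))
  cen4 <- motif_census(bifan, 4)
  expect_equal(nrow(cen4), 1)
  expect_equal(cen4$family, "BIFAN")
  expect_equal(cen4$count, 1)
})

test_that("census counts match brute-force induced counting on planted graphs", {
  plan <- planting_plan(14, 10, data.frame(
    family = c("BIFAN", "FEEDFORWARD_LOOP"), count = c(1, 1),
    disjoint = c(TRUE, TRUE)), seed = 23)
  pm <- plant_motifs(plan)
  for (fam in c("FEEDFORWARD_LOOP", "BIFAN")) {
    adj <- motif_adjacency(fam)
    k <- nrow(adj)
    cen <- motif_census(pm$network, k)
    got <- cen$count[cen$family == fam]
    expect_equal(if (length(got)) got else 0,
                 oracle_induced_count(pm$network, adj), info = fam)
  }
  # total equals the number of enumerated connected subsets
  cen <- motif_census(pm$network, 4)
  expect_equal(attr(cen, "total"),
               length(oracle_connected_subsets(pm$network, 4)))
})

test_that("census totals are invariant under node relabeling", {
  net <- generate_background(15, 35, seed = 31)
  relabeled <- with_seed_helper(4, {
    new_ids <- paste0("z", sample(LETTERS, length(net$nodes)))
    map <- setNames(new_ids, net$nodes)
    directed_network(unname(map[net$nodes]), data.frame(
      from = unname(map[net$edges$from]), to = unname(map[net$edges$to])))
  })
  for (k in 3:5) {
    a <- motif_census(net, k)
    b <- motif_census(relabeled, k)
    expect_equal(attr(a, "total"), attr(b, "total"))
    expect_equal(a[c("canonical_id", "count")], b[c("canonical_id", "count")])
  }
})

test_that("family naming covers MIC, feedback, and generalization tags", {
  mic <- motif_class(4, canonical_id(motif_adjacency(
    "MULTI_INPUT_CONVERGENCE", 4)))
  expect_equal(mic$family, "MULTI_INPUT_CONVERGENCE")

  cyc <- motif_class(3, canonical_id(motif_adjacency("FEEDBACK_LOOP", 3)))
  expect_equal(cyc$family, "FEEDBACK_LOOP")

  # FFL plus an extra regulator of C: OTHER, but a generalization of the FFL
  m <- matrix(0L, 4, 4)
  m[1, 2] <- m[2, 3] <- m[1, 3] <- m[4, 3] <- 1L
  mc <- motif_class(4, canonical_id(m))
  expect_equal(mc$family, "OTHER")
  expect_true("FEEDFORWARD_LOOP" %in% mc$family_generalization_of)
  expect_true(oracle_embeds(m, motif_adjacency("FEEDFORWARD_LOOP")))
})

test_that("generalization tags agree with the exhaustive embedding oracle", {
  for (k in 4:5) {
    for (seed in 1:25) {
      m <- random_adjacency(k, 0.35, 7000 + 100 * k + seed)
      mc <- motif_class(k, canonical_id(m))
      expect_equal("FEEDFORWARD_LOOP" %in% mc$family_generalization_of,
                   mc$family != "FEEDFORWARD_LOOP" &&
                     oracle_embeds(m, motif_adjacency("FEEDFORWARD_LOOP")))
      expect_equal("BIFAN" %in% mc$family_generalization_of,
                   mc$family != "BIFAN" &&
                     oracle_embeds(m, motif_adjacency("BIFAN")))
    }
  }
})

test_that("acyclic classes are never called feedback loops", {
  for (seed in 1:20) {
    m <- random_adjacency(4, 0.4, 300 + seed)
    # make acyclic by zeroing the lower triangle
    m[lower.tri(m)] <- 0L
    mc <- motif_class(4, canonical_id(m))
    expect_false(mc$family == "FEEDBACK_LOOP")
  }
})

test_that("census per class agrees with igraph's motif counter at k=3,4", {
  net <- generate_background(20, 60, seed = 41)
  ig <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                      directed = TRUE, vertices = net$nodes)
  for (k in 3:4) {
    cen <- motif_census(net, k)
    counts <- igraph::motifs(ig, size = k)  # NA for disconnected classes
    expect_equal(attr(cen, "total"), sum(counts, na.rm = TRUE))
    # per-class: look up each of our classes via igraph's isomorphism class
    for (r in seq_len(nrow(cen))) {
      adj <- matrix(as.integer(strsplit(cen$adjacency_bits[r], "")[[1]]),
                    k, k, byrow = TRUE)
      gsub <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
      cls <- igraph::isomorphism_class(gsub)
      expect_equal(cen$count[r], counts[cls + 1], info = cen$adjacency_bits[r])
    }
  }
})
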