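# Seeded synthetic inputs: background digraphs, planted motif instances,
# and CellDesigner-like pathway models with a prescribed composition. All
# generators are pure functions of their seeds.

#' Uniform random background digraph
#'
#' Draws exactly `n_edges` distinct directed non-self edges uniformly from
#' the n(n-1) possible ones.
#'
#' @param n_nodes Number of nodes (ids `n001`, `n002`, ...).
#' @param n_edges Number of edges; at most `n_nodes * (n_nodes - 1)`.
#' @param seed Integer seed.
#' @return A `directed_network`.
#' @export
generate_background <- function(n_nodes, n_edges, seed = 1) {
  max_e <- n_nodes * (n_nodes - 1)
  if (n_edges > max_e) {
    pm_stop(sprintf("requested %d edges but only %d are possible",
                    n_edges, max_e), "parameter")
  }
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  if (n_edges == 0) return(directed_network(nodes))
  with_seed(seed, {
    pick <- sample.int(max_e, n_edges)
    # index -> ordered pair, skipping the diagonal
    src <- (pick - 1) %/% (n_nodes - 1) + 1
    off <- (pick - 1) %% (n_nodes - 1) + 1
    dst <- ifelse(off >= src, off + 1, off)
    directed_network(nodes, data.frame(from = nodes[src], to = nodes[dst],
                                       stringsAsFactors = FALSE))
  })
}

#' Declarative plan for planting motif instances
#'
#' @param background_nodes,background_edges Size of the uniform background
#'   digraph.
#' @param plants A data frame with columns `family`
#'   (`FEEDFORWARD_LOOP`, `BIFAN`, `MULTI_INPUT_CONVERGENCE`,
#'   `FEEDBACK_LOOP`), `count`, and `disjoint` (logical: plant on nodes not
#'   used by any other disjoint plant).
#' @param seed Integer seed.
#' @return A list of class `planting_plan`.
#' @export
planting_plan <- function(background_nodes, background_edges, plants,
                          seed = 1) {
  plants <- as.data.frame(plants, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "count", "disjoint") %in% names(plants)))
  bad <- setdiff(plants$family, setdiff(MOTIF_FAMILIES, "OTHER"))
  if (length(bad)) pm_stop(sprintf("unknown family: %s", bad[1]), "parameter")
  structure(list(background_nodes = as.integer(background_nodes),
                 background_edges = as.integer(background_edges),
                 plants = plants, seed = as.integer(seed)),
            class = "planting_plan")
}

plant_size <- function(family) {
  switch(family, FEEDFORWARD_LOOP = 3, BIFAN = 4,
         MULTI_INPUT_CONVERGENCE = 4, FEEDBACK_LOOP = 3)
}

#' Plant motif instances onto a random background
#'
#' Generates the background, then adds each plant's edge set on freshly
#' chosen nodes (drawn without replacement from the unused pool when
#' `disjoint`). Planted edges are unioned with the background, so incidental
#' extra occurrences can arise; the returned ground truth (one node tuple
#' per planted instance) is therefore a lower bound on census counts, and an
#' exact count on an empty background with disjoint plants.
#'
#' @param plan A [planting_plan()].
#' @return A list with elements `network` (a `directed_network`) and
#'   `ground_truth` (a data frame with columns `family` and `nodes`, a list
#'   column of node-id tuples).
#' @export
plant_motifs <- function(plan) {
  net <- generate_background(plan$background_nodes, plan$background_edges,
                             plan$seed)
  nodes <- net$nodes
  demand <- sum(ifelse(plan$plants$disjoint,
                       plan$plants$count *
                         vapply(plan$plants$family, plant_size, 0),
                       0))
  if (demand > length(nodes)) {
    pm_stop(sprintf("disjoint plants need %d nodes but only %d exist",
                    demand, length(nodes)), "parameter")
  }
  with_seed(plan$seed + 1L, {
    pool <- sample(nodes)  # shuffled pool for disjoint plants
    truth_family <- character()
    truth_nodes <- list()
    extra_from <- character()
    extra_to <- character()
    for (i in seq_len(nrow(plan$plants))) {
      fam <- plan$plants$family[i]
      sz <- plant_size(fam)
      adj <- motif_adjacency(fam, sz)
      for (rep_i in seq_len(plan$plants$count[i])) {
        if (plan$plants$disjoint[i]) {
          chosen <- pool[seq_len(sz)]
          pool <- pool[-seq_len(sz)]
        } else {
          chosen <- sample(nodes, sz)
        }
        idx <- which(adj == 1, arr.ind = TRUE)
        extra_from <- c(extra_from, chosen[idx[, 1]])
        extra_to <- c(extra_to, chosen[idx[, 2]])
        truth_family <- c(truth_family, fam)
        truth_nodes[[length(truth_nodes) + 1]] <- chosen
      }
    }
    all_from <- c(net$edges$from, extra_from)
    all_to <- c(net$edges$to, extra_to)
    keep <- !duplicated(paste(all_from, all_to, sep = "\r"))
    list(
      network = directed_network(nodes, data.frame(
        from = all_from[keep], to = all_to[keep], stringsAsFactors = FALSE)),
      ground_truth = data.frame(family = truth_family,
                                nodes = I(truth_nodes),
                                stringsAsFactors = FALSE)
    )
  })
}

#' Declarative recipe for a synthetic pathway model
#'
#' @param species_counts Named integer vector / list: entity class ->
#'   count.
#' @param reaction_counts Named integer vector / list: interaction kind ->
#'   count.
#' @param pmid_pool Number of distinct synthetic PMIDs in the literature
#'   pool; every pool member ends up annotating at least one reaction, so a
#'   model citing at least `pmid_pool` references has exactly `pmid_pool`
#'   unique PMIDs.
#' @param mean_pmids_per_reaction Mean number of PMIDs per reaction
#'   (at least one is always assigned).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(species_counts, reaction_counts, pmid_pool = 50,
                           mean_pmids_per_reaction = 1.5, seed = 1) {
  species_counts <- unlist(species_counts)
  reaction_counts <- unlist(reaction_counts)
  bad <- setdiff(names(species_counts), ENTITY_CLASSES)
  if (length(bad)) pm_stop(sprintf("unknown class: %s", bad[1]), "parameter")
  bad <- setdiff(names(reaction_counts), INTERACTION_KINDS)
  if (length(bad)) pm_stop(sprintf("unknown kind: %s", bad[1]), "parameter")
  if (any(species_counts < 0) || any(reaction_counts < 0)) {
    pm_stop("counts must be non-negative", "parameter")
  }
  structure(list(species_counts = species_counts,
                 reaction_counts = reaction_counts,
                 pmid_pool = as.integer(pmid_pool),
                 mean_pmids_per_reaction = mean_pmids_per_reaction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# class pools a reaction kind draws its reactants / products from
kind_semantics <- function(kind) {
  any_cls <- ENTITY_CLASSES
  switch(kind,
    TRANSCRIPTIONAL_ACTIVATION = list(
      r = PROTEIN_CLASSES, p = "RNA", nr = 1, np = 1),
    TRANSLATION = list(r = "RNA", p = PROTEIN_CLASSES, nr = 1, np = 1),
    HETERODIMER_ASSOCIATION = list(
      r = c(PROTEIN_CLASSES, "COMPLEX"), p = "COMPLEX", nr = 2, np = 1),
    DISSOCIATION = list(r = "COMPLEX",
                        p = c(PROTEIN_CLASSES, "COMPLEX"), nr = 1, np = 2),
    list(r = any_cls, p = any_cls, nr = 1, np = 1)
  )
}

#' Generate a synthetic CellDesigner-like pathway model
#'
#' Builds a model whose [census()] exactly matches the spec: the requested
#' number of species per entity class and reactions per kind, wired by
#' seeded draws that respect kind semantics (transcriptional activations
#' produce RNAs, translations turn RNAs into proteins, associations form
#' complexes, dissociations break them). Wiring prefers previously used
#' species, emulating a signaling cascade's reuse of hubs. PMIDs are drawn
#' from the synthetic pool with every pool member cited at least once
#' (when the total citation count allows), and protein / RNA / gene species
#' receive unique synthetic GeneIDs.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated `pathway_model`.
#' @export
generate_synthetic_model <- function(spec) {
  counts <- spec$species_counts[spec$species_counts > 0]
  n_sp <- sum(counts)
  cls <- rep(names(counts), counts)
  ids <- sprintf("s%03d", seq_len(n_sp))

  with_seed(spec$seed, {
    gene_classes <- c(PROTEIN_CLASSES, "RNA", "GENE")
    next_gene <- 1000L
    species <- do.call(rbind, lapply(seq_len(n_sp), function(i) {
      gid <- integer()
      if (cls[i] %in% gene_classes) {
        gid <- next_gene + i
      }
      species_node(
        id = ids[i],
        display_name = sprintf("%s_%d", tolower(cls[i]), i),
        entity_class = cls[i],
        compartment = sample(COMPARTMENTS, 1,
                             prob = c(.5, .1, .05, .2, .05, .1)),
        active = runif(1) < 0.3,
        modifications = if (cls[i] %in% PROTEIN_CLASSES && runif(1) < 0.3) {
          sample(MODIFICATION_STATES, 1)
        } else character(),
        gene_ids = gid,
        pmids = integer()
      )
    }))

    rk <- spec$reaction_counts[spec$reaction_counts > 0]
    kinds <- rep(names(rk), rk)
    n_rx <- length(kinds)
    pool_pmids <- 10000000L + seq_len(spec$pmid_pool)
    used <- character()  # species already wired, preferred as reactants

    # cascades grow outward: reactants preferentially reuse already wired
    # species (hubs), products preferentially recruit fresh ones, so the
    # projected graph tends to form one large weak component, as a curated
    # signaling map does
    pick_species <- function(classes, n, avoid = character(),
                             prefer = c("used", "fresh")) {
      prefer <- match.arg(prefer)
      cand <- setdiff(ids[cls %in% classes], avoid)
      if (length(cand) < n) {
        pm_stop(sprintf(
          "spec requires %d species of class {%s} but only %d available",
          n, paste(classes, collapse = ","), length(cand)), "parameter")
      }
      pref <- if (prefer == "used") intersect(cand, used) else
        setdiff(cand, used)
      if (length(pref) >= n && runif(1) < 0.8) sample(pref, n) else
        sample(cand, n)
    }

    interactions <- vector("list", n_rx)
    for (i in seq_len(n_rx)) {
      sem <- kind_semantics(kinds[i])
      r <- pick_species(sem$r, sem$nr, prefer = "used")
      p <- pick_species(sem$p, sem$np, avoid = r, prefer = "fresh")
      used <- unique(c(used, r, p))
      modifiers <- NULL
      if (kinds[i] == "STATE_TRANSITION" && runif(1) < 0.4) {
        cand <- setdiff(ids[cls %in% PROTEIN_CLASSES], c(r, p))
        if (length(cand)) {
          modifiers <- data.frame(
            species_id = sample(cand, 1),
            role = sample(c("CATALYSIS", "INHIBITION", "UNKNOWN"), 1,
                          prob = c(.7, .2, .1)),
            stringsAsFactors = FALSE)
        }
      }
      n_pm <- max(1L, rpois(1, spec$mean_pmids_per_reaction))
      interactions[[i]] <- interaction_record(
        id = sprintf("re%03d", i), kind = kinds[i],
        reactant_ids = r, product_ids = p, modifiers = modifiers,
        pmids = sample(pool_pmids, min(n_pm, length(pool_pmids))),
        direct_known = kinds[i] != "UNKNOWN_TRANSITION"
      )
    }
    interactions <- do.call(rbind, interactions)

    # guarantee full pool coverage: every synthetic article cites something
    cited <- unique(unlist(interactions$pmids))
    missing <- setdiff(pool_pmids, cited)
    if (length(missing) && n_rx > 0) {
      slots <- rep(seq_len(n_rx), length.out = length(missing))
      for (j in seq_along(missing)) {
        i <- slots[j]
        interactions$pmids[[i]] <- sort(unique(c(interactions$pmids[[i]],
                                                 missing[j])))
      }
    }

    pathway_model(name = sprintf("synthetic_model_seed%d", spec$seed),
                  species = species, interactions = interactions)
  })
}

#' Synthetic preset emulating the dendritic-cell map's composition
#'
#' A model-scale preset with the published composition of the curated
#' dendritic-cell signaling map: 249 species of which 118 are protein
#' species (96 generic proteins, 20 receptors, 2 truncated proteins), the
#' printed reaction-kind breakdown (122 state transitions, 9 heterodimer
#' associations, 4 dissociations, 36 transcriptional activations, 8 unknown
#' transitions, 8 transport reactions, 21 inhibitions, 4 translations), and
#' a 167-article literature pool. The non-protein class split (RNAs,
#' complexes, small molecules, phenotypes) is not published and is a
#' structural choice. This is a synthetic stand-in for the real map:
#' composition matches, biology does not.
#'
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
dc_map_spec <- function(seed = 1) {
  synthetic_spec(
    species_counts = c(PROTEIN = 96, RECEPTOR = 20, TRUNCATED_PROTEIN = 2,
                       RNA = 40, COMPLEX = 60, SIMPLE_MOLECULE = 21,
                       PHENOTYPE = 10),
    reaction_counts = c(STATE_TRANSITION = 122, HETERODIMER_ASSOCIATION = 9,
                        DISSOCIATION = 4, TRANSCRIPTIONAL_ACTIVATION = 36,
                        UNKNOWN_TRANSITION = 8, TRANSPORT = 8,
                        INHIBITION = 21, TRANSLATION = 4),
    pmid_pool = 167,
    mean_pmids_per_reaction = 1.5,
    seed = seed
  )
}
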