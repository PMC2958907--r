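# Independent oracles: deliberately naive re-implementations used to check
# the package's optimised paths. They share no code with the package
# internals.

# weak connectivity of a node set under a directed edge data frame
oracle_weakly_connected <- function(nodes, edges) {
  if (length(nodes) == 1) return(TRUE)
  e <- edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
  seen <- nodes[1]
  repeat {
    grow <- unique(c(e$to[e$from %in% seen], e$from[e$to %in% seen]))
    new <- union(seen, grow)
    if (length(new) == length(seen)) break
    seen <- new
  }
  length(seen) == length(nodes)
}

# brute-force enumeration of connected k-subsets: all C(n,k) subsets
# filtered by weak connectivity
oracle_connected_subsets <- function(net, k) {
  if (k > length(net$nodes)) return(list())
  subs <- utils::combn(net$nodes, k, simplify = FALSE)
  Filter(function(s) oracle_weakly_connected(s, net$edges), subs)
}

subset_keys <- function(subsets) {
  sort(vapply(subsets, function(s) paste(sort(s), collapse = ","), ""))
}

# brute-force projection: loop over every (reaction, source, target) triple
oracle_projection <- function(model, modifier_targets = "PRODUCTS") {
  out <- character()
  for (i in seq_len(nrow(model$interactions))) {
    ia <- model$interactions[i, ]
    r <- ia$reactant_ids[[1]]
    p <- ia$product_ids[[1]]
    for (a in r) for (b in p) if (a != b) out <- c(out, paste(a, b))
    targets <- if (modifier_targets == "PRODUCTS") p else r
    for (a in ia$modifiers[[1]]$species_id) {
      for (b in targets) if (a != b) out <- c(out, paste(a, b))
    }
  }
  sort(unique(out))
}

edge_keys <- function(net) sort(paste(net$edges$from, net$edges$to))

# are two small adjacency matrices isomorphic? exhaustive permutation check
oracle_isomorphic <- function(a, b) {
  k <- nrow(a)
  for (p in all_perms(k)) {
    if (all(a[p, p] == b)) return(TRUE)
  }
  FALSE
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (sub in all_perms(n - 1)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1]] <- c(i, rest[sub])
    }
  }
  out
}

# exhaustive embedding search: does `pattern` occur in `adj` as a (not
# necessarily induced) subgraph?
oracle_embeds <- function(adj, pattern) {
  k <- nrow(adj)
  p <- nrow(pattern)
  if (p > k) return(FALSE)
  for (sel in utils::combn(seq_len(k), p, simplify = FALSE)) {
    for (perm in all_perms(p)) {
      nodes <- sel[perm]
      ok <- TRUE
      for (i in seq_len(p)) {
        for (j in seq_len(p)) {
          if (pattern[i, j] == 1 && adj[nodes[i], nodes[j]] != 1) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

# in/out degree tables of a directed_network
oracle_degrees <- function(net) {
  list(out = table(factor(net$edges$from, levels = net$nodes)),
       inn = table(factor(net$edges$to, levels = net$nodes)))
}

# count induced occurrences of a family's exact class by brute force
oracle_induced_count <- function(net, adj) {
  k <- nrow(adj)
  subs <- oracle_connected_subsets(net, k)
  n <- 0
  for (s in subs) {
    m <- matrix(0L, k, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i != j &&
            any(net$edges$from == s[i] & net$edges$to == s[j])) {
          m[i, j] <- 1L
        }
      }
    }
    if (oracle_isomorphic(m, adj)) n <- n + 1
  }
  n
}

# small random pathway model for property tests
random_model <- function(seed) {
  generate_synthetic_model(synthetic_spec(
    species_counts = c(PROTEIN = 8, RECEPTOR = 2, RNA = 3, COMPLEX = 4,
                       SIMPLE_MOLECULE = 2),
    reaction_counts = c(STATE_TRANSITION = 8, HETERODIMER_ASSOCIATION = 2,
                        DISSOCIATION = 1, TRANSCRIPTIONAL_ACTIVATION = 3,
                        TRANSPORT = 1, INHIBITION = 2, TRANSLATION = 1,
                        UNKNOWN_TRANSITION = 1),
    pmid_pool = 12, seed = seed))
}

random_adjacency <- function(k, p, seed) {
  m <- with_seed_helper(seed, matrix(as.integer(runif(k * k) < p), k, k))
  diag(m) <- 0L
  m
}

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

tmpfile <- function(ext = ".xml") tempfile(fileext = ext)
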