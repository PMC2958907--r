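# Motif classes: connected k-node induced subgraphs (k = 3..6) up to
# directed-graph isomorphism, identified by a canonical integer id.

#' Canonical id of a small directed adjacency matrix
#'
#' Encodes a k x k binary adjacency matrix (zero diagonal, k <= 6) as the
#' row-major bit integer (most significant bit first) and returns the
#' maximum of that integer over all k! simultaneous row/column permutations.
#' Isomorphic matrices map to the same id, non-isomorphic ones to different
#' ids, so the id names the isomorphism class.
#'
#' @param adjacency Square 0/1 matrix with zero diagonal, order 1..6.
#' @return The canonical id as a double (exact: at most 36 bits).
#' @export
canonical_id <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    pm_stop("adjacency matrix must be square", "input")
  }
  if (any(diag(adjacency) != 0)) {
    pm_stop("nonzero diagonal: self-loops are not allowed", "input")
  }
  cpp_canonical_id(matrix(as.integer(adjacency != 0), nrow(adjacency)))
}

# decode a canonical id back to its k x k adjacency matrix
adjacency_from_id <- function(id, k) {
  bits <- integer(k * k)
  for (pos in seq_len(k * k)) {
    bits[pos] <- floor(id / 2^(k * k - pos)) %% 2
  }
  matrix(bits, k, k, byrow = TRUE)
}

adjacency_bits_string <- function(id, k) {
  # row-major 0/1 string of the canonical adjacency matrix
  paste(as.integer(t(adjacency_from_id(id, k))), collapse = "")
}

#' Reference adjacency matrix of a named motif family
#'
#' @param family One of `FEEDFORWARD_LOOP` (3 nodes), `BIFAN` (4 nodes),
#'   `MULTI_INPUT_CONVERGENCE` (k-1 independent regulators converging on a
#'   single target) or `FEEDBACK_LOOP` (a directed k-cycle).
#' @param k Motif size; fixed at 3 for the feedforward loop and 4 for the
#'   bifan.
#' @return A k x k 0/1 adjacency matrix.
#' @export
motif_adjacency <- function(family, k = switch(family, FEEDFORWARD_LOOP = 3,
                                               BIFAN = 4, 4)) {
  switch(family,
    FEEDFORWARD_LOOP = {
      m <- matrix(0L, 3, 3)
      m[1, 2] <- m[2, 3] <- m[1, 3] <- 1L
      m
    },
    BIFAN = {
      m <- matrix(0L, 4, 4)
      m[1, 3] <- m[1, 4] <- m[2, 3] <- m[2, 4] <- 1L
      m
    },
    MULTI_INPUT_CONVERGENCE = {
      m <- matrix(0L, k, k)
      m[seq_len(k - 1), k] <- 1L
      m
    },
    FEEDBACK_LOOP = {
      m <- matrix(0L, k, k)
      for (i in seq_len(k)) m[i, i %% k + 1] <- 1L
      m
    },
    pm_stop(sprintf("unknown motif family: %s", family), "input")
  )
}

# canonical ids of the exactly-named families, cached per size
family_ref_ids <- local({
  cache <- new.env(parent = emptyenv())
  function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ids <- c(
      FEEDFORWARD_LOOP = if (k == 3) {
        canonical_id(motif_adjacency("FEEDFORWARD_LOOP"))
      } else NA_real_,
      BIFAN = if (k == 4) canonical_id(motif_adjacency("BIFAN")) else NA_real_,
      MULTI_INPUT_CONVERGENCE =
        canonical_id(motif_adjacency("MULTI_INPUT_CONVERGENCE", k))
    )
    cache[[key]] <- ids
    ids
  }
})

has_directed_cycle <- function(adj) {
  k <- nrow(adj)
  indeg <- colSums(adj)
  active <- rep(TRUE, k)
  repeat {
    src <- which(active & indeg == 0)
    if (length(src) == 0) break
    for (s in src) {
      active[s] <- FALSE
      indeg <- indeg - adj[s, ]
    }
  }
  any(active)
}

# closed-form containment tests (not-necessarily-induced subgraphs):
# an FFL exists iff some edge a->c is shortcut by a 2-path a->b->c;
# a bifan exists iff two distinct targets share at least two regulators
contains_ffl <- function(adj) {
  any((adj %*% adj) * adj > 0)
}

contains_bifan <- function(adj) {
  common <- t(adj) %*% adj  # common[c,d] = # shared regulators of c and d
  diag(common) <- 0
  any(common >= 2)
}

# does `pattern` (small digraph) embed into `adj` as a not-necessarily
# induced subgraph? brute force over injective vertex maps; k <= 6
contains_subgraph <- function(adj, pattern) {
  k <- nrow(adj)
  p <- nrow(pattern)
  if (p > k) return(FALSE)
  idx <- seq_len(k)
  maps <- combn(idx, p, simplify = FALSE)
  perms <- permutations_of(p)
  pe <- which(pattern == 1, arr.ind = TRUE)
  for (sel in maps) {
    for (pm in perms) {
      nodes <- sel[pm]
      ok <- all(adj[cbind(nodes[pe[, 1]], nodes[pe[, 2]])] == 1)
      if (ok) return(TRUE)
    }
  }
  FALSE
}

permutations_of <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- if (n == 1) list(1L) else {
      out <- list()
      for (i in seq_len(n)) {
        for (sub in permutations_of(n - 1)) {
          rest <- seq_len(n)[-i]
          out[[length(out) + 1]] <- c(i, rest[sub])
        }
      }
      out
    }
    cache[[key]] <<- res
    res
  }
})

#' Name the motif family of an isomorphism class
#'
#' Assigns the field's family names: `FEEDFORWARD_LOOP` (size 3, edges
#' A->B, B->C, A->C), `BIFAN` (size 4, two regulators sharing two targets),
#' `MULTI_INPUT_CONVERGENCE` (k-1 single-edge regulators converging on one
#' target and nothing else), `FEEDBACK_LOOP` (the class contains a directed
#' cycle), otherwise `OTHER`. Classes that contain a feedforward loop or a
#' bifan as a (not necessarily induced) subgraph are additionally tagged in
#' `family_generalization_of`.
#'
#' @param motif A `motif_class` as built by [motif_class()].
#' @return The `motif_class` with `family` and `family_generalization_of`
#'   filled in.
#' @export
name_family <- function(motif) {
  k <- motif$size
  adj <- adjacency_from_id(motif$canonical_id, k)
  refs <- family_ref_ids(k)
  fam <- if (!is.na(refs["FEEDFORWARD_LOOP"]) &&
             motif$canonical_id == refs["FEEDFORWARD_LOOP"]) {
    "FEEDFORWARD_LOOP"
  } else if (!is.na(refs["BIFAN"]) && motif$canonical_id == refs["BIFAN"]) {
    "BIFAN"
  } else if (motif$canonical_id == refs["MULTI_INPUT_CONVERGENCE"]) {
    "MULTI_INPUT_CONVERGENCE"
  } else if (has_directed_cycle(adj)) {
    "FEEDBACK_LOOP"
  } else {
    "OTHER"
  }
  gen <- character()
  if (fam != "FEEDFORWARD_LOOP" && contains_ffl(adj)) {
    gen <- c(gen, "FEEDFORWARD_LOOP")
  }
  if (fam != "BIFAN" && contains_bifan(adj)) {
    gen <- c(gen, "BIFAN")
  }
  motif$family <- fam
  motif$family_generalization_of <- gen
  motif
}

#' Construct a motif isomorphism class
#'
#' @param size Subgraph size, 3..6.
#' @param canonical_id Canonical id as returned by [canonical_id()].
#' @return A `motif_class` list with `size`, `canonical_id`,
#'   `adjacency_bits`, `family`, `family_generalization_of`.
#' @export
motif_class <- function(size, canonical_id) {
  if (!size %in% 3:6) pm_stop("motif size must be 3..6", "parameter")
  if (canonical_id < 0 || canonical_id >= 2^(size^2)) {
    pm_stop("canonical id out of range for this size", "input")
  }
  name_family(structure(list(
    size = as.integer(size), canonical_id = as.numeric(canonical_id),
    adjacency_bits = adjacency_bits_string(canonical_id, size),
    family = NA_character_, family_generalization_of = character()
  ), class = "motif_class"))
}

check_motif_size <- function(k, max_k = 6) {
  if (length(k) != 1 || is.na(k) || k < 3 || k > max_k) {
    pm_stop(sprintf("motif size must be in 3..%d", max_k), "parameter")
  }
  as.integer(k)
}

#' Enumerate connected k-node induced subgraphs
#'
#' ESU enumeration: every k-node subset whose induced subgraph is weakly
#' connected is visited exactly once, in deterministic order given the
#' (lexicographic) node ordering.
#'
#' @param net A `directed_network`.
#' @param k Subgraph size, 3..`max_k`.
#' @param max_k Upper size bound (default 6).
#' @return A list of character vectors (sorted node ids), one per subset.
#' @export
enumerate_connected_subgraphs <- function(net, k, max_k = 6) {
  k <- check_motif_size(k, max_k)
  if (k > length(net$nodes)) return(list())
  m <- cpp_enumerate_subgraphs(length(net$nodes), edge_matrix(net), k)
  lapply(seq_len(nrow(m)), function(i) net$nodes[m[i, ]])
}

#' Census of connected k-node induced subgraphs by isomorphism class
#'
#' Counts every weakly connected induced k-node subgraph of the network,
#' aggregated by canonical id (FANMOD-style induced-occurrence semantics).
#'
#' @param net A `directed_network`.
#' @param k Subgraph size, 3..6.
#' @return A `subgraph_census`: a tibble with columns `size`,
#'   `canonical_id`, `adjacency_bits`, `family`, `count`, ordered by
#'   `canonical_id`; attribute `total` holds the total subgraph count.
#' @export
motif_census <- function(net, k) {
  k <- check_motif_size(k)
  if (k > length(net$nodes)) {
    res <- list(canonical_id = numeric(), count = numeric(), total = 0)
  } else {
    res <- cpp_motif_census(length(net$nodes), edge_matrix(net), k)
  }
  fams <- vapply(res$canonical_id,
                 function(id) motif_class(k, id)$family, "")
  out <- tibble::tibble(
    size = rep(k, length(res$canonical_id)),
    canonical_id = res$canonical_id,
    adjacency_bits = vapply(res$canonical_id, adjacency_bits_string, "",
                            k = k),
    family = fams,
    count = as.numeric(res$count)
  )
  attr(out, "total") <- res$total
  class(out) <- c("subgraph_census", class(out))
  out
}
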