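# Projection of the typed process description onto a simple directed graph,
# the substrate for motif analysis.

#' Construct a directed network
#'
#' A simple directed graph (no self-loops, no parallel edges) with optional
#' edge signs. Node order is lexicographic and edge rows are sorted, so two
#' equal networks are identical objects.
#'
#' @param nodes Character vector of node ids (isolated nodes allowed).
#' @param edges Data frame with columns `from`, `to` and optionally `sign`
#'   (`ACTIVATING`, `INHIBITING` or `NEUTRAL`; default `NEUTRAL`).
#' @return An object of class `directed_network`.
#' @export
directed_network <- function(nodes = character(), edges = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  if (!"sign" %in% names(edges)) edges$sign <- "NEUTRAL"
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      sign = as.character(edges$sign),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  if (any(edges$from == edges$to)) {
    pm_stop("self-loop in directed network", "integrity")
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    pm_stop("parallel edge in directed network", "integrity")
  }
  if (any(!edges$sign %in% EDGE_SIGNS)) {
    pm_stop("unknown edge sign", "integrity")
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a directed network
#' @param net A `directed_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

# integer edge matrix (1-based, node index in net$nodes) for the C++ core
edge_matrix <- function(net) {
  cbind(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes))
}

net_from_edge_matrix <- function(nodes, em, signs = NULL) {
  directed_network(nodes, data.frame(
    from = nodes[em[, 1]], to = nodes[em[, 2]],
    sign = if (is.null(signs)) "NEUTRAL" else signs,
    stringsAsFactors = FALSE))
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = TRUE, vertices = net$nodes)
}

#' Projection rules for graph construction
#'
#' Controls how typed reactions collapse into pairwise directed edges:
#' whether modifier arcs point at the reaction's products or reactants,
#' whether edge signs are retained (the motif stage ignores them either
#' way), whether isolated species are dropped, and whether the analysis is
#' restricted to the largest weakly connected component.
#'
#' @param modifier_targets `"PRODUCTS"` (default: a catalyst or inhibitor
#'   influences formation of the products) or `"REACTANTS"`.
#' @param keep_signs Keep `ACTIVATING`/`INHIBITING` edge signs (default
#'   `TRUE`).
#' @param drop_isolated Drop species that end up with no edges (default
#'   `TRUE`).
#' @param component_policy `"LARGEST_WEAK"` (default) or `"WHOLE"`.
#' @return A list of class `projection_rules`.
#' @export
projection_rules <- function(modifier_targets = c("PRODUCTS", "REACTANTS"),
                             keep_signs = TRUE, drop_isolated = TRUE,
                             component_policy = c("LARGEST_WEAK", "WHOLE")) {
  structure(list(
    modifier_targets = match.arg(modifier_targets),
    keep_signs = isTRUE(keep_signs),
    drop_isolated = isTRUE(drop_isolated),
    component_policy = match.arg(component_policy)
  ), class = "projection_rules")
}

#' Project a pathway model onto a directed graph
#'
#' Collapses every typed reaction into pairwise edges: each reactant points
#' at each product (so associations point subunits at the complex,
#' dissociations point the complex at its parts, and transcriptional
#' activations point regulators at the RNA), and each modifier points at the
#' reaction's products (or reactants, per `rules`). Edges from `INHIBITION`
#' reactions or `INHIBITION` modifier roles carry an inhibiting sign;
#' duplicate edges collapse, with sign conflicts resolving to `INHIBITING`
#' (reported via a message); self-pairs are skipped. Finally the component
#' policy is applied.
#'
#' @param model A valid `pathway_model`.
#' @param rules A [projection_rules()] object.
#' @return A `directed_network`.
#' @export
project_to_graph <- function(model, rules = projection_rules()) {
  validate_pathway_model(model)
  from <- character()
  to <- character()
  sign <- character()
  for (i in seq_len(nrow(model$interactions))) {
    ia <- model$interactions[i, ]
    r <- ia$reactant_ids[[1]]
    p <- ia$product_ids[[1]]
    base_sign <- if (ia$kind == "INHIBITION") "INHIBITING" else "ACTIVATING"
    if (length(r) && length(p)) {
      pairs <- expand.grid(src = r, dst = p, stringsAsFactors = FALSE)
      from <- c(from, pairs$src)
      to <- c(to, pairs$dst)
      sign <- c(sign, rep(base_sign, nrow(pairs)))
    }
    mods <- ia$modifiers[[1]]
    if (nrow(mods)) {
      targets <- if (rules$modifier_targets == "PRODUCTS") p else r
      if (length(targets)) {
        pairs <- expand.grid(src = mods$species_id, dst = targets,
                             stringsAsFactors = FALSE)
        msign <- ifelse(rep(mods$role, times = length(targets)) ==
                          "INHIBITION", "INHIBITING", "ACTIVATING")
        from <- c(from, pairs$src)
        to <- c(to, pairs$dst)
        sign <- c(sign, msign)
      }
    }
  }
  keep <- from != to
  from <- from[keep]; to <- to[keep]; sign <- sign[keep]
  if (!rules$keep_signs) sign <- rep("NEUTRAL", length(sign))

  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(sign, key, function(s) {
      if (length(unique(s)) > 1) "CONFLICT" else s[1]
    })
    n_conf <- sum(agg == "CONFLICT")
    if (n_conf > 0) {
      message(sprintf(
        "%d duplicate edge(s) with conflicting sign resolved to INHIBITING",
        n_conf))
    }
    first <- !duplicated(key)
    from <- from[first]; to <- to[first]
    sign <- unname(agg[key[first]])
    sign[sign == "CONFLICT"] <- "INHIBITING"
  }

  nodes <- if (rules$drop_isolated) unique(c(from, to)) else model$species$id
  net <- directed_network(nodes, data.frame(from = from, to = to,
                                            sign = sign,
                                            stringsAsFactors = FALSE))
  if (rules$component_policy == "LARGEST_WEAK") {
    net <- largest_weak_component(net)
  }
  net
}

#' Largest weakly connected component
#'
#' Induced subgraph on the largest weakly connected node set; among
#' same-size components the one containing the lexicographically smallest
#' node id wins.
#'
#' @param net A `directed_network`.
#' @return A `directed_network` (empty input passes through).
#' @export
largest_weak_component <- function(net) {
  if (length(net$nodes) == 0) return(net)
  comp <- igraph::components(as_igraph(net), mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie-break: component holding the smallest node id (nodes are sorted)
    first_member <- vapply(best, function(b) {
      min(which(comp$membership == b))
    }, 0L)
    best <- best[which.min(first_member)]
  }
  keep <- net$nodes[comp$membership == best]
  sel <- net$edges$from %in% keep & net$edges$to %in% keep
  directed_network(keep, net$edges[sel, , drop = FALSE])
}

#' Read / write a directed network as a TSV edge list
#'
#' The format keeps isolated nodes alive: one `#node <id>` header line per
#' node, then `source<TAB>target<TAB>sign` data rows. Writing then reading
#' reproduces the network exactly.
#'
#' @param net A `directed_network`.
#' @param path File path.
#' @return `write_edge_list()` returns `path` invisibly;
#'   `read_edge_list()` returns a `directed_network`.
#' @export
write_edge_list <- function(net, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) pm_stop(
                    sprintf("cannot write %s", path), "io"))
  on.exit(close(con))
  writeLines(c(paste0("#node ", net$nodes),
               paste(net$edges$from, net$edges$to, net$edges$sign,
                     sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) pm_stop(sprintf("file not found: %s", path), "input")
  lines <- readLines(path, encoding = "UTF-8")
  node_lines <- grepl("^#node ", lines)
  nodes <- sub("^#node ", "", lines[node_lines])
  data <- lines[!node_lines & nzchar(lines)]
  if (length(data) == 0) return(directed_network(nodes))
  parts <- strsplit(data, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2)
  if (length(bad)) {
    pm_stop(sprintf("malformed edge row at line %d",
                    which(!node_lines & nzchar(lines))[bad[1]]), "format")
  }
  directed_network(nodes, data.frame(
    from = vapply(parts, `[`, "", 1),
    to = vapply(parts, `[`, "", 2),
    sign = vapply(parts, function(p) {
      if (length(p) >= 3) p[3] else "NEUTRAL"
    }, ""),
    stringsAsFactors = FALSE))
}
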