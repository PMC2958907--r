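# Degree-preserving null ensemble and the z-score / empirical p-value
# enrichment criterion.

#' Randomization configuration for motif enrichment
#'
#' Defaults reproduce the published criterion: motifs with z-score > 2 and
#' empirical p-value < 0.005 in 1000 degree-preserving shuffled networks are
#' called significantly over-represented.
#'
#' @param n_random Ensemble size (default 1000).
#' @param swaps_per_edge Attempted edge-pair switches per edge per replicate
#'   (Q, default 10).
#' @param seed Integer seed; every ensemble replicate derives its own RNG
#'   stream from `(seed, replicate index)`.
#' @param z_threshold Significance threshold on the z-score (default 2).
#' @param p_threshold Significance threshold on the empirical p-value
#'   (default 0.005).
#' @return A list of class `randomization_config`.
#' @export
randomization_config <- function(n_random = 1000, swaps_per_edge = 10,
                                 seed = 1, z_threshold = 2,
                                 p_threshold = 0.005) {
  stopifnot(n_random >= 1, swaps_per_edge >= 1)
  structure(list(
    n_random = as.integer(n_random),
    swaps_per_edge = as.integer(swaps_per_edge),
    seed = as.numeric(seed),
    z_threshold = as.numeric(z_threshold),
    p_threshold = as.numeric(p_threshold)
  ), class = "randomization_config")
}

#' Degree-preserving edge-switch randomization
#'
#' Performs `swaps_per_edge * n_edges` attempted pair switches
#' `(a->b, c->d) -> (a->d, c->b)`, rejecting any switch that would create a
#' self-loop or a parallel edge, so every node keeps its exact in- and
#' out-degree. Reproducible from `(config$seed, stream_index)`.
#'
#' @param net A `directed_network`.
#' @param config A [randomization_config()].
#' @param stream_index Replicate index (>= 1); distinct indices give
#'   independent, reproducible streams.
#' @return A `directed_network` with the same degree sequences. If no switch
#'   was ever accepted the input is returned unchanged with a message.
#' @export
switch_randomize <- function(net, config = randomization_config(),
                             stream_index = 1) {
  if (n_edges(net) < 2) {
    message("graph admits no valid switch; returned unchanged")
    return(net)
  }
  res <- cpp_switch_randomize(length(net$nodes), edge_matrix(net),
                              config$swaps_per_edge, config$seed,
                              stream_index)
  if (res$accepted == 0) {
    message("graph admits no valid switch; returned unchanged")
    return(net)
  }
  net_from_edge_matrix(net$nodes, res$edges)
}

#' Motif enrichment against the degree-preserving null ensemble
#'
#' Censuses the real graph at size `k`, then each of `n_random` switched
#' replicates, and scores every class observed in the real graph with
#' `z = (count_real - mean_random) / sd_random` (population sd over the
#' ensemble) and the one-sided empirical p-value (fraction of replicates
#' whose count meets or exceeds the real count, no smoothing). A class is
#' significant when `z > z_threshold` and `p < p_threshold`. When the
#' ensemble is degenerate (`sd = 0`): equal counts give `z = 0`, not
#' significant; a strictly larger real count gives `z = Inf` with
#' significance decided by the p-value alone.
#'
#' @param net A `directed_network`.
#' @param k Motif size, 3..6.
#' @param config A [randomization_config()].
#' @return A tibble with one row per motif class observed in the real
#'   graph, columns `size`, `canonical_id`, `adjacency_bits`, `family`,
#'   `count_real`, `frequency_percent`, `mean_random`, `sd_random`,
#'   `z_score`, `p_value`, `significant`, ordered by `z_score` descending
#'   (ties by `canonical_id` ascending).
#' @export
motif_enrichment <- function(net, k, config = randomization_config()) {
  k <- check_motif_size(k)
  if (k > length(net$nodes) || n_edges(net) == 0) {
    return(empty_enrichment(k))
  }
  res <- cpp_enrichment_counts(length(net$nodes), edge_matrix(net), k,
                               config$n_random, config$swaps_per_edge,
                               config$seed)
  nc <- length(res$canonical_id)
  if (nc == 0) return(empty_enrichment(k))
  ens <- res$ensemble
  mean_r <- colMeans(ens)
  sd_r <- sqrt(colMeans(ens^2) - mean_r^2)  # population sd
  sd_r[sd_r < 0] <- 0
  count_real <- res$count_real
  z <- ifelse(sd_r > 0, (count_real - mean_r) / sd_r,
              ifelse(count_real > mean_r, Inf, 0))
  p <- vapply(seq_len(nc), function(i) {
    mean(ens[, i] >= count_real[i])
  }, 0)
  sig <- ifelse(is.infinite(z), p < config$p_threshold,
                z > config$z_threshold & p < config$p_threshold)
  fams <- vapply(res$canonical_id,
                 function(id) motif_class(k, id)$family, "")
  out <- tibble::tibble(
    size = rep(k, nc),
    canonical_id = res$canonical_id,
    adjacency_bits = vapply(res$canonical_id, adjacency_bits_string, "",
                            k = k),
    family = fams,
    count_real = as.numeric(count_real),
    frequency_percent = 100 * count_real / max(res$total_real, 1),
    mean_random = mean_r,
    sd_random = sd_r,
    z_score = z,
    p_value = p,
    significant = as.logical(sig)
  )
  out[order(-out$z_score, out$canonical_id), ]
}

empty_enrichment <- function(k) {
  tibble::tibble(
    size = integer(), canonical_id = numeric(), adjacency_bits = character(),
    family = character(), count_real = numeric(),
    frequency_percent = numeric(), mean_random = numeric(),
    sd_random = numeric(), z_score = numeric(), p_value = numeric(),
    significant = logical()
  )
}
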