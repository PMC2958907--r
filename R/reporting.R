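# Machine-readable reports mirroring a curated knowledgebase's per-node
# annotation pages: for every species, the interactions it participates in
# (with its role) and the pooled literature references.

#' Per-node annotation report
#'
#' One record per species, ordered by node id. Each record lists exactly
#' the interactions referencing the node (with role reactant / product /
#' modifier) and the de-duplicated, ascending union of the node's own PMIDs
#' and the PMIDs of those interactions.
#'
#' @param model A valid `pathway_model`.
#' @return A tibble with columns `node_id`, `display_name`, `gene_ids`
#'   (list), `interactions` (list of data frames with `interaction_id`,
#'   `kind`, `role`), `pmids` (list).
#' @export
annotation_report <- function(model) {
  validate_pathway_model(model)
  sp <- model$species
  ia <- model$interactions
  # membership index: species -> (interaction, role) rows
  links <- list()
  add_link <- function(ids, i, role) {
    for (s in ids) {
      links[[s]] <<- rbind(links[[s]], data.frame(
        interaction_id = ia$id[i], kind = ia$kind[i], role = role,
        stringsAsFactors = FALSE))
    }
  }
  for (i in seq_len(nrow(ia))) {
    add_link(ia$reactant_ids[[i]], i, "reactant")
    add_link(ia$product_ids[[i]], i, "product")
    add_link(ia$modifiers[[i]]$species_id, i, "modifier")
  }
  empty_links <- data.frame(interaction_id = character(), kind = character(),
                            role = character(), stringsAsFactors = FALSE)
  ia_pmids <- stats::setNames(ia$pmids, ia$id)
  ord <- order(sp$id)
  tibble::tibble(
    node_id = sp$id[ord],
    display_name = sp$display_name[ord],
    gene_ids = sp$gene_ids[ord],
    interactions = lapply(sp$id[ord], function(s) {
      lk <- links[[s]]
      if (is.null(lk)) empty_links else lk
    }),
    pmids = lapply(ord, function(j) {
      lk <- links[[sp$id[j]]]
      extra <- if (is.null(lk)) integer() else
        unlist(ia_pmids[unique(lk$interaction_id)])
      sort(unique(c(sp$pmids[[j]], extra)))
    })
  )
}

#' Write census, enrichment and annotation reports
#'
#' Serializes a [census()] report to `census.json` (exact field names),
#' enrichment rows to `enrichment.tsv` (sorted by z-score descending, ties
#' by canonical id ascending) and the [annotation_report()] to
#' `annotations.json`. Output is a pure function of the inputs:
#' byte-identical across runs. The companion readers
#' [read_census_json()], [read_enrichment_tsv()] and
#' [read_annotations_json()] reproduce the inputs.
#'
#' @param census_report A `census_report`.
#' @param enrichment_rows A tibble from [motif_enrichment()] (possibly row
#'   bound over several sizes).
#' @param annotations A tibble from [annotation_report()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_reports <- function(census_report, enrichment_rows, annotations,
                          out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) {
    pm_stop(sprintf("cannot create output directory %s", out_dir), "io")
  }
  paths <- c(census = file.path(out_dir, "census.json"),
             enrichment = file.path(out_dir, "enrichment.tsv"),
             annotations = file.path(out_dir, "annotations.json"))

  jsonlite::write_json(unclass(census_report), paths["census"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  er <- enrichment_rows[order(-enrichment_rows$z_score,
                              enrichment_rows$canonical_id), ]
  er$z_score <- ifelse(is.infinite(er$z_score), "Inf",
                       format(er$z_score, digits = 15, trim = TRUE,
                              scientific = FALSE))
  utils::write.table(er, paths["enrichment"], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  ann <- lapply(seq_len(nrow(annotations)), function(i) {
    list(
      node_id = annotations$node_id[i],
      display_name = annotations$display_name[i],
      gene_ids = as.integer(annotations$gene_ids[[i]]),
      interactions = annotations$interactions[[i]],
      pmids = as.integer(annotations$pmids[[i]])
    )
  })
  jsonlite::write_json(ann, paths["annotations"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read back serialized reports
#'
#' @param path File written by [write_reports()].
#' @return `read_census_json()`: a `census_report`;
#'   `read_enrichment_tsv()`: an enrichment tibble;
#'   `read_annotations_json()`: an annotation tibble.
#' @export
read_census_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(
    n_species = as.integer(x$n_species),
    n_interactions = as.integer(x$n_interactions),
    species_by_class = lapply(x$species_by_class, as.integer),
    interactions_by_kind = lapply(x$interactions_by_kind, as.integer),
    n_protein_species = as.integer(x$n_protein_species),
    n_unique_pmids = as.integer(x$n_unique_pmids),
    n_unique_gene_ids = as.integer(x$n_unique_gene_ids)
  ), class = "census_report")
}

#' @rdname read_census_json
#' @export
read_enrichment_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(adjacency_bits = "character"))
  if (nrow(df) == 0) return(empty_enrichment(3)[0, ])
  df$z_score <- as.numeric(df$z_score)
  df$significant <- as.logical(df$significant)
  tibble::as_tibble(df)
}

#' @rdname read_census_json
#' @export
read_annotations_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  empty_links <- data.frame(interaction_id = character(), kind = character(),
                            role = character(), stringsAsFactors = FALSE)
  tibble::tibble(
    node_id = vapply(x, function(r) r$node_id, ""),
    display_name = vapply(x, function(r) r$display_name, ""),
    gene_ids = lapply(x, function(r) as.integer(unlist(r$gene_ids))),
    interactions = lapply(x, function(r) {
      if (length(r$interactions) == 0) return(empty_links)
      do.call(rbind, lapply(r$interactions, function(l) {
        data.frame(interaction_id = l$interaction_id, kind = l$kind,
                   role = l$role, stringsAsFactors = FALSE)
      }))
    }),
    pmids = lapply(x, function(r) as.integer(unlist(r$pmids)))
  )
}
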