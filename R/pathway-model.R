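#' Build a single species record
#'
#' A species is one node of the process diagram: a protein, receptor,
#' truncated protein, RNA, gene, complex, small molecule or phenotype,
#' optionally carrying an activity flag, post-translational modifications,
#' and PubMed / NCBI Gene annotations.
#'
#' @param id Unique species identifier (non-empty string).
#' @param display_name Human-readable name; defaults to `id`.
#' @param entity_class One of `r paste(ENTITY_CLASSES, collapse = ", ")`.
#' @param compartment One of the map's compartments
#'   (`r paste(COMPARTMENTS, collapse = ", ")`).
#' @param active Logical; whether the species is drawn in its active state.
#' @param modifications Character vector, subset of
#'   `c("PHOSPHORYLATED", "UBIQUITINATED")`.
#' @param gene_ids Integer vector of NCBI Gene identifiers (no duplicates).
#' @param pmids Integer vector of PubMed identifiers (no duplicates).
#' @return A one-row tibble suitable for the `species` slot of
#'   [pathway_model()].
#' @export
species_node <- function(id, display_name = id, entity_class = "PROTEIN",
                         compartment = "cytoplasm", active = FALSE,
                         modifications = character(),
                         gene_ids = integer(), pmids = integer()) {
  tibble::tibble(
    id = as.character(id),
    display_name = as.character(display_name),
    entity_class = as.character(entity_class),
    compartment = as.character(compartment),
    active = as.logical(active),
    modifications = list(as.character(modifications)),
    gene_ids = list(as.integer(gene_ids)),
    pmids = list(as.integer(pmids))
  )
}

#' Build a single interaction record
#'
#' An interaction is one typed reaction of the process diagram. Catalysis is
#' not a kind of its own: it is a modifier role (usually on a state
#' transition), mirroring how curated maps count catalysed reactions among
#' state transitions.
#'
#' @param id Unique interaction identifier.
#' @param kind One of `r paste(INTERACTION_KINDS, collapse = ", ")`.
#' @param reactant_ids,product_ids Character vectors of species ids; not both
#'   empty.
#' @param modifiers A data frame with columns `species_id` and `role`
#'   (`CATALYSIS`, `INHIBITION` or `UNKNOWN`), or `NULL`.
#' @param pmids Integer vector of PubMed identifiers.
#' @param direct_known Logical; `FALSE` marks the map's question-mark
#'   uncertainty about the mechanism being direct.
#' @return A one-row tibble suitable for the `interactions` slot of
#'   [pathway_model()].
#' @export
interaction_record <- function(id, kind, reactant_ids = character(),
                               product_ids = character(), modifiers = NULL,
                               pmids = integer(), direct_known = TRUE) {
  if (is.null(modifiers)) {
    modifiers <- data.frame(species_id = character(), role = character(),
                            stringsAsFactors = FALSE)
  }
  tibble::tibble(
    id = as.character(id),
    kind = as.character(kind),
    reactant_ids = list(as.character(reactant_ids)),
    product_ids = list(as.character(product_ids)),
    modifiers = list(modifiers),
    pmids = list(as.integer(pmids)),
    direct_known = as.logical(direct_known)
  )
}

#' Assemble and validate a pathway model
#'
#' The in-memory form of a CellDesigner-style SBML pathway map: typed
#' species plus typed interactions with modifier arcs and literature
#' annotations. All referential-integrity invariants are checked on
#' construction.
#'
#' @param name Model name.
#' @param species Tibble of species rows, as built by [species_node()].
#' @param interactions Tibble of interaction rows, as built by
#'   [interaction_record()].
#' @param source_path Optional path the model was read from.
#' @return An object of class `pathway_model`.
#' @seealso [read_celldesigner_sbml()], [census()], [project_to_graph()]
#' @export
pathway_model <- function(name, species, interactions, source_path = NULL) {
  if (is.null(species) || nrow(species) == 0) {
    species <- species_node("..dummy")[0, ]
  }
  if (is.null(interactions) || nrow(interactions) == 0) {
    interactions <- interaction_record("..dummy", "STATE_TRANSITION",
                                       reactant_ids = "x")[0, ]
  }
  model <- structure(
    list(name = as.character(name), species = tibble::as_tibble(species),
         interactions = tibble::as_tibble(interactions),
         source_path = source_path),
    class = "pathway_model"
  )
  validate_pathway_model(model)
  model
}

#' Validate pathway-model invariants
#'
#' Checks id uniqueness, enum membership, referential integrity of every
#' reactant/product/modifier reference, non-empty endpoint lists, and
#' duplicate-free annotation lists. Called by [pathway_model()]; exported so
#' programmatically edited models can be re-checked.
#'
#' @param model A `pathway_model`.
#' @return The model, invisibly, if valid; otherwise an integrity error.
#' @export
validate_pathway_model <- function(model) {
  sp <- model$species
  ia <- model$interactions
  if (any(!nzchar(sp$id))) pm_stop("species with empty id", "integrity")
  if (anyDuplicated(sp$id)) {
    pm_stop(sprintf("duplicate species id: %s",
                    sp$id[duplicated(sp$id)][1]), "integrity")
  }
  if (anyDuplicated(ia$id)) {
    pm_stop(sprintf("duplicate interaction id: %s",
                    ia$id[duplicated(ia$id)][1]), "integrity")
  }
  bad <- setdiff(sp$entity_class, ENTITY_CLASSES)
  if (length(bad)) {
    pm_stop(sprintf("unknown entity class: %s", bad[1]), "integrity")
  }
  bad <- setdiff(ia$kind, INTERACTION_KINDS)
  if (length(bad)) {
    pm_stop(sprintf("unknown interaction kind: %s", bad[1]), "integrity")
  }
  for (col in c("gene_ids", "pmids")) {
    if (any(vapply(sp[[col]], anyDuplicated, 0L) > 0L)) {
      pm_stop(sprintf("duplicate entries in species %s", col), "integrity")
    }
  }
  known <- sp$id
  for (i in seq_len(nrow(ia))) {
    r <- ia$reactant_ids[[i]]
    p <- ia$product_ids[[i]]
    m <- ia$modifiers[[i]]$species_id
    if (length(r) == 0 && length(p) == 0) {
      pm_stop(sprintf("interaction %s has neither reactants nor products",
                      ia$id[i]), "integrity")
    }
    dangling <- setdiff(c(r, p, m), known)
    if (length(dangling)) {
      pm_stop(sprintf("interaction %s references unknown species %s",
                      ia$id[i], dangling[1]), "integrity")
    }
    roles <- ia$modifiers[[i]]$role
    if (length(roles) && any(!roles %in% MODIFIER_ROLES)) {
      pm_stop(sprintf("interaction %s has unknown modifier role", ia$id[i]),
              "integrity")
    }
  }
  invisible(model)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("<pathway_model> %s: %d species, %d interactions\n",
              x$name, nrow(x$species), nrow(x$interactions)))
  invisible(x)
}

#' Census of a pathway model
#'
#' Deterministic composition counts of the kind curated-map papers print:
#' totals, species by entity class, interactions by kind, the number of
#' protein species (proteins + receptors + truncated proteins), and the
#' number of distinct PubMed and Gene identifiers. Unique PMIDs are taken
#' over the union of species-level and interaction-level annotations.
#'
#' @param model A `pathway_model`.
#' @return An object of class `census_report`: a list with fields
#'   `n_species`, `n_interactions`, `species_by_class`,
#'   `interactions_by_kind`, `n_protein_species`, `n_unique_pmids`,
#'   `n_unique_gene_ids`.
#' @export
census <- function(model) {
  validate_pathway_model(model)
  sp <- model$species
  ia <- model$interactions
  by_class <- vapply(ENTITY_CLASSES,
                     function(cl) sum(sp$entity_class == cl), 0L)
  by_kind <- vapply(INTERACTION_KINDS,
                    function(kd) sum(ia$kind == kd), 0L)
  pmids <- unique(c(unlist(sp$pmids), unlist(ia$pmids)))
  gids <- unique(unlist(sp$gene_ids))
  structure(list(
    n_species = nrow(sp),
    n_interactions = nrow(ia),
    species_by_class = as.list(by_class),
    interactions_by_kind = as.list(by_kind),
    n_protein_species = sum(by_class[PROTEIN_CLASSES]),
    n_unique_pmids = length(pmids),
    n_unique_gene_ids = length(gids)
  ), class = "census_report")
}

#' @export
print.census_report <- function(x, ...) {
  cat(sprintf("<census_report> %d species / %d interactions\n",
              x$n_species, x$n_interactions))
  cat(sprintf("  protein species: %d; unique PMIDs: %d; unique GeneIDs: %d\n",
              x$n_protein_species, x$n_unique_pmids, x$n_unique_gene_ids))
  cls <- Filter(function(v) v > 0, x$species_by_class)
  kds <- Filter(function(v) v > 0, x$interactions_by_kind)
  cat("  species:", paste(names(cls), unlist(cls), sep = "=",
                          collapse = ", "), "\n")
  cat("  interactions:", paste(names(kds), unlist(kds), sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}
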