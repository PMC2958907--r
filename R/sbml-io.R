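# CellDesigner-flavoured SBML Level 2 I/O.
#
# The reader is deliberately tolerant: curated maps are edited with several
# CellDesigner versions whose annotation dialects differ, so class / type
# tags are matched case-insensitively anywhere inside the CellDesigner
# extension (namespace-agnostic XPath), protein subtypes are resolved
# through proteinReference -> listOfProteins, and unrecognised tags degrade
# to UNKNOWN / UNKNOWN_TRANSITION instead of erroring. The writer emits one
# canonical dialect that the reader round-trips.

CD_NS <- "http://www.sbml.org/2001/ns/celldesigner"
SBML_NS <- "http://www.sbml.org/sbml/level2/version4"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# all first capture groups of `pattern` in `text`, as unique integers in
# order of appearance
extract_ints <- function(text, patterns) {
  out <- integer()
  for (pat in patterns) {
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    cs <- attr(m, "capture.start")[, 1]
    cl <- attr(m, "capture.length")[, 1]
    out <- c(out, as.integer(substring(text, cs, cs + cl - 1)))
  }
  unique(out)
}

PMID_PATTERNS <- c("(?i)pmid[\\s:=]{0,3}([0-9]+)", "(?i)pubmed/([0-9]+)",
                   "(?i)list_uids=([0-9]+)")
GENEID_PATTERNS <- c("(?i)gene\\s?id[\\s:=]{0,3}([0-9]+)",
                     "(?i)ncbi\\.nlm\\.nih\\.gov/gene/([0-9]+)")

ln1 <- function(node, name) {
  xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']", name))
}
ln_all <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

#' Read a CellDesigner-flavoured SBML pathway map
#'
#' Parses an SBML Level 2 document with CellDesigner extension annotations
#' into a [pathway_model()]. Entity classes are taken from the
#' `speciesIdentity` class tag (with protein subtypes `RECEPTOR` and
#' `TRUNCATED` resolved through the protein reference table); reaction kinds
#' from the `reactionType` tag; PubMed and NCBI Gene identifiers are
#' harvested from annotation and notes text by pattern extraction. Species
#' without a recognisable class become `UNKNOWN`; reactions without a
#' recognisable type become `UNKNOWN_TRANSITION`.
#'
#' @param path Path to an SBML (XML) file.
#' @return A validated `pathway_model`.
#' @export
read_celldesigner_sbml <- function(path) {
  if (!file.exists(path)) {
    pm_stop(sprintf("file not found: %s", path), "input")
  }
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) pm_stop(
                    sprintf("not well-formed XML: %s", conditionMessage(e)),
                    "format"))
  root <- xml2::xml_root(doc)
  model_node <- xml2::xml_find_first(
    root, "./*[local-name()='model']")
  if (is.na(xml2::xml_name(model_node)) ||
      tolower(xml2::xml_name(root)) != "sbml") {
    pm_stop("document contains no SBML model element", "format")
  }

  # protein subtype table (id -> RECEPTOR / TRUNCATED / GENERIC)
  prot_nodes <- xml2::xml_find_all(
    model_node,
    "./*[local-name()='annotation']//*[local-name()='protein']")
  prot_type <- stats::setNames(
    toupper(xml2::xml_attr(prot_nodes, "type")),
    xml2::xml_attr(prot_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(
    model_node,
    "./*[local-name()='listOfSpecies']/*[local-name()='species']")
  species <- do.call(rbind, lapply(seq_along(sp_nodes), function(i) {
    nd <- sp_nodes[[i]]
    id <- xml2::xml_attr(nd, "id")
    name <- xml2::xml_attr(nd, "name")
    if (is.na(name) || !nzchar(name)) name <- id
    cls_node <- ln1(nd, "class")
    cls <- if (is.na(xml2::xml_name(cls_node))) "" else
      toupper(trimws(xml2::xml_text(cls_node)))
    if (cls == "PROTEIN") {
      ref <- ln1(nd, "proteinReference")
      if (!is.na(xml2::xml_name(ref))) {
        pt <- prot_type[trimws(xml2::xml_text(ref))]
        if (!is.na(pt) && pt == "RECEPTOR") cls <- "RECEPTOR"
        if (!is.na(pt) && grepl("TRUNCATED", pt)) cls <- "TRUNCATED_PROTEIN"
      }
    }
    if (cls %in% c("TRUNCATED", "TRUNCATED PROTEIN")) cls <- "TRUNCATED_PROTEIN"
    if (cls %in% c("SIMPLEMOLECULE", "SIMPLE MOLECULE")) cls <- "SIMPLE_MOLECULE"
    if (!cls %in% ENTITY_CLASSES) cls <- "UNKNOWN"
    comp <- xml2::xml_attr(nd, "compartment")
    if (is.na(comp) || !comp %in% COMPARTMENTS) comp <- "cytoplasm"
    act_node <- ln1(nd, "activity")
    active <- !is.na(xml2::xml_name(act_node)) &&
      tolower(trimws(xml2::xml_text(act_node))) == "active"
    mods <- ln_all(nd, "modification")
    states <- toupper(xml2::xml_attr(mods, "state"))
    states <- intersect(unique(states[!is.na(states)]), MODIFICATION_STATES)
    txt <- xml2::xml_text(nd)
    species_node(
      id = id, display_name = name, entity_class = cls, compartment = comp,
      active = active, modifications = states,
      gene_ids = extract_ints(txt, GENEID_PATTERNS),
      pmids = extract_ints(txt, PMID_PATTERNS)
    )
  }))

  rx_nodes <- xml2::xml_find_all(
    model_node,
    "./*[local-name()='listOfReactions']/*[local-name()='reaction']")
  interactions <- do.call(rbind, lapply(seq_along(rx_nodes), function(i) {
    nd <- rx_nodes[[i]]
    id <- xml2::xml_attr(nd, "id")
    if (is.na(id)) id <- sprintf("re%d", i)
    kt_node <- ln1(nd, "reactionType")
    kind <- if (is.na(xml2::xml_name(kt_node))) "" else
      toupper(trimws(xml2::xml_text(kt_node)))
    if (kind %in% c("TRANSCRIPTION", "TRANSCRIPTIONALACTIVATION")) {
      kind <- "TRANSCRIPTIONAL_ACTIVATION"
    }
    if (kind %in% c("NEGATIVE_INFLUENCE", "INHIBITION")) kind <- "INHIBITION"
    if (!kind %in% INTERACTION_KINDS) kind <- "UNKNOWN_TRANSITION"
    reactants <- xml2::xml_attr(xml2::xml_find_all(
      nd, paste0("./*[local-name()='listOfReactants']",
                 "/*[local-name()='speciesReference']")), "species")
    products <- xml2::xml_attr(xml2::xml_find_all(
      nd, paste0("./*[local-name()='listOfProducts']",
                 "/*[local-name()='speciesReference']")), "species")
    mod_ids <- xml2::xml_attr(xml2::xml_find_all(
      nd, paste0("./*[local-name()='listOfModifiers']",
                 "/*[local-name()='modifierSpeciesReference']")), "species")
    # roles come from celldesigner modification elements keyed by species id
    role_nodes <- ln_all(nd, "modification")
    role_map <- character()
    for (rn in role_nodes) {
      tp <- toupper(xml2::xml_attr(rn, "type"))
      who <- xml2::xml_attr(rn, "modifiers")
      if (is.na(tp) || is.na(who)) next
      if (!tp %in% MODIFIER_ROLES) tp <- "UNKNOWN"
      for (w in strsplit(who, ",", fixed = TRUE)[[1]]) {
        role_map[trimws(w)] <- tp
      }
    }
    roles <- ifelse(mod_ids %in% names(role_map),
                    role_map[mod_ids], "UNKNOWN")
    txt <- xml2::xml_text(nd)
    interaction_record(
      id = id, kind = kind, reactant_ids = reactants, product_ids = products,
      modifiers = data.frame(species_id = mod_ids,
                             role = as.character(roles),
                             stringsAsFactors = FALSE),
      pmids = extract_ints(txt, PMID_PATTERNS),
      direct_known = !grepl("question mark", txt, ignore.case = TRUE)
    )
  }))

  name <- xml2::xml_attr(model_node, "name")
  if (is.na(name)) name <- xml2::xml_attr(model_node, "id")
  if (is.na(name)) name <- "model"
  pathway_model(name = name, species = species, interactions = interactions,
                source_path = path)
}

#' Write a pathway model as CellDesigner-flavoured SBML
#'
#' Emits SBML Level 2 with CellDesigner-style annotations: species classes
#' in `speciesIdentity` (receptors and truncated proteins via the protein
#' reference table), reaction kinds in `reactionType`, modifier roles in
#' reaction-level `modification` elements, and PMID / GeneID annotations as
#' notes text. `read(write(m))` preserves counts, classes, kinds and
#' annotation lists; output is byte-deterministic.
#'
#' @param model A valid `pathway_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_celldesigner_sbml <- function(model, path) {
  validate_pathway_model(model)
  sp <- model$species
  ia <- model$interactions
  L <- character()
  add <- function(...) L[[length(L) + 1]] <<- paste0(...)

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(sprintf('<sbml xmlns="%s" xmlns:celldesigner="%s" level="2" version="4">',
              SBML_NS, CD_NS))
  add(sprintf('  <model id="model_1" name="%s">', xml_escape(model$name)))

  # protein reference table for receptor / truncated subtypes
  add("    <annotation>")
  add("      <celldesigner:extension>")
  add("        <celldesigner:listOfProteins>")
  for (i in seq_len(nrow(sp))) {
    if (sp$entity_class[i] %in% PROTEIN_CLASSES) {
      tp <- switch(sp$entity_class[i], RECEPTOR = "RECEPTOR",
                   TRUNCATED_PROTEIN = "TRUNCATED", "GENERIC")
      add(sprintf('          <celldesigner:protein id="pr_%s" name="%s" type="%s"/>',
                  xml_escape(sp$id[i]), xml_escape(sp$display_name[i]), tp))
    }
  }
  add("        </celldesigner:listOfProteins>")
  add("      </celldesigner:extension>")
  add("    </annotation>")

  add("    <listOfCompartments>")
  for (cm in COMPARTMENTS) {
    add(sprintf('      <compartment id="%s" name="%s"/>', cm, cm))
  }
  add("    </listOfCompartments>")

  add("    <listOfSpecies>")
  for (i in seq_len(nrow(sp))) {
    add(sprintf('      <species id="%s" name="%s" compartment="%s">',
                xml_escape(sp$id[i]), xml_escape(sp$display_name[i]),
                sp$compartment[i]))
    add("        <annotation>")
    add("          <celldesigner:extension>")
    add("            <celldesigner:speciesIdentity>")
    cls <- sp$entity_class[i]
    wcls <- if (cls %in% PROTEIN_CLASSES) "PROTEIN" else cls
    add(sprintf("              <celldesigner:class>%s</celldesigner:class>",
                wcls))
    if (cls %in% PROTEIN_CLASSES) {
      add(sprintf("              <celldesigner:proteinReference>pr_%s</celldesigner:proteinReference>",
                  xml_escape(sp$id[i])))
    }
    add("            </celldesigner:speciesIdentity>")
    add(sprintf("            <celldesigner:activity>%s</celldesigner:activity>",
                if (isTRUE(sp$active[i])) "active" else "inactive"))
    mods <- sp$modifications[[i]]
    if (length(mods)) {
      add("            <celldesigner:listOfModifications>")
      for (md in mods) {
        add(sprintf('              <celldesigner:modification state="%s"/>',
                    tolower(md)))
      }
      add("            </celldesigner:listOfModifications>")
    }
    add("          </celldesigner:extension>")
    add("        </annotation>")
    notes <- annotation_notes(sp$pmids[[i]], sp$gene_ids[[i]], TRUE)
    if (nzchar(notes)) {
      add("        <notes>")
      add(sprintf('          <body xmlns="http://www.w3.org/1999/xhtml">%s</body>',
                  xml_escape(notes)))
      add("        </notes>")
    }
    add("      </species>")
  }
  add("    </listOfSpecies>")

  add("    <listOfReactions>")
  for (i in seq_len(nrow(ia))) {
    add(sprintf('      <reaction id="%s" reversible="false">',
                xml_escape(ia$id[i])))
    add("        <annotation>")
    add("          <celldesigner:extension>")
    add(sprintf("            <celldesigner:reactionType>%s</celldesigner:reactionType>",
                ia$kind[i]))
    mods <- ia$modifiers[[i]]
    if (nrow(mods)) {
      add("            <celldesigner:listOfModification>")
      for (j in seq_len(nrow(mods))) {
        add(sprintf('              <celldesigner:modification type="%s" modifiers="%s"/>',
                    mods$role[j], xml_escape(mods$species_id[j])))
      }
      add("            </celldesigner:listOfModification>")
    }
    add("          </celldesigner:extension>")
    add("        </annotation>")
    notes <- annotation_notes(ia$pmids[[i]], integer(), ia$direct_known[i])
    if (nzchar(notes)) {
      add("        <notes>")
      add(sprintf('          <body xmlns="http://www.w3.org/1999/xhtml">%s</body>',
                  xml_escape(notes)))
      add("        </notes>")
    }
    r <- ia$reactant_ids[[i]]
    if (length(r)) {
      add("        <listOfReactants>")
      for (s in r) add(sprintf('          <speciesReference species="%s"/>',
                               xml_escape(s)))
      add("        </listOfReactants>")
    }
    p <- ia$product_ids[[i]]
    if (length(p)) {
      add("        <listOfProducts>")
      for (s in p) add(sprintf('          <speciesReference species="%s"/>',
                               xml_escape(s)))
      add("        </listOfProducts>")
    }
    if (nrow(mods)) {
      add("        <listOfModifiers>")
      for (s in mods$species_id) {
        add(sprintf('          <modifierSpeciesReference species="%s"/>',
                    xml_escape(s)))
      }
      add("        </listOfModifiers>")
    }
    add("      </reaction>")
  }
  add("    </listOfReactions>")
  add("  </model>")
  add("</sbml>")

  txt <- unlist(L)
  # well-formedness check before touching disk
  tryCatch(xml2::read_xml(paste(txt, collapse = "\n")),
           error = function(e) pm_stop(
             sprintf("internal writer error: %s", conditionMessage(e)),
             "format"))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) pm_stop(
                    sprintf("cannot write %s: %s", path,
                            conditionMessage(e)), "io"))
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(path)
}

annotation_notes <- function(pmids, gene_ids, direct_known) {
  parts <- character()
  if (length(pmids)) {
    parts <- c(parts, paste0("PMID: ", paste(pmids, collapse = ", PMID: ")))
  }
  if (length(gene_ids)) {
    parts <- c(parts,
               paste0("GeneID: ", paste(gene_ids, collapse = ", GeneID: ")))
  }
  if (!isTRUE(direct_known)) {
    parts <- c(parts, "question mark: direct mechanism uncertain")
  }
  paste(parts, collapse = "; ")
}
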