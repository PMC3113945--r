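# SBML interoperability (Level 2/3 core subset: compartments, species,
# reactions; pathway grouping via the Level 3 groups extension or a two-column
# sidecar file). Built on xml2.

attrLocal <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

#' Import a network from SBML
#'
#' Maps SBML species to compounds and SBML reactions to reactions. SBML
#' compartment IDs are translated to the package's compartment vocabulary
#' (cytosol, periplasm, inner_membrane, outer_membrane) through
#' `compartmentMap`; an SBML compartment with no mapping is an error unless
#' `defaultCompartment` is given. Pathway membership is taken from Level 3
#' `groups` annotations when present, and/or from a sidecar file (two
#' tab-separated columns: reaction_id, pathway_id). Reactions without any
#' grouping get an empty pathway list (the unassigned grid).
#'
#' @param path SBML document path.
#' @param grouping optional sidecar file path.
#' @param compartmentMap named character vector, SBML compartment id ->
#'   package compartment. Identity mappings for the package vocabulary are
#'   always included.
#' @param defaultCompartment fallback compartment for unmapped SBML
#'   compartments, or `NULL` (strict).
#' @param organismId organism identifier for the resulting PGDB; defaults to
#'   the SBML model id (or "SBML-IMPORT").
#' @return a validated [PGDB-class].
#' @export
loadSBML <- function(path, grouping = NULL, compartmentMap = character(0),
                     defaultCompartment = NULL, organismId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(model))) stop("not an SBML document: no <model>", call. = FALSE)
  if (is.null(organismId)) {
    organismId <- attrLocal(model, "id")
    if (is.na(organismId) || !nzchar(organismId)) organismId <- "SBML-IMPORT"
  }

  cmap <- c(stats::setNames(REACTION_COMPARTMENTS, REACTION_COMPARTMENTS), compartmentMap)
  mapCompartment <- function(cid) {
    if (is.na(cid) || !nzchar(cid)) return(defaultCompartment %||% "cytosol")
    if (cid %in% names(cmap)) return(unname(cmap[[cid]]))
    if (!is.null(defaultCompartment)) return(defaultCompartment)
    stop("unmappable SBML compartment '", cid,
         "'; supply compartmentMap or defaultCompartment", call. = FALSE)
  }

  ents <- list()
  for (sp in xml2::xml_find_all(model, ".//listOfSpecies/species")) {
    id <- attrLocal(sp, "id")
    nm <- attrLocal(sp, "name"); if (is.na(nm) || !nzchar(nm)) nm <- id
    ents[[length(ents) + 1L]] <- newCompound(id, nm)
  }

  refVec <- function(rxn, listName) {
    refs <- xml2::xml_find_all(rxn, sprintf("./%s/speciesReference", listName))
    if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
    sp <- vapply(refs, attrLocal, "", name = "species")
    st <- vapply(refs, attrLocal, "", name = "stoichiometry")
    st <- ifelse(is.na(st), 1, as.numeric(st))
    agg <- tapply(st, sp, sum)  # merge duplicate species references
    stats::setNames(as.numeric(agg), names(agg))
  }

  memberships <- list()
  for (rxn in xml2::xml_find_all(model, ".//listOfReactions/reaction")) {
    id <- attrLocal(rxn, "id")
    nm <- attrLocal(rxn, "name"); if (is.na(nm) || !nzchar(nm)) nm <- id
    comp <- mapCompartment(attrLocal(rxn, "compartment"))
    ents[[length(ents) + 1L]] <- newReaction(
      id, nm, substrates = refVec(rxn, "listOfReactants"),
      products = refVec(rxn, "listOfProducts"), compartment = comp)
    memberships[[id]] <- character(0)
  }

  # Level 3 groups package: <group id kind> <listOfMembers> <member idRef>
  # (matched by local name: prefixed-namespace nodes survive xml_ns_strip)
  groupPathways <- list()
  for (g in xml2::xml_find_all(model, ".//*[local-name()='group']")) {
    gid <- attrLocal(g, "id")
    if (is.na(gid)) next
    gname <- attrLocal(g, "name"); if (is.na(gname) || !nzchar(gname)) gname <- gid
    members <- vapply(xml2::xml_find_all(g, ".//*[local-name()='member']"),
                      attrLocal, "", name = "idRef")
    members <- intersect(members, names(memberships))
    if (!length(members)) next
    groupPathways[[gid]] <- list(name = gname, reactions = members)
    for (m in members) memberships[[m]] <- union(memberships[[m]], gid)
  }

  if (!is.null(grouping)) {
    side <- utils::read.table(grouping, sep = "\t", header = FALSE,
                              col.names = c("reaction", "pathway"),
                              stringsAsFactors = FALSE, comment.char = "#")
    for (i in seq_len(nrow(side))) {
      rid <- side$reaction[i]; pid <- side$pathway[i]
      if (!rid %in% names(memberships))
        stop("sidecar references unknown reaction '", rid, "'", call. = FALSE)
      if (is.null(groupPathways[[pid]]))
        groupPathways[[pid]] <- list(name = pid, reactions = character(0))
      groupPathways[[pid]]$reactions <- union(groupPathways[[pid]]$reactions, rid)
      memberships[[rid]] <- union(memberships[[rid]], pid)
    }
  }

  # write memberships back onto reactions, then materialize pathway entities
  ents <- lapply(ents, function(e) {
    if (e$kind == "reaction") e$pathways <- memberships[[e$frameId]] %||% character(0)
    e
  })
  for (pid in names(groupPathways))
    ents[[length(ents) + 1L]] <- newPathway(pid, groupPathways[[pid]]$name,
                                            reactions = groupPathways[[pid]]$reactions,
                                            category = "other")
  newPGDB(organismId, ents)
}

xmlq <- function(x) gsub("\"", "&quot;",
                         gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", x))))

#' Export a network to SBML Level 3
#'
#' Writes compounds as species, reactions with stoichiometry and a reaction
#' `compartment` attribute using the package compartment vocabulary, and
#' pathway membership as Level 3 `groups`. Lossy for proteins/genes (outside
#' the SBML core subset used here); intended for interoperability round trips
#' of the species/reaction skeleton.
#'
#' @param pgdb a [PGDB-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportSBML <- function(pgdb, path) {
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:groups=\"http://www.sbml.org/sbml/level3/version1/groups/version1\" ",
           "level=\"3\" version=\"1\">"),
    sprintf("<model id=\"%s\">", xmlq(pgdb@organismId)),
    "<listOfCompartments>",
    sprintf("<compartment id=\"%s\" constant=\"true\"/>", REACTION_COMPARTMENTS),
    "</listOfCompartments>")

  cpds <- entitiesOfKind(pgdb, "compound")
  if (length(cpds)) {
    out <- c(out, "<listOfSpecies>",
      vapply(cpds[order(names(cpds))], function(e)
        sprintf("<species id=\"%s\" name=\"%s\" compartment=\"cytosol\" constant=\"false\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"/>",
                xmlq(e$frameId), xmlq(e$name)), ""),
      "</listOfSpecies>")
  }
  rxns <- entitiesOfKind(pgdb, "reaction")
  if (length(rxns)) {
    out <- c(out, "<listOfReactions>")
    for (e in rxns[order(names(rxns))]) {
      out <- c(out, sprintf("<reaction id=\"%s\" name=\"%s\" compartment=\"%s\" reversible=\"false\" fast=\"false\">",
                            xmlq(e$frameId), xmlq(e$name), e$compartment))
      sref <- function(v, tag) {
        if (!length(v)) return(character(0))
        c(sprintf("<%s>", tag),
          sprintf("<speciesReference species=\"%s\" stoichiometry=\"%g\" constant=\"true\"/>",
                  xmlq(names(v)), unname(v)),
          sprintf("</%s>", tag))
      }
      out <- c(out, sref(e$substrates, "listOfReactants"),
               sref(e$products, "listOfProducts"), "</reaction>")
    }
    out <- c(out, "</listOfReactions>")
  }
  pws <- entitiesOfKind(pgdb, "pathway")
  if (length(pws)) {
    out <- c(out, "<groups:listOfGroups>")
    for (e in pws[order(names(pws))]) {
      out <- c(out,
        sprintf("<groups:group groups:id=\"%s\" groups:name=\"%s\" groups:kind=\"partonomy\">",
                xmlq(e$frameId), xmlq(e$name)),
        "<groups:listOfMembers>",
        sprintf("<groups:member groups:idRef=\"%s\"/>", xmlq(e$reactions)),
        "</groups:listOfMembers>", "</groups:group>")
    }
    out <- c(out, "</groups:listOfGroups>")
  }
  out <- c(out, "</model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}
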