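# Entity constructors and the PGDB content stamp.

entityBase <- function(id, name, synonyms, kind) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("entity '", id, "': name must be a non-empty string", call. = FALSE)
  list(frameId = id, name = name,
       synonyms = as.character(synonyms %||% character(0)), kind = kind)
}

#' Entity constructors
#'
#' Build the entity records stored in a [PGDB-class]. Every entity has a
#' unique `id` (frame ID), a display `name` and optional `synonyms`.
#'
#' @param id frame ID (unique within the PGDB; matching is case-sensitive).
#' @param name display name (case-insensitive in searches).
#' @param synonyms character vector of alternative names.
#' @param formula optional chemical formula.
#' @return a named list record with a `kind` field.
#' @name entities
NULL

#' @rdname entities
#' @export
newCompound <- function(id, name, synonyms = character(0), formula = NULL) {
  e <- entityBase(id, name, synonyms, "compound")
  e$formula <- formula
  e
}

#' @rdname entities
#' @param substrates,products named numeric vectors: names are compound frame
#'   IDs, values are stoichiometric coefficients (> 0).
#' @param ec character vector of EC numbers.
#' @param enzymes protein frame IDs catalyzing the reaction.
#' @param compartment one of cytosol, periplasm, inner_membrane, outer_membrane.
#' @param pathways pathway frame IDs (empty = unassigned grid).
#' @export
newReaction <- function(id, name, substrates, products, synonyms = character(0),
                        ec = character(0), enzymes = character(0),
                        compartment = "cytosol", pathways = character(0)) {
  e <- entityBase(id, name, synonyms, "reaction")
  substrates <- unlist(substrates); products <- unlist(products)
  if (length(substrates) && (is.null(names(substrates)) || any(substrates <= 0)))
    stop("reaction '", id, "': substrates must be a named vector of positive coefficients",
         call. = FALSE)
  if (length(products) && (is.null(names(products)) || any(products <= 0)))
    stop("reaction '", id, "': products must be a named vector of positive coefficients",
         call. = FALSE)
  e$substrates <- substrates %||% stats::setNames(numeric(0), character(0))
  e$products <- products %||% stats::setNames(numeric(0), character(0))
  e$ec <- as.character(ec)
  e$enzymes <- as.character(enzymes)
  e$compartment <- match.arg(compartment, REACTION_COMPARTMENTS)
  e$pathways <- as.character(pathways)
  e
}

#' @rdname entities
#' @param isEnzyme,isTransporter protein role flags.
#' @param genes gene frame IDs encoding the protein/RNA.
#' @export
newProtein <- function(id, name, synonyms = character(0), isEnzyme = FALSE,
                       isTransporter = FALSE, genes = character(0)) {
  e <- entityBase(id, name, synonyms, "protein")
  e$isEnzyme <- isTRUE(isEnzyme)
  e$isTransporter <- isTRUE(isTransporter)
  e$genes <- as.character(genes)
  e
}

#' @rdname entities
#' @export
newRNA <- function(id, name, synonyms = character(0), genes = character(0)) {
  e <- entityBase(id, name, synonyms, "rna")
  e$genes <- as.character(genes)
  e
}

#' @rdname entities
#' @param products protein or RNA frame IDs produced by the gene.
#' @export
newGene <- function(id, name, synonyms = character(0), products = character(0)) {
  e <- entityBase(id, name, synonyms, "gene")
  e$products <- as.character(products)
  e
}

#' @rdname entities
#' @param reactions ordered reaction frame IDs (drawn as a top-down chain).
#' @param category one of central, catabolic, anabolic_intermediary, signal,
#'   other; drives horizontal placement on the map.
#' @param cluster optional cluster-group label (e.g. "amino-acid biosynthesis").
#' @export
newPathway <- function(id, name, reactions, synonyms = character(0),
                       category = "other", cluster = NULL) {
  e <- entityBase(id, name, synonyms, "pathway")
  e$reactions <- as.character(reactions)
  e$category <- match.arg(category, PATHWAY_CATEGORIES)
  e$cluster <- cluster
  e
}

# every frame ID referenced by an entity record
entityRefs <- function(e) {
  switch(e$kind,
    reaction = c(names(e$substrates), names(e$products), e$enzymes, e$pathways),
    protein = e$genes,
    rna = e$genes,
    gene = e$products,
    pathway = e$reactions,
    character(0))
}

canonicalEntity <- function(e) {
  e$synonyms <- sort(e$synonyms)
  if (e$kind == "reaction") {
    e$substrates <- as.list(e$substrates[order(names(e$substrates))])
    e$products <- as.list(e$products[order(names(e$products))])
    e$ec <- sort(e$ec); e$enzymes <- sort(e$enzymes); e$pathways <- sort(e$pathways)
  } else if (e$kind %in% c("protein", "rna")) {
    e$genes <- sort(e$genes)
  } else if (e$kind == "gene") {
    e$products <- sort(e$products)
  }
  # pathway reaction order is meaningful (the drawn chain) and is kept
  e[order(names(e))]
}

#' Compute the content stamp of a network
#'
#' sha1 hash of a canonicalized serialization (entities sorted by frame ID,
#' set-valued fields sorted, numbers normalized), so the stamp is invariant
#' under reordering of the input file and changes iff content changes.
#'
#' @param organismId organism identifier string.
#' @param entities named list of entity records.
#' @return a 40-character hex string.
#' @export
computeStamp <- function(organismId, entities) {
  ord <- order(names(entities))
  canon <- list(organism = organismId,
                entities = lapply(entities[ord], canonicalEntity))
  json <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = 12, null = "null")
  digest::digest(as.character(json), algo = "sha1", serialize = FALSE)
}

#' Construct a PGDB from entity records
#'
#' @param organismId organism identifier.
#' @param entities list of entity records (see [newCompound()] and friends);
#'   may be unnamed, names are taken from the records' frame IDs.
#' @param check if `TRUE` (default), fail on duplicate or dangling frame IDs.
#' @return a validated [PGDB-class] with a computed version stamp.
#' @export
newPGDB <- function(organismId, entities = list(), check = TRUE) {
  ids <- vapply(entities, function(e) e$frameId, "")
  names(entities) <- ids
  if (check && length(entities)) {
    if (anyDuplicated(ids))
      stop("duplicate frame IDs: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    refs <- unique(unlist(lapply(entities, entityRefs)))
    dangling <- setdiff(refs, ids)
    if (length(dangling))
      stop("dangling reference(s): ", paste(sort(dangling), collapse = ", "),
           call. = FALSE)
  }
  new("PGDB", organismId = organismId, entities = entities,
      versionStamp = computeStamp(organismId, entities))
}
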