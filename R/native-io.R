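# Native network dialect: a versioned YAML schema with one section per entity
# kind. The full schema is documented in inst/doc-schema/network-schema.md and
# in the vignette; writeNetwork() emits the canonical form (entities sorted by
# frame ID), loadNetwork() accepts any order -- the version stamp is order
# invariant either way.

NATIVE_SCHEMA_VERSION <- 1L

reqField <- function(rec, field, section, i) {
  v <- rec[[field]]
  if (is.null(v))
    stop(sprintf("schema violation in %s record %d: missing field '%s'",
                 section, i, field), call. = FALSE)
  v
}

asCoefVec <- function(x, section, i) {
  if (is.null(x) || length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  v <- unlist(x)
  if (is.null(names(v)) || !is.numeric(v))
    stop(sprintf("schema violation in %s record %d: expected a map of compound id -> coefficient",
                 section, i), call. = FALSE)
  v
}

#' Read a network from the native YAML dialect
#'
#' Parses and validates a network file, resolving every cross-reference.
#' The dialect has top-level keys `cellmapr_network` (schema version),
#' `organism`, and one list section per entity kind (`compounds`, `reactions`,
#' `proteins`, `rnas`, `genes`, `pathways`).
#'
#' @param path path to a network YAML file.
#' @return a validated [PGDB-class].
#' @seealso [writeNetwork()], [loadSBML()]
#' @export
loadNetwork <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$cellmapr_network))
    stop("schema violation: missing 'cellmapr_network' version key", call. = FALSE)
  org <- doc$organism
  if (is.null(org) || !nzchar(org))
    stop("schema violation: missing 'organism'", call. = FALSE)

  ents <- list()
  sec <- function(name, f) {
    for (i in seq_along(doc[[name]])) {
      rec <- doc[[name]][[i]]
      ents[[length(ents) + 1L]] <<- f(rec, i)
    }
  }
  sec("compounds", function(r, i)
    newCompound(reqField(r, "id", "compounds", i), reqField(r, "name", "compounds", i),
                synonyms = unlist(r$synonyms) %||% character(0), formula = r$formula))
  sec("reactions", function(r, i)
    newReaction(reqField(r, "id", "reactions", i), reqField(r, "name", "reactions", i),
                substrates = asCoefVec(r$substrates, "reactions", i),
                products = asCoefVec(r$products, "reactions", i),
                synonyms = unlist(r$synonyms) %||% character(0),
                ec = unlist(r$ec) %||% character(0),
                enzymes = unlist(r$enzymes) %||% character(0),
                compartment = r$compartment %||% "cytosol",
                pathways = unlist(r$pathways) %||% character(0)))
  sec("proteins", function(r, i)
    newProtein(reqField(r, "id", "proteins", i), reqField(r, "name", "proteins", i),
               synonyms = unlist(r$synonyms) %||% character(0),
               isEnzyme = isTRUE(r$enzyme), isTransporter = isTRUE(r$transporter),
               genes = unlist(r$genes) %||% character(0)))
  sec("rnas", function(r, i)
    newRNA(reqField(r, "id", "rnas", i), reqField(r, "name", "rnas", i),
           synonyms = unlist(r$synonyms) %||% character(0),
           genes = unlist(r$genes) %||% character(0)))
  sec("genes", function(r, i)
    newGene(reqField(r, "id", "genes", i), reqField(r, "name", "genes", i),
            synonyms = unlist(r$synonyms) %||% character(0),
            products = unlist(r$products) %||% character(0)))
  sec("pathways", function(r, i)
    newPathway(reqField(r, "id", "pathways", i), reqField(r, "name", "pathways", i),
               reactions = unlist(r$reactions) %||% character(0),
               synonyms = unlist(r$synonyms) %||% character(0),
               category = r$category %||% "other", cluster = r$cluster))

  newPGDB(org, ents)
}

entityToRecord <- function(e) {
  r <- list(id = e$frameId, name = e$name)
  if (length(e$synonyms)) r$synonyms <- as.list(e$synonyms)
  switch(e$kind,
    compound = { if (!is.null(e$formula)) r$formula <- e$formula },
    reaction = {
      r$substrates <- as.list(e$substrates)
      r$products <- as.list(e$products)
      if (length(e$ec)) r$ec <- as.list(e$ec)
      if (length(e$enzymes)) r$enzymes <- as.list(e$enzymes)
      r$compartment <- e$compartment
      if (length(e$pathways)) r$pathways <- as.list(e$pathways)
    },
    protein = {
      r$enzyme <- e$isEnzyme; r$transporter <- e$isTransporter
      if (length(e$genes)) r$genes <- as.list(e$genes)
    },
    rna = { if (length(e$genes)) r$genes <- as.list(e$genes) },
    gene = { if (length(e$products)) r$products <- as.list(e$products) },
    pathway = {
      r$reactions <- as.list(e$reactions)
      r$category <- e$category
      if (!is.null(e$cluster)) r$cluster <- e$cluster
    })
  r
}

#' Write a network in the native YAML dialect
#'
#' Emits the canonical form: one section per entity kind, entities sorted by
#' frame ID. `loadNetwork(writeNetwork(pgdb))` reproduces the PGDB, stamp
#' included.
#'
#' @param pgdb a [PGDB-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(pgdb, path) {
  sections <- list(compound = "compounds", reaction = "reactions",
                   protein = "proteins", rna = "rnas", gene = "genes",
                   pathway = "pathways")
  doc <- list(cellmapr_network = NATIVE_SCHEMA_VERSION, organism = pgdb@organismId)
  for (k in names(sections)) {
    ents <- entitiesOfKind(pgdb, k)
    if (!length(ents)) next
    ents <- ents[order(names(ents))]
    doc[[sections[[k]]]] <- lapply(unname(ents), entityToRecord)
  }
  yaml::write_yaml(doc, path, indent.mapping.sequence = TRUE)
  invisible(path)
}
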