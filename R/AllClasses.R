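#' @import methods
NULL

ENTITY_KINDS <- c("compound", "reaction", "pathway", "protein", "rna", "gene")
REACTION_COMPARTMENTS <- c("cytosol", "periplasm", "inner_membrane", "outer_membrane")
PATHWAY_CATEGORIES <- c("central", "catabolic", "anabolic_intermediary", "signal", "other")
REGION_NAMES <- c("extracellular", "outer_membrane", "periplasm", "inner_membrane",
                  "cytoplasm", "unassigned_grid", "signal_strip")

#' PGDB: an organism-specific pathway/genome network
#'
#' Container for the entities of one organism's metabolic network: compounds,
#' reactions, pathways, proteins, RNAs and genes, each identified by a unique
#' frame ID. The `versionStamp` is a content hash of the canonicalized network;
#' it changes if and only if the network content changes and is the key used by
#' the tile cache to decide whether diagrams must be regenerated.
#'
#' Entities are stored as plain named lists (records); use [entity()],
#' [entityIds()] and [entitiesOfKind()] rather than reaching into the slot.
#'
#' @slot organismId single string identifying the organism.
#' @slot entities named list of entity records, names are frame IDs.
#' @slot versionStamp sha1 content hash of the canonicalized network.
#' @export
setClass("PGDB", representation(
  organismId = "character",
  entities = "list",
  versionStamp = "character"
))

setValidity("PGDB", function(object) {
  msgs <- character(0)
  if (length(object@organismId) != 1L || !nzchar(object@organismId))
    msgs <- c(msgs, "organismId must be a single non-empty string")
  ids <- names(object@entities)
  if (length(object@entities) > 0) {
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
      msgs <- c(msgs, "entities must be named by frame ID")
    else if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicate frame IDs: %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    kinds <- vapply(object@entities, function(e) e$kind %||% "", "")
    bad <- !kinds %in% ENTITY_KINDS
    if (any(bad))
      msgs <- c(msgs, sprintf("unknown entity kind for: %s",
                              paste(ids[bad], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Master layout of a cellular overview diagram
#'
#' Zoom-independent placement of every drawable object, in abstract master
#' units (equal to pixels at the deepest zoom level, origin top-left, y grows
#' downward). Produced by [layoutMaster()]; consumed by [specializeLayout()].
#'
#' @slot canvasWidth,canvasHeight canvas size in master units.
#' @slot regions data.frame (name, x0, y0, x1, y1) of diagram regions.
#' @slot clusterBoxes data.frame of shaded pathway-cluster boxes.
#' @slot glyphs data.frame of node glyphs (one row per placed occurrence).
#' @slot segments data.frame of reaction line segments.
#' @slot labels data.frame of label candidates (master anchors + class).
#' @export
setClass("MasterLayout", representation(
  canvasWidth = "numeric",
  canvasHeight = "numeric",
  regions = "data.frame",
  clusterBoxes = "data.frame",
  glyphs = "data.frame",
  segments = "data.frame",
  labels = "data.frame"
))

#' Concrete per-zoom-level layout
#'
#' Pixel geometry of every element retained at one zoom level after the
#' semantic-zoom feature policy and the label-fit rule have been applied.
#'
#' @slot level zoom level index, 0 (lowest magnification) .. levels-1.
#' @slot scale master units per pixel at this level.
#' @slot width,height raster dimensions in pixels.
#' @slot glyphs,segments,clusterBoxes,regions,labels pixel-space element tables.
#' @export
setClass("ZoomLayout", representation(
  level = "integer",
  scale = "numeric",
  width = "integer",
  height = "integer",
  glyphs = "data.frame",
  segments = "data.frame",
  clusterBoxes = "data.frame",
  regions = "data.frame",
  labels = "data.frame"
))

#' A named graphical overlay (search result or omics frame)
#'
#' A separate graphical plane of colored primitives drawn above the base
#' tiles. Primitives are stored in master coordinates and projected to any
#' zoom level at display/export time, so one search serves all levels.
#'
#' @slot name the query keyword (or experiment name) identifying the overlay.
#' @slot color default highlight color (hex string).
#' @slot primitives data.frame (shape, x0, y0, x1, y1, color) in master units.
#' @slot found data.frame (frameId, name, x, y) of objects found, with the
#'   master-coordinate marker anchor for each.
#' @slot active logical; inactive overlays are kept but not drawn.
#' @export
setClass("Overlay", representation(
  name = "character",
  color = "character",
  primitives = "data.frame",
  found = "data.frame",
  active = "logical"
))

#' Search index over a PGDB
#'
#' Lowercased string maps over name, synonyms and frame ID per entity kind,
#' an EC-number table, and the gene/enzyme expansion maps used by the
#' highlight commands. Rebuilt iff the PGDB version stamp changes.
#'
#' @slot stamp PGDB version stamp the index was built from.
#' @slot strings data.frame (kind, key, field, frameId); key is lowercase.
#' @slot ec data.frame (ec, frameId) for reactions.
#' @slot geneProducts,enzymeReactions named lists: expansion maps closed over
#'   the PGDB's gene->product and enzyme->reaction relations.
#' @export
setClass("SearchIndex", representation(
  stamp = "character",
  strings = "data.frame",
  ec = "data.frame",
  geneProducts = "list",
  enzymeReactions = "list"
))

#' Tile cache rooted in a directory
#'
#' File-system cache of encoded tiles, keyed organism/stamp/zoom/col_row.
#' Embedding the version stamp in the path makes invalidation atomic. The
#' `counters` environment tracks renders and cache hits (used to verify
#' cache purity: a hit performs zero rendering).
#'
#' @slot root cache root directory.
#' @slot format encoded raster format, "png" (default) or "gif".
#' @slot counters environment with `renders` and `hits` counts.
#' @export
setClass("TileCache", representation(
  root = "character",
  format = "character",
  counters = "environment"
))

#' Omics dataset parsed from a tab-delimited datafile
#'
#' @slot labels row labels (gene / reaction / compound / protein identifiers),
#'   kept verbatim.
#' @slot values numeric matrix, one column per experiment; NA marks missing.
#' @slot experiments experiment (column) names.
#' @export
setClass("OmicsDataset", representation(
  labels = "character",
  values = "matrix",
  experiments = "character"
))

#' Value-to-color mapping for the omics viewer
#'
#' @slot ramp ordered color stops (hex strings), interpolated linearly.
#' @slot domain numeric length-2, the [min, max] data range (post-transform).
#' @slot transform "identity" or "log10".
#' @slot missingColor color for resolved rows with a missing value.
#' @export
setClass("ColorMap", representation(
  ramp = "character",
  domain = "numeric",
  transform = "character",
  missingColor = "character"
))

#' Ordered per-experiment overlays forming an omics animation
#'
#' @slot frames list of [Overlay-class] objects, one per experiment column,
#'   in column order.
#' @slot colormap the shared [ColorMap-class] (one color key per animation).
#' @slot experiments experiment names, parallel to `frames`.
#' @export
setClass("OmicsFrameSet", representation(
  frames = "list",
  colormap = "ColorMap",
  experiments = "character"
))

#' Typed web-service style requests
#'
#' A minimal request includes the organism identifier and the zoom level.
#' `HighlightRequest` adds a search command family, mode and query;
#' `OmicsRequest` adds a datafile locator (http or file scheme), column
#' selection and colormap parameters.
#'
#' @slot organismId organism unique identifier.
#' @slot zoom zoom level index.
#' @aliases OmicsRequest-class
#' @export
setClass("HighlightRequest", representation(
  organismId = "character",
  zoom = "integer",
  family = "character",
  mode = "character",
  query = "character"
))

#' @rdname HighlightRequest-class
#' @export
setClass("OmicsRequest", representation(
  organismId = "character",
  zoom = "integer",
  scheme = "character",
  datafile = "character",
  columns = "integer",
  transform = "character"
))

#' Deterministic synthetic-organism fixture specification
#'
#' Counts and rates controlling [makeOrganism()]. The same spec (same seed)
#' always yields a byte-identical PGDB.
#'
#' @slot seed integer seed for the explicit counter-based random source.
#' @slot counts named list: pathways per category, reactions per pathway,
#'   unassigned reactions, transporters, periplasmic reactions, genes per
#'   enzyme.
#' @slot synonymDensity expected synonyms per entity, in [0, 2].
#' @slot nameCollisionRate fraction of entities reusing a name stem.
#' @export
setClass("FixtureSpec", representation(
  seed = "integer",
  counts = "list",
  synonymDensity = "numeric",
  nameCollisionRate = "numeric"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "PGDB", function(object) {
  kinds <- vapply(object@entities, function(e) e$kind, "")
  cat("PGDB for organism", object@organismId, "\n")
  cat("  stamp:", substr(object@versionStamp, 1, 12), "\n")
  if (length(kinds)) {
    tab <- table(factor(kinds, levels = ENTITY_KINDS))
    cat(" ", paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  } else cat("  (empty)\n")
})

setMethod("show", "MasterLayout", function(object) {
  cat(sprintf("MasterLayout %gx%g master units: %d glyphs, %d segments, %d cluster boxes\n",
              object@canvasWidth, object@canvasHeight,
              nrow(object@glyphs), nrow(object@segments), nrow(object@clusterBoxes)))
})

setMethod("show", "ZoomLayout", function(object) {
  cat(sprintf("ZoomLayout level %d (scale %g): %dx%d px, %d glyphs, %d segments, %d labels\n",
              object@level, object@scale, object@width, object@height,
              nrow(object@glyphs), nrow(object@segments), nrow(object@labels)))
})

setMethod("show", "Overlay", function(object) {
  cat(sprintf("Overlay '%s' (%s): %d primitives, %d found, %s\n",
              object@name, object@color, nrow(object@primitives), nrow(object@found),
              if (object@active) "active" else "inactive"))
})

setMethod("show", "OmicsFrameSet", function(object) {
  cat(sprintf("OmicsFrameSet: %d frame(s) [%s], domain [%g, %g]\n",
              length(object@frames), paste(object@experiments, collapse = ", "),
              object@colormap@domain[1], object@colormap@domain[2]))
})

#' @rdname PGDB-class
#' @param object,pgdb a `PGDB` object.
#' @export
organismId <- function(pgdb) pgdb@organismId

#' @rdname PGDB-class
#' @export
versionStamp <- function(pgdb) pgdb@versionStamp

#' @rdname PGDB-class
#' @export
entityIds <- function(pgdb) names(pgdb@entities)

#' @rdname PGDB-class
#' @param id a frame ID.
#' @export
entity <- function(pgdb, id) {
  e <- pgdb@entities[[id]]
  if (is.null(e)) stop("no entity with frame ID '", id, "'", call. = FALSE)
  e
}

#' @rdname PGDB-class
#' @param kind one of compound, reaction, pathway, protein, rna, gene.
#' @export
entitiesOfKind <- function(pgdb, kind) {
  kind <- match.arg(kind, ENTITY_KINDS)
  Filter(function(e) e$kind == kind, pgdb@entities)
}
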