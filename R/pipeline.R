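# End-to-end base-image pipeline: master layout -> per-level layouts ->
# rasters -> tiles (cached) -> node/frame data bundle. The master layout is
# persisted next to the tiles as a structured-text document: like the
# network itself it is part of the organism's published state.

dfToLists <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))

#' Serialize / restore a master layout
#'
#' `masterLayoutJSON` produces a canonical JSON string (byte-identical for
#' identical layouts); `writeMasterLayout`/`readMasterLayout` persist and
#' restore it losslessly.
#'
#' @param master a [MasterLayout-class].
#' @return a JSON string.
#' @export
masterLayoutJSON <- function(master) {
  doc <- list(canvas = c(master@canvasWidth, master@canvasHeight),
              regions = dfToLists(master@regions),
              clusterBoxes = dfToLists(master@clusterBoxes),
              glyphs = dfToLists(master@glyphs),
              segments = dfToLists(master@segments),
              labels = dfToLists(master@labels))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 8, null = "null"))
}

#' @rdname masterLayoutJSON
#' @param path file path.
#' @export
writeMasterLayout <- function(master, path) {
  writeLines(masterLayoutJSON(master), path)
  invisible(path)
}

#' @rdname masterLayoutJSON
#' @export
readMasterLayout <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  asDf <- function(x, empty) if (length(x) == 0) empty else
    as.data.frame(x, stringsAsFactors = FALSE)
  new("MasterLayout", canvasWidth = doc$canvas[1], canvasHeight = doc$canvas[2],
      regions = asDf(doc$regions, data.frame()),
      clusterBoxes = asDf(doc$clusterBoxes, emptyBoxes()),
      glyphs = asDf(doc$glyphs, emptyGlyphs()),
      segments = asDf(doc$segments, emptySegments()),
      labels = asDf(doc$labels, emptyLabels()))
}

#' Build the complete published map bundle for an organism
#'
#' Runs the full pipeline: layout (step 1, persisted), per-level
#' specialization (step 2), rasterization (step 3) and tiling (step 4,
#' through the stamp-keyed cache), plus the node-data and frame-data client
#' files. Re-running with an unmodified network performs zero renders: all
#' levels are cache hits.
#'
#' @param pgdb a validated [PGDB-class].
#' @param outdir output directory for layout and client data.
#' @param cache a [TileCache-class] (defaults to `outdir`/tiles).
#' @param levels number of zoom levels.
#' @param style rendering style.
#' @param params layout parameters.
#' @return invisible list: `map` (a [CellMap-class]), `zoomLayouts`,
#'   `cache`, and the per-call `counters` (renders / hits).
#' @export
buildMap <- function(pgdb, outdir, cache = NULL, levels = 6L,
                     style = defaultStyle(), params = layoutParams()) {
  rep0 <- validatePGDB(pgdb)
  if (!isCleanReport(rep0, allowWarnings = TRUE))
    stop("PGDB fails validation; first error: ",
         rep0$message[rep0$severity == "error"][1], call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cache)) cache <- tileCache(file.path(outdir, "tiles"))

  map <- cellMap(pgdb, params)
  writeMasterLayout(map@master, file.path(outdir, "masterlayout.json"))
  zls <- specializeAll(map@master, levels = levels)

  before <- cacheCounters(cache)
  pipeline <- function(zoom) renderImage(zls[[zoom + 1L]], style)
  for (lev in seq_len(levels) - 1L)
    ensureLevel(cache, pgdb@organismId, pgdb@versionStamp, lev, pipeline,
                bg = style$colors$background)

  nd <- lapply(zls, buildNodeData)
  fd <- buildFrameData(pgdb)
  exportClientData(nd, fd, file.path(outdir, "clientdata"))

  after <- cacheCounters(cache)
  invisible(list(map = map, zoomLayouts = zls, cache = cache,
                 counters = list(renders = after$renders - before$renders,
                                 hits = after$hits - before$hits)))
}
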