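# Node data (per-zoom clickable geometry) and frame data (per-object tooltip
# text and links): the two products that accompany the tiles, making objects
# in the rendered images locatable and describable.

#' Build node data for one zoom level
#'
#' Maps every drawn element of a zoom layout to a geometric primitive in
#' that level's pixel coordinates: circles for circular glyphs, rectangles
#' for boxes/triangles/tees, and polylines (with a 3-pixel half-width hit
#' corridor) for reaction lines. One drawn element contributes exactly one
#' primitive; primitives are clamped to the raster bounds.
#'
#' @param zl a [ZoomLayout-class].
#' @return named list frameId -> list of primitives; each primitive is a
#'   list with a `type` field ("circle", "rect" or "polyline").
#' @export
buildNodeData <- function(zl) {
  nd <- list()
  add <- function(id, prim) nd[[id]] <<- c(nd[[id]], list(prim))
  W <- zl@width; H <- zl@height
  cl <- function(v, hi) pmin(pmax(v, 0), hi)
  g <- zl@glyphs
  for (i in seq_len(nrow(g))) {
    if (g$shape[i] == "circle")
      add(g$frameId[i], list(type = "circle", cx = g$px[i], cy = g$py[i],
                             r = g$psize[i], element = g$glyphId[i]))
    else
      add(g$frameId[i], list(type = "rect",
                             x0 = cl(g$px[i] - g$psize[i], W),
                             y0 = cl(g$py[i] - g$psize[i], H),
                             x1 = cl(g$px[i] + g$psize[i], W),
                             y1 = cl(g$py[i] + g$psize[i], H),
                             element = g$glyphId[i]))
  }
  s <- zl@segments
  for (i in seq_len(nrow(s)))
    add(s$frameId[i], list(type = "polyline",
                           x = c(cl(s$px0[i], W), cl(s$px1[i], W)),
                           y = c(cl(s$py0[i], H), cl(s$py1[i], H)),
                           halfWidth = 3, element = s$segId[i]))
  nd
}

#' Point query against node data
#'
#' @param nd node data from [buildNodeData()].
#' @param x,y pixel coordinates.
#' @return character vector of frame IDs whose primitives contain the point.
#' @export
hitTest <- function(nd, x, y) {
  hit1 <- function(p) {
    switch(p$type,
      circle = (x - p$cx)^2 + (y - p$cy)^2 <= p$r^2,
      rect = x >= p$x0 && x <= p$x1 && y >= p$y0 && y <= p$y1,
      polyline = {
        hw <- p$halfWidth
        any(vapply(seq_len(length(p$x) - 1), function(i) {
          px <- p$x[i:(i + 1)]; py <- p$y[i:(i + 1)]
          L2 <- (px[2] - px[1])^2 + (py[2] - py[1])^2
          t <- if (L2 == 0) 0 else
            max(0, min(1, ((x - px[1]) * (px[2] - px[1]) +
                           (y - py[1]) * (py[2] - py[1])) / L2))
          (x - (px[1] + t * (px[2] - px[1])))^2 +
            (y - (py[1] + t * (py[2] - py[1])))^2 <= hw^2
        }, TRUE))
      },
      FALSE)
  }
  ids <- names(nd)
  ids[vapply(ids, function(id) any(vapply(nd[[id]], hit1, TRUE)), TRUE)]
}

frameText <- function(pgdb, e) {
  lines <- c(paste0("Class: ", e$kind))
  links <- character(0)
  if (length(e$synonyms))
    lines <- c(lines, paste0("Synonyms: ", paste(e$synonyms, collapse = "; ")))
  if (e$kind == "compound" && !is.null(e$formula))
    lines <- c(lines, paste0("Formula: ", e$formula))
  if (e$kind == "reaction") {
    if (length(e$ec)) lines <- c(lines, paste0("EC: ", paste(e$ec, collapse = ", ")))
    if (length(e$pathways)) {
      pn <- vapply(sort(e$pathways), function(p) entity(pgdb, p)$name, "")
      lines <- c(lines, paste0("Pathways: ", paste(pn, collapse = "; ")))
      links <- c(links, sort(e$pathways))
    }
    if (length(e$enzymes)) {
      en <- vapply(sort(e$enzymes), function(p) entity(pgdb, p)$name, "")
      lines <- c(lines, paste0("Enzymes: ", paste(en, collapse = "; ")))
      links <- c(links, sort(e$enzymes))
    }
    links <- c(links, sort(unique(c(names(e$substrates), names(e$products)))))
  }
  if (e$kind %in% c("protein", "rna") && length(e$genes)) {
    gn <- vapply(sort(e$genes), function(g) entity(pgdb, g)$name, "")
    lines <- c(lines, paste0("Genes: ", paste(gn, collapse = "; ")))
    links <- c(links, sort(e$genes))
  }
  if (e$kind == "protein")
    lines <- c(lines, paste0("Roles: ", paste(
      c(if (e$isEnzyme) "enzyme", if (e$isTransporter) "transporter",
        if (!e$isEnzyme && !e$isTransporter) "protein"), collapse = ", ")))
  if (e$kind == "gene" && length(e$products)) {
    pn <- vapply(sort(e$products), function(p) entity(pgdb, p)$name, "")
    lines <- c(lines, paste0("Products: ", paste(pn, collapse = "; ")))
    links <- c(links, sort(e$products))
  }
  if (e$kind == "pathway") {
    lines <- c(lines, paste0("Reactions: ", length(e$reactions)),
               paste0("Category: ", e$category))
    links <- c(links, e$reactions)
  }
  list(title = e$name, class = e$kind, text = lines, links = unique(links))
}

#' Build tooltip frame data for every entity
#'
#' Deterministic per-object descriptive text (name, class, synonyms, EC
#' numbers, pathway memberships, gene/product relations) plus link targets
#' to related objects. Every frame ID with node data at any level has frame
#' data.
#'
#' @param pgdb a [PGDB-class].
#' @return named list frameId -> list(title, class, text, links).
#' @export
buildFrameData <- function(pgdb) {
  ids <- sort(entityIds(pgdb))
  stats::setNames(lapply(ids, function(id) frameText(pgdb, entity(pgdb, id))), ids)
}

#' Export node and frame data for map clients
#'
#' Writes one JSON document per zoom level for node data
#' (`nodedata-z<level>.json`) and one `framedata.json`, a neutral
#' structured-text form loadable by any client. [loadClientData()] reads the
#' bundle back.
#'
#' @param nodeData list of node data, one element per zoom level.
#' @param frameData frame data from [buildFrameData()].
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
exportClientData <- function(nodeData, frameData, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (k in seq_along(nodeData)) {
    f <- file.path(dir, sprintf("nodedata-z%d.json", k - 1L))
    jsonlite::write_json(list(level = k - 1L, objects = nodeData[[k]]), f,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  f <- file.path(dir, "framedata.json")
  jsonlite::write_json(frameData, f, auto_unbox = TRUE)
  invisible(c(files, f))
}

#' @rdname exportClientData
#' @export
loadClientData <- function(dir) {
  nf <- sort(list.files(dir, pattern = "^nodedata-z\\d+\\.json$", full.names = TRUE))
  nodeData <- lapply(nf, function(f) {
    doc <- jsonlite::read_json(f, simplifyVector = FALSE)
    lapply(doc$objects, function(prims) lapply(prims, function(p) {
      if (!is.null(p$x)) { p$x <- unlist(p$x); p$y <- unlist(p$y) }
      p
    }))
  })
  list(nodeData = nodeData,
       frameData = jsonlite::read_json(file.path(dir, "framedata.json"),
                                       simplifyVector = FALSE))
}
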