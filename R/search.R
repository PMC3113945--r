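# The five highlight command families. Every search produces a named Overlay
# whose primitives live in master coordinates (projected per zoom at
# display/export time) plus a found-object list with marker anchors.

#' CellMap: a PGDB with its layout and search index
#'
#' Convenience container bundling the network, its master layout and the
#' search index; the unit the highlight and omics commands operate on.
#'
#' @slot pgdb the [PGDB-class].
#' @slot master the [MasterLayout-class].
#' @slot index the [SearchIndex-class].
#' @export
setClass("CellMap", representation(
  pgdb = "PGDB", master = "MasterLayout", index = "SearchIndex"))

setMethod("show", "CellMap", function(object) {
  cat("CellMap of", object@pgdb@organismId, "\n")
  methods::show(object@master)
})

#' @rdname CellMap-class
#' @param pgdb a validated [PGDB-class].
#' @param params layout parameters, see [layoutParams()].
#' @export
cellMap <- function(pgdb, params = layoutParams()) {
  new("CellMap", pgdb = pgdb, master = layoutMaster(pgdb, params),
      index = buildSearchIndex(pgdb))
}

#' Build the search index for a PGDB
#'
#' Lowercase maps over name, each synonym and frame ID for every entity
#' kind; an EC-number table; and expansion maps (gene to products and their
#' reactions, enzyme to reactions) closed over the PGDB's relations. The
#' index records the PGDB stamp it was built from so callers can rebuild
#' exactly when the network changes.
#'
#' @param pgdb a [PGDB-class].
#' @return a [SearchIndex-class].
#' @export
buildSearchIndex <- function(pgdb) {
  rows <- list(); ecs <- list()
  for (e in pgdb@entities) {
    vals <- c(name = e$name, frame_id = e$frameId)
    syn <- e$synonyms
    rows[[length(rows) + 1L]] <- data.frame(
      kind = e$kind,
      key = tolower(c(unname(vals), syn)),
      field = c("name", "frame_id", rep("synonym", length(syn))),
      frameId = e$frameId, stringsAsFactors = FALSE)
    if (e$kind == "reaction" && length(e$ec))
      ecs[[length(ecs) + 1L]] <- data.frame(ec = e$ec, frameId = e$frameId,
                                            stringsAsFactors = FALSE)
  }
  strings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), key = character(0), field = character(0),
               frameId = character(0), stringsAsFactors = FALSE)
  ec <- if (length(ecs)) do.call(rbind, ecs) else
    data.frame(ec = character(0), frameId = character(0), stringsAsFactors = FALSE)

  enzymeReactions <- list()
  for (e in entitiesOfKind(pgdb, "reaction"))
    for (en in e$enzymes)
      enzymeReactions[[en]] <- c(enzymeReactions[[en]], e$frameId)

  geneProducts <- list()
  for (g in entitiesOfKind(pgdb, "gene")) {
    exp <- list(reactions = character(0), rnas = character(0),
                transporters = character(0), enzymes = character(0))
    for (pid in g$products) {
      pr <- pgdb@entities[[pid]]
      if (is.null(pr)) next
      if (pr$kind == "rna") exp$rnas <- c(exp$rnas, pid)
      if (pr$kind == "protein") {
        if (isTRUE(pr$isTransporter)) exp$transporters <- c(exp$transporters, pid)
        if (isTRUE(pr$isEnzyme) || !is.null(enzymeReactions[[pid]]))
          exp$enzymes <- c(exp$enzymes, pid)
        exp$reactions <- c(exp$reactions, enzymeReactions[[pid]] %||% character(0))
      }
    }
    geneProducts[[g$frameId]] <- lapply(exp, unique)
  }

  new("SearchIndex", stamp = pgdb@versionStamp, strings = strings, ec = ec,
      geneProducts = geneProducts, enzymeReactions = enzymeReactions)
}

# ids of one kind matching a query under a mode.
# exact: case-sensitive on frame_id, case-insensitive on name (no synonyms);
# substring: case-insensitive over name, synonyms and frame_id.
matchIds <- function(index, pgdb, kind, q, mode) {
  if (!nzchar(q)) stop("empty query", call. = FALSE)
  st <- index@strings[index@strings$kind == kind, , drop = FALSE]
  if (mode == "exact") {
    byId <- st$frameId[st$field == "frame_id" &
                       vapply(st$frameId, identical, TRUE, y = q)]
    byName <- st$frameId[st$field == "name" & st$key == tolower(q)]
    sort(unique(c(byId, byName)))
  } else {
    sort(unique(st$frameId[grepl(tolower(q), st$key, fixed = TRUE)]))
  }
}

familyColors <- c(pathways = "#E07000", reactions = "#D02090", genes = "#0090D0",
                  enzymes = "#00A040", compounds = "#C8A000")

# assemble an Overlay from drawn elements of a set of objects
overlayFromObjects <- function(map, name, color, foundIds, highlightIds = foundIds,
                               unresolved = character(0)) {
  m <- map@master
  hl <- unique(highlightIds)
  seg <- m@segments[m@segments$frameId %in% hl, , drop = FALSE]
  gly <- m@glyphs[m@glyphs$frameId %in% hl, , drop = FALSE]
  prim <- rbind(
    if (nrow(seg)) data.frame(shape = "line", x0 = seg$x0, y0 = seg$y0,
                              x1 = seg$x1, y1 = seg$y1, frameId = seg$frameId,
                              color = color, stringsAsFactors = FALSE),
    if (nrow(gly)) data.frame(shape = ifelse(gly$shape == "circle", "circle", "rect"),
                              x0 = gly$x - gly$size, y0 = gly$y - gly$size,
                              x1 = gly$x + gly$size, y1 = gly$y + gly$size,
                              frameId = gly$frameId, color = color,
                              stringsAsFactors = FALSE))
  if (is.null(prim))
    prim <- data.frame(shape = character(0), x0 = numeric(0), y0 = numeric(0),
                       x1 = numeric(0), y1 = numeric(0), frameId = character(0),
                       color = character(0), stringsAsFactors = FALSE)

  anchorOf <- function(id) {
    gi <- which(gly$frameId == id)
    if (length(gi)) return(c(gly$x[gi[1]], gly$y[gi[1]]))
    si <- which(seg$frameId == id)
    if (length(si)) return(c((seg$x0[si[1]] + seg$x1[si[1]]) / 2,
                             (seg$y0[si[1]] + seg$y1[si[1]]) / 2))
    # objects without own drawn geometry (e.g. pathways) anchor on their parts
    c(NA_real_, NA_real_)
  }
  found <- do.call(rbind, c(list(data.frame(
    frameId = character(0), name = character(0), x = numeric(0), y = numeric(0),
    stringsAsFactors = FALSE)),
    lapply(unique(foundIds), function(id) {
      a <- anchorOf(id)
      if (is.na(a[1]) && pgdbHas(map@pgdb, id)) {
        e <- entity(map@pgdb, id)
        if (e$kind == "pathway") {
          si <- which(m@segments$pathway == id)
          if (length(si)) a <- c((m@segments$x0[si[1]] + m@segments$x1[si[1]]) / 2,
                                 (m@segments$y0[si[1]] + m@segments$y1[si[1]]) / 2)
        }
      }
      data.frame(frameId = id,
                 name = if (pgdbHas(map@pgdb, id)) entity(map@pgdb, id)$name else id,
                 x = a[1], y = a[2], stringsAsFactors = FALSE)
    })))
  new("Overlay", name = name, color = color, primitives = prim, found = found,
      active = TRUE)
}

pgdbHas <- function(pgdb, id) !is.null(pgdb@entities[[id]])

#' Highlight commands
#'
#' The five search families. Every command returns an [Overlay-class] named
#' after the query. `searchPathways` highlights the reactions of the
#' pathways found; `searchReactions` the reactions found (modes: exact,
#' substring, ec — full EC number or EC prefix — and enzyme_name, which
#' resolves enzymes and then their reactions); `searchGenes` expands matched
#' genes to their products' display elements (reactions, RNAs, transporters,
#' enzymes; file mode reads one identifier per line and reports unresolvable
#' ones without failing); `searchEnzymes` highlights the reactions and
#' protein glyphs of the enzymes found; `searchCompounds` highlights every
#' duplicate glyph occurrence of the compounds found.
#'
#' @param map a [CellMap-class].
#' @param q query string (or, for `searchGenes` file mode, a file path).
#' @param mode search mode; see each command.
#' @param color highlight color; defaults to a per-family color.
#' @return an [Overlay-class].
#' @name highlight
NULL

#' @rdname highlight
#' @export
searchPathways <- function(map, q, mode = c("substring", "exact"), color = NULL) {
  mode <- match.arg(mode)
  ids <- matchIds(map@index, map@pgdb, "pathway", q, mode)
  rxns <- unique(c(character(0),
                   unlist(lapply(ids, function(id) entity(map@pgdb, id)$reactions))))
  overlayFromObjects(map, q, color %||% familyColors[["pathways"]],
                     foundIds = ids, highlightIds = rxns)
}

#' @rdname highlight
#' @export
searchReactions <- function(map, q,
                            mode = c("substring", "exact", "ec", "enzyme_name"),
                            color = NULL) {
  mode <- match.arg(mode)
  color <- color %||% familyColors[["reactions"]]
  if (mode == "ec") {
    if (!grepl("^[0-9]+(\\.[0-9]+){0,3}$", q))
      stop("malformed EC number: '", q, "'", call. = FALSE)
    ec <- map@index@ec
    hit <- ec$ec == q | startsWith(ec$ec, paste0(q, "."))
    ids <- sort(unique(ec$frameId[hit]))
  } else if (mode == "enzyme_name") {
    enz <- matchIds(map@index, map@pgdb, "protein", q, "substring")
    ids <- sort(unique(c(character(0), unlist(map@index@enzymeReactions[enz]))))
  } else {
    ids <- matchIds(map@index, map@pgdb, "reaction", q, mode)
  }
  overlayFromObjects(map, q, color, foundIds = ids)
}

#' @rdname highlight
#' @export
searchGenes <- function(map, q, mode = c("substring", "exact", "file"),
                        color = NULL) {
  mode <- match.arg(mode)
  unresolved <- character(0)
  if (mode == "file") {
    ids0 <- readLines(q, warn = FALSE)
    ids0 <- trimws(ids0); ids0 <- ids0[nzchar(ids0)]
    genes <- character(0)
    st <- map@index@strings
    gstr <- st[st$kind == "gene", , drop = FALSE]
    for (id in ids0) {
      hit <- gstr$frameId[(gstr$field == "frame_id" &
                             vapply(gstr$frameId, identical, TRUE, y = id)) |
                          (gstr$field == "name" & gstr$key == tolower(id))]
      if (length(hit)) genes <- c(genes, hit) else unresolved <- c(unresolved, id)
    }
    genes <- sort(unique(genes))
    name <- basename(q)
  } else {
    genes <- matchIds(map@index, map@pgdb, "gene", q, mode)
    name <- q
  }
  exp <- map@index@geneProducts[genes]
  elements <- sort(unique(c(character(0), unlist(lapply(exp, unlist)))))
  ov <- overlayFromObjects(map, name, color %||% familyColors[["genes"]],
                           foundIds = elements)
  attr(ov@found, "genes") <- genes
  attr(ov@found, "unresolved") <- unresolved
  ov
}

#' @rdname highlight
#' @export
searchEnzymes <- function(map, q, mode = c("substring", "exact"), color = NULL) {
  mode <- match.arg(mode)
  cand <- matchIds(map@index, map@pgdb, "protein", q, mode)
  # an enzyme is a protein flagged as such or appearing as a reaction's enzyme
  enz <- cand[vapply(cand, function(id)
    isTRUE(entity(map@pgdb, id)$isEnzyme) ||
      !is.null(map@index@enzymeReactions[[id]]), TRUE)]
  rxns <- unique(c(character(0), unlist(map@index@enzymeReactions[enz])))
  overlayFromObjects(map, q, color %||% familyColors[["enzymes"]],
                     foundIds = enz, highlightIds = c(enz, rxns))
}

#' @rdname highlight
#' @export
searchCompounds <- function(map, q, mode = c("substring", "exact"), color = NULL) {
  mode <- match.arg(mode)
  ids <- matchIds(map@index, map@pgdb, "compound", q, mode)
  overlayFromObjects(map, q, color %||% familyColors[["compounds"]], foundIds = ids)
}

#' List the objects found by an overlay
#'
#' Deterministic order (display name, then frame ID); each entry carries the
#' master-coordinate anchor used for the red location marker.
#'
#' @param ov an [Overlay-class].
#' @return data.frame (frameId, name, x, y), ordered.
#' @export
listOverlay <- function(ov) {
  f <- ov@found
  f[order(f$name, f$frameId), , drop = FALSE]
}

#' Prefix auto-completion over the index
#'
#' @param index a [SearchIndex-class].
#' @param prefix query prefix (case-insensitive).
#' @param kind optional entity kind filter.
#' @param n maximum number of completions (default 20).
#' @return data.frame (kind, key, frameId) in name order.
#' @export
autocomplete <- function(index, prefix, kind = NULL, n = 20L) {
  st <- index@strings
  if (!is.null(kind)) st <- st[st$kind == kind, , drop = FALSE]
  hit <- st[startsWith(st$key, tolower(prefix)), , drop = FALSE]
  hit <- hit[!duplicated(paste(hit$frameId, hit$key)), , drop = FALSE]
  hit <- hit[order(hit$key, hit$frameId), , drop = FALSE]
  utils::head(hit[, c("kind", "key", "frameId")], n)
}

#' Export an overlay document / project it to SVG
#'
#' `exportOverlay` writes the overlay (name, color, primitives in master
#' coordinates, found list) as a YAML document consumable by map clients.
#' `overlaySVG` projects the primitives onto a zoom level and writes an SVG
#' plane of the same size as that level's raster.
#'
#' @param ov an [Overlay-class].
#' @param path output file.
#' @param level zoom level index for the SVG projection.
#' @param levels total zoom levels.
#' @return `path`, invisibly.
#' @export
exportOverlay <- function(ov, path) {
  doc <- list(name = ov@name, color = ov@color, active = ov@active,
              primitives = lapply(seq_len(nrow(ov@primitives)), function(i)
                as.list(ov@primitives[i, ])),
              found = lapply(seq_len(nrow(ov@found)), function(i)
                as.list(ov@found[i, ])))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname exportOverlay
#' @export
overlaySVG <- function(ov, path, level, levels = 6L) {
  sc <- zoomScale(level, levels)
  p <- ov@primitives
  lines <- c(sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" data-level=\"%d\">", level))
  for (i in seq_len(nrow(p))) {
    x0 <- roundHalfUp(p$x0[i] / sc); y0 <- roundHalfUp(p$y0[i] / sc)
    x1 <- roundHalfUp(p$x1[i] / sc); y1 <- roundHalfUp(p$y1[i] / sc)
    lines <- c(lines, switch(p$shape[i],
      line = sprintf("<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"%s\" stroke-width=\"3\"/>",
                     x0, y0, x1, y1, p$color[i]),
      circle = sprintf("<circle cx=\"%d\" cy=\"%d\" r=\"%d\" fill=\"%s\"/>",
                       (x0 + x1) %/% 2, (y0 + y1) %/% 2,
                       max(1, (x1 - x0) %/% 2), p$color[i]),
      rect = sprintf("<rect x=\"%d\" y=\"%d\" width=\"%d\" height=\"%d\" fill=\"%s\"/>",
                     x0, y0, max(1, x1 - x0), max(1, y1 - y0), p$color[i])))
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}
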