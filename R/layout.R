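# Master layout: deterministic slot-packing honoring the cellular-overview
# drawing conventions. Central pathways (glycolysis/TCA stand-ins) in the
# middle column, catabolic to the right, anabolic/intermediary to the left,
# signal-transduction pathways in a strip along the bottom left, pathway-less
# reactions in a rectangular grid at the far right, periplasmic reactions in
# the band between the two membranes, transporters embedded in their membrane.
# Coordinates are master units: top-left origin, y grows downward, one master
# unit = one pixel at the deepest zoom level.

#' Layout parameters
#'
#' Geometric constants of the master layout, in master units. All defaults
#' are overridable; the canvas is capped at `canvasMax` in either dimension.
#'
#' @param ... name = value overrides of the defaults.
#' @return a named list of parameters.
#' @export
layoutParams <- function(...) {
  p <- list(
    margin = 30,
    stepH = 40,          # vertical extent of one reaction step
    topPad = 26,         # pathway headroom (pathway label zone)
    bottomPad = 14,
    nodeR = 4,           # main-chain metabolite circle radius
    sideR = 3,           # side metabolite triangle half-extent
    sideDx = 16,         # side metabolite x offset from the reaction line
    enzDx = 28,          # enzyme box x offset
    enzHalf = 4,         # enzyme box half-extent
    pwCellW = 60,        # width allotted to one pathway chain
    pwGap = 14,
    clusterPad = 16,
    clusterLabelH = 12,
    clusterGapY = 24,
    colGap = 50,
    extracellularH = 44,
    outerMembraneH = 22,
    periplasmH = 64,
    innerMembraneH = 22,
    cytoTopGap = 28,     # gap between inner membrane and first cluster box
    gridCols = 4,
    gridCellW = 64,
    gridCellH = 56,
    gridGap = 40,        # gap between catabolic column and the grid
    signalGapY = 30,
    transporterGap = 46,
    transporterHalfW = 5,
    periRxnGap = 44,
    canvasMax = 24000)
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

#' Unassigned-grid dimensions
#'
#' Row-major rectangular arrangement: `n` cells at `ncol` columns need
#' `ceiling(n / ncol)` rows.
#'
#' @param n number of grid cells (reactions).
#' @param ncol number of columns.
#' @return c(rows, cols) actually used.
#' @export
gridDims <- function(n, ncol) {
  if (n == 0) return(c(0L, 0L))
  c(as.integer(ceiling(n / ncol)), as.integer(min(n, ncol)))
}

categoryColumn <- c(central = "middle", catabolic = "right",
                    anabolic_intermediary = "left", other = "left",
                    signal = NA_character_)

#' Assign every pathway, reaction and membrane protein to a diagram region
#'
#' Placement rules: central pathways go to the middle cytoplasm column,
#' catabolic to the right, anabolic/intermediary (and "other") to the left,
#' signal pathways to the bottom-left signal strip. Reaction compartment takes
#' precedence over pathway category: periplasmic reactions go to the periplasm
#' band and membrane reactions to their membrane regardless of pathway;
#' pathway-less cytosolic reactions go to the unassigned grid. Transporter
#' proteins are embedded in a membrane band (outer if any of their reactions
#' is outer-membrane, else inner).
#'
#' @param pgdb a [PGDB-class].
#' @return data.frame (frameId, kind, region, column); column is one of
#'   left/middle/right for cytoplasmic pathways and their reactions, NA
#'   otherwise.
#' @export
assignRegions <- function(pgdb) {
  rows <- list()
  add <- function(frameId, kind, region, column = NA_character_)
    rows[[length(rows) + 1L]] <<- data.frame(frameId = frameId, kind = kind,
                                             region = region, column = column,
                                             stringsAsFactors = FALSE)
  pws <- entitiesOfKind(pgdb, "pathway")
  pwRegion <- character(0)
  pwColumn <- character(0)
  for (p in pws) {
    reg <- if (p$category == "signal") "signal_strip" else "cytoplasm"
    col <- categoryColumn[[p$category]]
    pwRegion[p$frameId] <- reg
    pwColumn[p$frameId] <- col
    add(p$frameId, "pathway", reg, col)
  }
  for (r in entitiesOfKind(pgdb, "reaction")) {
    if (r$compartment == "periplasm") add(r$frameId, "reaction", "periplasm")
    else if (r$compartment %in% c("inner_membrane", "outer_membrane"))
      add(r$frameId, "reaction", r$compartment)
    else if (length(r$pathways) == 0) add(r$frameId, "reaction", "unassigned_grid")
    else {
      host <- sort(r$pathways)[1]
      add(r$frameId, "reaction", pwRegion[[host]], pwColumn[[host]])
    }
  }
  for (pr in entitiesOfKind(pgdb, "protein")) {
    if (!isTRUE(pr$isTransporter)) next
    rxns <- Filter(function(e) e$kind == "reaction" && pr$frameId %in% e$enzymes,
                   pgdb@entities)
    comps <- vapply(rxns, function(e) e$compartment, "")
    band <- if (any(comps == "outer_membrane")) "outer_membrane" else "inner_membrane"
    add(pr$frameId, "protein", band)
  }
  if (!length(rows))
    return(data.frame(frameId = character(0), kind = character(0),
                      region = character(0), column = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

emptyGlyphs <- function() data.frame(
  glyphId = character(0), frameId = character(0), kind = character(0),
  gclass = character(0), shape = character(0), x = numeric(0), y = numeric(0),
  size = numeric(0), region = character(0), pathway = character(0),
  stringsAsFactors = FALSE)

emptySegments <- function() data.frame(
  segId = character(0), frameId = character(0), pathway = character(0),
  region = character(0), x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
  y1 = numeric(0), stringsAsFactors = FALSE)

emptyLabels <- function() data.frame(
  labelId = character(0), frameId = character(0), text = character(0),
  class = character(0), x = numeric(0), y = numeric(0),
  anchorGlyph = character(0), stringsAsFactors = FALSE)

emptyBoxes <- function() data.frame(
  cluster = character(0), category = character(0), x0 = numeric(0),
  y0 = numeric(0), x1 = numeric(0), y1 = numeric(0), stringsAsFactors = FALSE)

# ---- pathway chain geometry (local coordinates) ----------------------------

# Choose the main substrate/product of each step so consecutive steps chain
# through a shared compound where the network allows it; shared chain nodes
# are emitted at identical coordinates and collapsed by duplicateMetabolites().
chainPlan <- function(pgdb, rxnIds) {
  n <- length(rxnIds)
  plan <- vector("list", n)
  prevMain <- NA_character_
  for (i in seq_len(n)) {
    r <- entity(pgdb, rxnIds[i])
    subs <- names(r$substrates); prods <- names(r$products)
    mainSub <- if (!is.na(prevMain) && prevMain %in% subs) prevMain
               else if (length(subs)) subs[1] else NA_character_
    nxtSubs <- if (i < n) names(entity(pgdb, rxnIds[i + 1])$substrates) else character(0)
    shared <- intersect(prods, nxtSubs)
    mainProd <- if (length(shared)) shared[1] else if (length(prods)) prods[1] else NA_character_
    plan[[i]] <- list(
      rxn = rxnIds[i],
      mainSub = mainSub, chained = !is.na(prevMain) && identical(mainSub, prevMain),
      sideSubs = setdiff(subs, mainSub),
      mainProd = mainProd, sideProds = setdiff(prods, mainProd))
    prevMain <- mainProd
  }
  plan
}

# Emit glyph/segment/label rows for one pathway chain with its local origin
# at (x0, y0). Returns list(glyphs, segments, labels, width, height).
drawChain <- function(pgdb, pwId, rxnIds, x0, y0, region, p,
                      withPathwayLabel = TRUE) {
  G <- list(); S <- list(); L <- list()
  xc <- x0 + 24
  addG <- function(frameId, kind, gclass, shape, x, y, size)
    G[[length(G) + 1L]] <<- data.frame(
      glyphId = NA_character_, frameId = frameId, kind = kind, gclass = gclass,
      shape = shape, x = x, y = y, size = size, region = region,
      pathway = pwId %||% NA_character_, stringsAsFactors = FALSE)
  addS <- function(frameId, xx0, yy0, xx1, yy1)
    S[[length(S) + 1L]] <<- data.frame(
      segId = NA_character_, frameId = frameId,
      pathway = pwId %||% NA_character_, region = region,
      x0 = xx0, y0 = yy0, x1 = xx1, y1 = yy1, stringsAsFactors = FALSE)
  addL <- function(frameId, text, class, x, y)
    L[[length(L) + 1L]] <<- data.frame(
      labelId = NA_character_, frameId = frameId, text = text, class = class,
      x = x, y = y, anchorGlyph = NA_character_, stringsAsFactors = FALSE)

  top <- if (withPathwayLabel) y0 + p$topPad else y0 + 8
  if (withPathwayLabel && !is.null(pwId)) {
    pw <- entity(pgdb, pwId)
    addL(pwId, pw$name, "pathway_name", x0 - 8, y0 + 4)
  }
  plan <- chainPlan(pgdb, rxnIds)
  for (i in seq_along(plan)) {
    st <- plan[[i]]
    r <- entity(pgdb, st$rxn)
    yTop <- top + (i - 1) * p$stepH
    yBot <- yTop + p$stepH
    addS(st$rxn, xc, yTop + p$nodeR + 1, xc, yBot - p$nodeR - 1)
    if (!is.na(st$mainSub) && !(st$chained && i > 1)) {
      addG(st$mainSub, "compound", "glyph_compound", "circle", xc, yTop, p$nodeR)
      addL(st$mainSub, entity(pgdb, st$mainSub)$name, "compound_name",
           xc + p$nodeR + 2, yTop - 3)
    }
    for (j in seq_along(st$sideSubs)) {
      sx <- xc - p$sideDx - 10 * ((j - 1) %/% 2)
      sy <- yTop + 12 + 10 * ((j - 1) %% 2)
      addG(st$sideSubs[j], "compound", "glyph_compound", "triangle", sx, sy, p$sideR)
      addL(st$sideSubs[j], entity(pgdb, st$sideSubs[j])$name, "compound_name",
           sx - 2, sy - 10)
    }
    if (!is.na(st$mainProd)) {
      addG(st$mainProd, "compound", "glyph_compound", "circle", xc, yBot, p$nodeR)
      addL(st$mainProd, entity(pgdb, st$mainProd)$name, "compound_name",
           xc + p$nodeR + 2, yBot - 3)
    }
    for (j in seq_along(st$sideProds)) {
      sx <- xc + p$sideDx + 10 * ((j - 1) %/% 2)
      sy <- yTop + p$stepH - 12 - 10 * ((j - 1) %% 2)
      addG(st$sideProds[j], "compound", "glyph_compound", "triangle", sx, sy, p$sideR)
      addL(st$sideProds[j], entity(pgdb, st$sideProds[j])$name, "compound_name",
           sx + p$sideR + 2, sy - 3)
    }
    enz <- r$enzymes
    for (k in seq_along(enz)) {
      pr <- entity(pgdb, enz[k])
      ey <- yTop + p$stepH / 2 + 12 * (k - 1)
      addG(enz[k], "protein",
           if (isTRUE(pr$isTransporter)) "glyph_transporter" else "glyph_enzyme",
           "box", xc + p$enzDx, ey, p$enzHalf)
      addL(enz[k], pr$name, "enzyme_name", xc + p$enzDx + p$enzHalf + 2, ey - 3)
      for (g in pr$genes)
        addL(g, entity(pgdb, g)$name, "gene_name",
             xc + p$enzDx + p$enzHalf + 2, ey + 5)
    }
    if (length(r$ec))
      addL(st$rxn, r$ec[1], "ec_number", xc + 4, yTop + p$stepH / 2 - 12)
  }
  h <- (top - y0) + length(plan) * p$stepH + p$bottomPad
  list(glyphs = G, segments = S, labels = L, width = p$pwCellW, height = h)
}

#' Collapse coincident metabolite glyph occurrences
#'
#' Each reaction renders its own substrate and product glyphs locally; within
#' a pathway's linear chain, consecutive steps emit their shared intermediate
#' at identical coordinates. This pass collapses glyph rows with identical
#' (frameId, x, y) into one glyph, so a metabolite shared by two chain steps
#' owns a single glyph while the same metabolite used in another pathway (or
#' another grid cell) keeps its own duplicate glyph. No connecting edges are
#' ever added between duplicate glyphs.
#'
#' @param master a [MasterLayout-class].
#' @return the layout with collapsed glyphs and deduplicated labels.
#' @export
duplicateMetabolites <- function(master) {
  g <- master@glyphs
  if (nrow(g)) {
    key <- paste(g$frameId, g$x, g$y, sep = "\r")
    g <- g[!duplicated(key), , drop = FALSE]
    g$glyphId <- sprintf("g%04d", seq_len(nrow(g)))
    rownames(g) <- NULL
  }
  l <- master@labels
  if (nrow(l)) {
    lk <- paste(l$frameId, l$class, l$x, l$y, sep = "\r")
    l <- l[!duplicated(lk), , drop = FALSE]
    l$labelId <- sprintf("L%04d", seq_len(nrow(l)))
    rownames(l) <- NULL
  }
  methods::initialize(master, glyphs = g, labels = l)
}

# ---- the master layout -----------------------------------------------------

#' Compute the zoom-independent master layout
#'
#' Step 1 of the base-image pipeline: places every drawable object once, in
#' master coordinates. Deterministic: the same PGDB always yields an
#' identical layout. Clusters are packed per column in category order,
#' pathways within a cluster by descending reaction count (ties by frame ID).
#'
#' @param pgdb a validated [PGDB-class].
#' @param params see [layoutParams()].
#' @return a [MasterLayout-class].
#' @export
layoutMaster <- function(pgdb, params = layoutParams()) {
  p <- params
  regmap <- assignRegions(pgdb)
  rxnRegion <- stats::setNames(regmap$region[regmap$kind == "reaction"],
                               regmap$frameId[regmap$kind == "reaction"])

  allG <- list(); allS <- list(); allL <- list(); boxes <- list()
  collect <- function(d) {
    allG[[length(allG) + 1L]] <<- d$glyphs
    allS[[length(allS) + 1L]] <<- d$segments
    allL[[length(allL) + 1L]] <<- d$labels
  }

  bandTopY <- c(extracellular = 0, outer_membrane = p$extracellularH,
                periplasm = p$extracellularH + p$outerMembraneH,
                inner_membrane = p$extracellularH + p$outerMembraneH + p$periplasmH)
  cytoY <- p$extracellularH + p$outerMembraneH + p$periplasmH + p$innerMembraneH

  # pathway -> reactions it actually draws (compartment precedence + draw-once)
  pws <- entitiesOfKind(pgdb, "pathway")
  pws <- pws[order(names(pws))]
  drawnBy <- character(0)
  pwDraws <- list()
  for (pw in pws) {
    mine <- pw$reactions[rxnRegion[pw$reactions] %in% c("cytoplasm", "signal_strip")]
    mine <- mine[!mine %in% names(drawnBy)]
    drawnBy[mine] <- pw$frameId
    pwDraws[[pw$frameId]] <- mine
  }

  # cluster grouping per column
  clusterOf <- function(pw) pw$cluster %||% paste(pw$category, "pathways")
  colOf <- vapply(pws, function(pw) categoryColumn[[pw$category]] %||% NA_character_, "")
  columns <- list(left = character(0), middle = character(0), right = character(0))
  signalPws <- character(0)
  for (pw in pws) {
    if (pw$category == "signal") signalPws <- c(signalPws, pw$frameId)
    else columns[[colOf[[pw$frameId]]]] <- c(columns[[colOf[[pw$frameId]]]], pw$frameId)
  }

  # measure one cluster: pathways side by side, sorted by desc reaction count
  planCluster <- function(pwIds) {
    cnt <- vapply(pwIds, function(id) length(pwDraws[[id]]), 0L)
    pwIds <- pwIds[order(-cnt, pwIds)]
    pwIds <- pwIds[vapply(pwIds, function(id) length(pwDraws[[id]]) > 0, TRUE)]
    if (!length(pwIds)) return(NULL)
    hts <- vapply(pwIds, function(id)
      p$topPad + length(pwDraws[[id]]) * p$stepH + p$bottomPad, 0)
    list(pwIds = pwIds,
         w = 2 * p$clusterPad + length(pwIds) * p$pwCellW +
             (length(pwIds) - 1) * p$pwGap,
         h = 2 * p$clusterPad + p$clusterLabelH + max(hts))
  }

  emitCluster <- function(plan, clusterName, category, x0, y0, region) {
    boxes[[length(boxes) + 1L]] <<- data.frame(
      cluster = clusterName, category = category, x0 = x0, y0 = y0,
      x1 = x0 + plan$w, y1 = y0 + plan$h, stringsAsFactors = FALSE)
    allL[[length(allL) + 1L]] <<- list(data.frame(
      labelId = NA_character_, frameId = clusterName, text = clusterName,
      class = "cluster_name", x = x0 + 4, y = y0 + 3,
      anchorGlyph = NA_character_, stringsAsFactors = FALSE))
    px <- x0 + p$clusterPad
    for (id in plan$pwIds) {
      collect(drawChain(pgdb, id, pwDraws[[id]], px,
                        y0 + p$clusterPad + p$clusterLabelH, region, p))
      px <- px + p$pwCellW + p$pwGap
    }
  }

  # pack the three cytoplasm columns
  colX <- p$margin
  colBottom <- cytoY + p$cytoTopGap
  colRights <- c(left = NA_real_, middle = NA_real_, right = NA_real_)
  colLefts <- c(left = NA_real_, middle = NA_real_, right = NA_real_)
  for (colName in c("left", "middle", "right")) {
    ids <- columns[[colName]]
    cl <- split(ids, vapply(ids, function(id) clusterOf(entity(pgdb, id)), ""))
    cl <- cl[order(names(cl))]
    plans <- lapply(cl, planCluster)
    plans <- plans[!vapply(plans, is.null, TRUE)]
    if (!length(plans)) next
    colW <- max(vapply(plans, function(pl) pl$w, 0))
    y <- cytoY + p$cytoTopGap
    for (nm in names(plans)) {
      cat0 <- entity(pgdb, cl[[nm]][1])$category
      emitCluster(plans[[nm]], nm, cat0, colX, y, "cytoplasm")
      y <- y + plans[[nm]]$h + p$clusterGapY
    }
    colLefts[colName] <- colX
    colRights[colName] <- colX + colW
    colBottom <- max(colBottom, y - p$clusterGapY)
    colX <- colX + colW + p$colGap
  }

  # unassigned-reaction grid, right of the rightmost column
  gridRxns <- sort(names(rxnRegion)[rxnRegion == "unassigned_grid"])
  gridX <- colX + if (any(!is.na(colRights))) p$gridGap - p$colGap else 0
  gridY <- cytoY + p$cytoTopGap
  dims <- gridDims(length(gridRxns), p$gridCols)
  for (i in seq_along(gridRxns)) {
    row <- (i - 1) %/% p$gridCols; col <- (i - 1) %% p$gridCols
    cx <- gridX + col * p$gridCellW
    cy <- gridY + row * p$gridCellH
    collect(drawChain(pgdb, NULL, gridRxns[i], cx, cy, "unassigned_grid", p,
                      withPathwayLabel = FALSE))
  }
  gridW <- dims[2] * p$gridCellW
  gridH <- dims[1] * p$gridCellH

  # signal strip below the left column
  sigY <- colBottom + p$signalGapY
  sigX <- p$margin
  sigH <- 0
  if (length(signalPws)) {
    cl <- split(signalPws,
                vapply(signalPws, function(id) clusterOf(entity(pgdb, id)), ""))
    cl <- cl[order(names(cl))]
    for (nm in names(cl)) {
      plan <- planCluster(cl[[nm]])
      if (is.null(plan)) next
      emitCluster(plan, nm, "signal", sigX, sigY, "signal_strip")
      sigX <- sigX + plan$w + p$pwGap
      sigH <- max(sigH, plan$h)
    }
  }

  # RNAs (tRNAs etc.): tee icons stacked along the left edge of the cytoplasm
  rnas <- entitiesOfKind(pgdb, "rna")
  rnas <- rnas[order(names(rnas))]
  rnaBottom <- 0
  for (i in seq_along(rnas)) {
    rn <- rnas[[i]]
    ry <- cytoY + p$cytoTopGap + 12 + (i - 1) * 18
    allG[[length(allG) + 1L]] <- list(data.frame(
      glyphId = NA_character_, frameId = rn$frameId, kind = "rna",
      gclass = "glyph_rna", shape = "tee", x = 12, y = ry, size = 4,
      region = "cytoplasm", pathway = NA_character_, stringsAsFactors = FALSE))
    allL[[length(allL) + 1L]] <- list(data.frame(
      labelId = NA_character_, frameId = rn$frameId, text = rn$name,
      class = "rna_name", x = 18, y = ry - 3, anchorGlyph = NA_character_,
      stringsAsFactors = FALSE))
    rnaBottom <- ry + 10
  }

  # canvas width now known
  contentRight <- max(p$margin + 200, colX - p$colGap,
                      gridX + gridW, if (sigH > 0) sigX - p$pwGap else 0)
  canvasW <- contentRight + p$margin
  canvasH <- max(colBottom, gridY + gridH, rnaBottom,
                 if (sigH > 0) sigY + sigH else 0, cytoY + 100) + p$margin
  if (canvasW > p$canvasMax || canvasH > p$canvasMax)
    stop(sprintf("canvas overflow: layout needs %gx%g master units, max is %gx%g",
                 canvasW, canvasH, p$canvasMax, p$canvasMax), call. = FALSE)

  # periplasmic reactions: right side of the band between the membranes
  periRxns <- sort(names(rxnRegion)[rxnRegion == "periplasm"])
  periTop <- bandTopY[["periplasm"]]
  for (i in seq_along(periRxns)) {
    cx <- canvasW - p$margin - (i - 1) * p$periRxnGap - 44
    collect(drawChain(pgdb, NULL, periRxns[i], cx, periTop + 2, "periplasm",
                      layoutParams(stepH = p$periplasmH - 20, nodeR = p$nodeR,
                                   sideDx = p$sideDx, sideR = p$sideR,
                                   enzDx = p$enzDx, enzHalf = p$enzHalf,
                                   bottomPad = 2),
                      withPathwayLabel = FALSE))
  }

  # transporters embedded in their membrane band; each membrane reaction is
  # drawn once as a line crossing its band at the transporter slot
  transMap <- regmap[regmap$kind == "protein", , drop = FALSE]
  memRxns <- sort(names(rxnRegion)[rxnRegion %in% c("inner_membrane", "outer_membrane")])
  slot <- c(inner_membrane = 0L, outer_membrane = 0L)
  placedTrans <- character(0)
  bandH <- c(inner_membrane = p$innerMembraneH, outer_membrane = p$outerMembraneH)
  for (rid in memRxns) {
    r <- entity(pgdb, rid)
    band <- r$compartment
    slot[band] <- slot[band] + 1L
    x <- p$margin + 30 + (slot[band] - 1L) * p$transporterGap
    top <- bandTopY[[band]]; bot <- top + bandH[[band]]
    hasTrans <- any(vapply(r$enzymes, function(en)
      isTRUE(entity(pgdb, en)$isTransporter), TRUE))
    # the transport line is drawn as stubs either side of the band so the
    # embedded transporter box (and the hit corridors) stay unambiguous
    segRows <- if (hasTrans) list(c(top - 14, top - 8), c(bot + 8, bot + 14))
               else list(c(top - 14, bot + 14))
    for (sr in segRows)
      allS[[length(allS) + 1L]] <- list(data.frame(
        segId = NA_character_, frameId = rid, pathway = NA_character_,
        region = band, x0 = x, y0 = sr[1], x1 = x, y1 = sr[2],
        stringsAsFactors = FALSE))
    gl <- list()
    subs <- names(r$substrates); prods <- names(r$products)
    if (length(subs))
      gl[[length(gl) + 1L]] <- data.frame(
        glyphId = NA_character_, frameId = subs[1], kind = "compound",
        gclass = "glyph_compound", shape = "circle", x = x, y = top - 18,
        size = p$sideR, region = band, pathway = NA_character_,
        stringsAsFactors = FALSE)
    if (length(prods))
      gl[[length(gl) + 1L]] <- data.frame(
        glyphId = NA_character_, frameId = prods[1], kind = "compound",
        gclass = "glyph_compound", shape = "circle", x = x, y = bot + 18,
        size = p$sideR, region = band, pathway = NA_character_,
        stringsAsFactors = FALSE)
    for (en in r$enzymes) {
      pr <- entity(pgdb, en)
      if (isTRUE(pr$isTransporter) && !en %in% placedTrans) {
        placedTrans <- c(placedTrans, en)
        gl[[length(gl) + 1L]] <- data.frame(
          glyphId = NA_character_, frameId = en, kind = "protein",
          gclass = "glyph_transporter", shape = "box", x = x,
          y = (top + bot) / 2, size = bandH[[band]] / 2 + 4,
          region = band, pathway = NA_character_, stringsAsFactors = FALSE)
        allL[[length(allL) + 1L]] <- list(data.frame(
          labelId = NA_character_, frameId = en, text = pr$name,
          class = "enzyme_name", x = x + p$transporterHalfW + 3, y = (top + bot) / 2 - 3,
          anchorGlyph = NA_character_, stringsAsFactors = FALSE))
      }
    }
    allG[[length(allG) + 1L]] <- gl
  }
  # transporters never seen on a membrane reaction still get a membrane slot
  for (i in seq_len(nrow(transMap))) {
    en <- transMap$frameId[i]
    if (en %in% placedTrans) next
    band <- transMap$region[i]
    slot[band] <- slot[band] + 1L
    x <- p$margin + 30 + (slot[band] - 1L) * p$transporterGap
    top <- bandTopY[[band]]; bot <- top + bandH[[band]]
    allG[[length(allG) + 1L]] <- list(data.frame(
      glyphId = NA_character_, frameId = en, kind = "protein",
      gclass = "glyph_transporter", shape = "box", x = x, y = (top + bot) / 2,
      size = bandH[[band]] / 2 + 4, region = band, pathway = NA_character_,
      stringsAsFactors = FALSE))
  }

  regions <- data.frame(
    name = c("extracellular", "outer_membrane", "periplasm", "inner_membrane",
             "cytoplasm"),
    x0 = 0,
    y0 = c(0, bandTopY[["outer_membrane"]], bandTopY[["periplasm"]],
           bandTopY[["inner_membrane"]], cytoY),
    x1 = canvasW,
    y1 = c(bandTopY[["outer_membrane"]], bandTopY[["periplasm"]],
           bandTopY[["inner_membrane"]], cytoY, canvasH),
    stringsAsFactors = FALSE)
  if (length(gridRxns))
    regions <- rbind(regions, data.frame(
      name = "unassigned_grid", x0 = gridX - 8, y0 = gridY - 8,
      x1 = gridX + gridW + 8, y1 = gridY + gridH + 8, stringsAsFactors = FALSE))
  if (sigH > 0)
    regions <- rbind(regions, data.frame(
      name = "signal_strip", x0 = p$margin - 8, y0 = sigY - 8,
      x1 = sigX - p$pwGap + 8, y1 = sigY + sigH + 8, stringsAsFactors = FALSE))

  bindOr <- function(lst, empty) {
    flat <- unlist(lst, recursive = FALSE)
    if (!length(flat)) empty else do.call(rbind, flat)
  }
  g <- bindOr(allG, emptyGlyphs())
  s <- bindOr(allS, emptySegments())
  l <- bindOr(allL, emptyLabels())
  if (nrow(s)) { s$segId <- sprintf("s%04d", seq_len(nrow(s))); rownames(s) <- NULL }

  master <- new("MasterLayout", canvasWidth = canvasW, canvasHeight = canvasH,
                regions = regions,
                clusterBoxes = if (length(boxes)) do.call(rbind, boxes) else emptyBoxes(),
                glyphs = g, segments = s, labels = l)
  duplicateMetabolites(master)
}
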