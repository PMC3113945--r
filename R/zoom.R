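# Semantic zoom: specialize the master layout per level. Six levels by
# default, scale factor 2 between adjacent levels; level 0 is the lowest
# magnification (32 master units per pixel), the deepest level renders at
# 1:1. The feature policy is monotone: anything drawn at level k is drawn at
# every higher level.

#' Default semantic-zoom feature policy
#'
#' Minimum zoom level at which each object / label class appears. Level 0
#' shows glyphs (compounds, transporters, RNAs), reaction lines and cluster
#' shading; enzymes are withheld until level 2 (never shown at the lowest
#' level); pathway and cluster names appear at level 1, compound names at
#' level 3, enzyme/gene/RNA names at level 4, EC numbers at level 5. Fully
#' configurable; any replacement must keep `minLevel` monotone semantics
#' (a class appears at its `minLevel` and every level above).
#'
#' @return named integer vector, feature class -> minimum level.
#' @export
zoomPolicy <- function() {
  c(glyph_compound = 0L, glyph_transporter = 0L, glyph_rna = 0L,
    segment = 0L, cluster_box = 0L, region = 0L,
    glyph_enzyme = 2L,
    cluster_name = 1L, pathway_name = 1L,
    compound_name = 3L,
    enzyme_name = 4L, gene_name = 4L, rna_name = 4L,
    ec_number = 5L)
}

#' @rdname zoomPolicy
#' @param level zoom level index.
#' @param levels total number of levels in the pyramid.
#' @export
zoomScale <- function(level, levels = 6L) 2^(levels - 1L - level)

roundHalfUp <- function(x) floor(x + 0.5)

labelBox <- function(xpx, ypx, text, font = FONT5X7) {
  w <- textWidth(text, font)
  c(x0 = xpx, y0 = ypx, x1 = xpx + w, y1 = ypx + font$height)
}

boxesOverlap <- function(a, bx0, by0, bx1, by1) {
  a[1] < bx1 & a[3] > bx0 & a[2] < by1 & a[4] > by0
}

#' Specialize the master layout at every zoom level
#'
#' Applies the feature policy, converts master units to pixels (rounding
#' half-up, once), and runs the label-fit rule. A label is dropped — never
#' truncated — if its text box at the level's font size would collide with a
#' glyph or an already-placed label; candidates are processed in a fixed
#' deterministic order. Placements cascade upward: a label placed at level k
#' is kept at level k+1 (where the doubled geometry guarantees it still
#' overlaps no other label), so the drawn-element set is monotone
#' non-decreasing in the zoom index.
#'
#' @param master a [MasterLayout-class].
#' @param levels number of zoom levels (default 6).
#' @param policy a feature policy, see [zoomPolicy()].
#' @return list of [ZoomLayout-class], one per level (index 1 = level 0).
#' @export
specializeAll <- function(master, levels = 6L, policy = zoomPolicy()) {
  g <- master@glyphs; s <- master@segments; l <- master@labels
  placedPrev <- character(0)
  out <- vector("list", levels)
  for (lev in seq_len(levels) - 1L) {
    sc <- zoomScale(lev, levels)
    W <- as.integer(ceiling(master@canvasWidth / sc))
    H <- as.integer(ceiling(master@canvasHeight / sc))

    gk <- g[policy[g$gclass] <= lev, , drop = FALSE]
    if (nrow(gk)) {
      gk$px <- roundHalfUp(gk$x / sc); gk$py <- roundHalfUp(gk$y / sc)
      gk$psize <- pmax(1, roundHalfUp(gk$size / sc))
    } else { gk$px <- numeric(0); gk$py <- numeric(0); gk$psize <- numeric(0) }

    sk <- s
    if (nrow(sk)) {
      sk$px0 <- roundHalfUp(sk$x0 / sc); sk$py0 <- roundHalfUp(sk$y0 / sc)
      sk$px1 <- roundHalfUp(sk$x1 / sc); sk$py1 <- roundHalfUp(sk$y1 / sc)
    } else { sk$px0 <- sk$py0 <- sk$px1 <- sk$py1 <- numeric(0) }

    boxes <- master@clusterBoxes
    if (nrow(boxes)) {
      boxes$px0 <- roundHalfUp(boxes$x0 / sc); boxes$py0 <- roundHalfUp(boxes$y0 / sc)
      boxes$px1 <- roundHalfUp(boxes$x1 / sc); boxes$py1 <- roundHalfUp(boxes$y1 / sc)
    } else { boxes$px0 <- boxes$py0 <- boxes$px1 <- boxes$py1 <- numeric(0) }

    regs <- master@regions
    if (nrow(regs)) {
      regs$px0 <- roundHalfUp(regs$x0 / sc); regs$py0 <- roundHalfUp(regs$y0 / sc)
      regs$px1 <- roundHalfUp(regs$x1 / sc); regs$py1 <- roundHalfUp(regs$y1 / sc)
    } else { regs$px0 <- regs$py0 <- regs$px1 <- regs$py1 <- numeric(0) }

    # label fit: greedy in labelId order; inherit lower-level placements
    cand <- l[policy[l$class] <= lev, , drop = FALSE]
    placedBoxes <- matrix(numeric(0), ncol = 4)
    placedIds <- character(0)
    if (nrow(cand)) {
      cand <- cand[order(cand$labelId), , drop = FALSE]
      cand$px <- roundHalfUp(cand$x / sc); cand$py <- roundHalfUp(cand$y / sc)
      glyphBx <- cbind(gk$px - gk$psize, gk$py - gk$psize,
                       gk$px + gk$psize, gk$py + gk$psize)
      # inherited placements first: labels shown at a lower level stay shown,
      # and new candidates must clear them
      inherited <- cand$labelId %in% placedPrev
      for (i in which(inherited)) {
        placedBoxes <- rbind(placedBoxes,
                             labelBox(cand$px[i], cand$py[i], cand$text[i]))
        placedIds <- c(placedIds, cand$labelId[i])
      }
      for (i in which(!inherited)) {
        bx <- labelBox(cand$px[i], cand$py[i], cand$text[i])
        hitG <- nrow(glyphBx) > 0 &&
          any(boxesOverlap(bx, glyphBx[, 1], glyphBx[, 2], glyphBx[, 3], glyphBx[, 4]))
        hitL <- nrow(placedBoxes) > 0 &&
          any(boxesOverlap(bx, placedBoxes[, 1], placedBoxes[, 2],
                           placedBoxes[, 3], placedBoxes[, 4]))
        if (!hitG && !hitL && bx[3] <= W && bx[4] <= H && bx[1] >= 0 && bx[2] >= 0) {
          placedBoxes <- rbind(placedBoxes, bx)
          placedIds <- c(placedIds, cand$labelId[i])
        }
      }
    }
    lk <- cand[cand$labelId %in% placedIds, , drop = FALSE]
    if (nrow(lk)) {
      lk$bx0 <- lk$px; lk$by0 <- lk$py
      lk$bx1 <- lk$px + vapply(lk$text, textWidth, 0)
      lk$by1 <- lk$py + FONT5X7$height
    } else { lk$px <- lk$py <- lk$bx0 <- lk$by0 <- lk$bx1 <- lk$by1 <- numeric(0) }
    placedPrev <- union(placedPrev, placedIds)

    out[[lev + 1L]] <- new("ZoomLayout", level = as.integer(lev), scale = sc,
                           width = W, height = H, glyphs = gk, segments = sk,
                           clusterBoxes = boxes, regions = regs, labels = lk)
  }
  out
}

#' Specialize the master layout at one zoom level
#'
#' Step 2 of the base-image pipeline for a single level. Internally computes
#' the lower levels too (the label-fit cascade is defined bottom-up), so
#' prefer [specializeAll()] when several levels are needed.
#'
#' @inheritParams specializeAll
#' @param level zoom level index in 0 .. levels-1.
#' @return a [ZoomLayout-class].
#' @export
specializeLayout <- function(master, level, levels = 6L, policy = zoomPolicy()) {
  level <- as.integer(level)
  if (level < 0L || level >= levels)
    stop("zoom level must be in 0..", levels - 1L, call. = FALSE)
  specializeAll(master, levels = levels, policy = policy)[[level + 1L]]
}
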