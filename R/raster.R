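# Raster primitives. A raster is a numeric array [height, width, 3] with
# channel values in [0, 1] (the layout used by the png package). Drawing
# happens on a canvas environment holding the array, so pixel writes are
# in-place (one reference) rather than copy-on-write; the finished buffer is
# returned as a plain array. All drawing is integer pixel arithmetic --
# byte-deterministic and independent of the eventual encoded format.

hex2rgb <- function(hex) as.vector(grDevices::col2rgb(hex)) / 255

#' Create a blank raster
#'
#' @param width,height dimensions in pixels.
#' @param bg background color (hex string).
#' @return numeric array `[height, width, 3]` in `[0, 1]`.
#' @export
newRaster <- function(width, height, bg = "#FFFFFF") {
  rgb <- hex2rgb(bg)
  array(rep(rgb, each = height * width), dim = c(height, width, 3))
}

# A canvas buffers pixel writes (linear indices + per-pixel color channels)
# and applies them in three vectorized assignments at commit time; with
# duplicated indices the last write wins, preserving draw order.
newCanvas <- function(width, height, bg = "#FFFFFF") {
  cv <- new.env(parent = emptyenv())
  cv$bg <- bg
  cv$base <- NULL
  cv$w <- as.integer(width); cv$h <- as.integer(height)
  cv$idx <- list(); cv$r <- list(); cv$g <- list(); cv$b <- list()
  cv
}

asCanvas <- function(img) {
  cv <- newCanvas(dim(img)[2], dim(img)[1])
  cv$base <- img
  cv
}

cvCommit <- function(cv) {
  px <- if (is.null(cv$base)) newRaster(cv$w, cv$h, cv$bg) else cv$base + 0
  idx <- unlist(cv$idx, use.names = FALSE)
  if (length(idx)) {
    n <- cv$h * cv$w
    px[idx] <- unlist(cv$r, use.names = FALSE)
    px[idx + n] <- unlist(cv$g, use.names = FALSE)
    px[idx + 2 * n] <- unlist(cv$b, use.names = FALSE)
  }
  px
}

cvPush <- function(cv, idx, rgb) {
  k <- length(cv$idx) + 1L
  cv$idx[[k]] <- idx
  m <- length(idx)
  cv$r[[k]] <- rep.int(rgb[1], m)
  cv$g[[k]] <- rep.int(rgb[2], m)
  cv$b[[k]] <- rep.int(rgb[3], m)
  invisible(cv)
}

cvSetPixels <- function(cv, xs, ys, col) {
  keep <- xs >= 1 & xs <= cv$w & ys >= 1 & ys <= cv$h
  xs <- xs[keep]; ys <- ys[keep]
  if (!length(xs)) return(invisible(cv))
  cvPush(cv, (xs - 1) * cv$h + ys, hex2rgb(col))
}

cvFillRect <- function(cv, x0, y0, x1, y1, col) {
  if (x1 < 1 || x0 > cv$w || y1 < 1 || y0 > cv$h) return(invisible(cv))
  xs <- max(x0, 1):min(x1, cv$w); ys <- max(y0, 1):min(y1, cv$h)
  idx <- rep((xs - 1) * cv$h, each = length(ys)) + ys
  cvPush(cv, idx, hex2rgb(col))
}

cvStrokeRect <- function(cv, x0, y0, x1, y1, col) {
  cvFillRect(cv, x0, y0, x1, y0, col)
  cvFillRect(cv, x0, y1, x1, y1, col)
  cvFillRect(cv, x0, y0, x0, y1, col)
  cvFillRect(cv, x1, y0, x1, y1, col)
}

# Bresenham-style line; width grows the stroke perpendicular to the major axis
cvLine <- function(cv, x0, y0, x1, y1, col, width = 1) {
  n <- max(abs(x1 - x0), abs(y1 - y0)) + 1
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  if (width > 1) {
    r <- seq_len(width) - 1 - (width - 1) %/% 2
    if (abs(x1 - x0) >= abs(y1 - y0)) {
      ys <- rep(ys, times = length(r)) + rep(r, each = n)
      xs <- rep(xs, times = length(r))
    } else {
      xs <- rep(xs, times = length(r)) + rep(r, each = n)
      ys <- rep(ys, times = length(r))
    }
  }
  cvSetPixels(cv, xs, ys, col)
}

cvCircle <- function(cv, cx, cy, r, col) {
  dy <- seq(-r, r)
  dx <- floor(sqrt(pmax(r^2 - dy^2, 0)))
  xs <- unlist(lapply(seq_along(dy), function(i) (cx - dx[i]):(cx + dx[i])))
  ys <- rep(cy + dy, times = 2 * dx + 1)
  cvSetPixels(cv, xs, ys, col)
}

# upward-pointing triangle with half-extent r
cvTriangle <- function(cv, cx, cy, r, col) {
  rows <- seq(-r, r)
  hw <- floor((seq_along(rows) - 1) / length(rows) * (r + 0.5))
  xs <- unlist(lapply(seq_along(rows), function(i) (cx - hw[i]):(cx + hw[i])))
  ys <- rep(cy + rows, times = 2 * hw + 1)
  cvSetPixels(cv, xs, ys, col)
}

# 'tee' icon: vertical stem with a top crossbar
cvTee <- function(cv, cx, cy, r, col) {
  cvFillRect(cv, cx - r, cy - r, cx + r, cy - r + max(1, r %/% 2) - 1, col)
  cvFillRect(cv, cx, cy - r, cx, cy + r, col)
}

cvText <- function(cv, x, y, text, col, font = FONT5X7) {
  ch <- textChars(text, font)
  for (i in seq_along(ch)) {
    gl <- font$glyphs[[ch[i]]]
    ij <- which(gl, arr.ind = TRUE)
    if (nrow(ij))
      cvSetPixels(cv, x + (i - 1) * font$advance + ij[, 2] - 1,
                  y + ij[, 1] - 1, col)
  }
  invisible(cv)
}

#' Default rendering style
#'
#' Colors, glyph palette and font used by [renderImage()]. Reaction lines
#' are blue, cluster boxes are shaded, membranes drawn as solid bands.
#' Override any entry via `...` or load a YAML style file with
#' [readStyle()].
#'
#' @param ... name = value overrides (colors list entries are merged).
#' @return a style list.
#' @export
defaultStyle <- function(...) {
  st <- list(
    font = "builtin5x7",
    colors = list(
      background   = "#FFFEF5",
      extracellular = "#F4F2E4",
      membrane     = "#E3CF8C",
      periplasm    = "#EBF2F8",
      cluster      = "#E4EDE4",
      clusterBorder = "#B9CDB9",
      regionBorder = "#C8C8B4",
      reaction     = "#2222CC",
      compound     = "#8B2500",
      sideCompound = "#A06A00",
      enzyme       = "#2E6B2E",
      transporter  = "#7A3E8F",
      rna          = "#3A3A3A",
      label        = "#1A1A1A",
      highlight    = "#FF00FF",
      marker       = "#DD0000",
      missing      = "#9E9E9E"))
  ov <- list(...)
  if (!is.null(ov$colors)) {
    st$colors[names(ov$colors)] <- ov$colors
    ov$colors <- NULL
  }
  st[names(ov)] <- ov
  st
}

#' Load a style configuration file
#'
#' YAML file with optional keys `font` and `colors` (a map of color names to
#' hex strings); unspecified entries keep their defaults.
#'
#' @param path YAML style file.
#' @return a style list.
#' @export
readStyle <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(defaultStyle, doc)
}

glyphColor <- function(st, gclass, shape) {
  cl <- st$colors
  switch(gclass,
         glyph_compound = if (shape == "triangle") cl$sideCompound else cl$compound,
         glyph_enzyme = cl$enzyme,
         glyph_transporter = cl$transporter,
         glyph_rna = cl$rna,
         cl$label)
}

#' Render one zoom level to a raster
#'
#' Step 3 of the base-image pipeline: draws regions, cluster shading,
#' reaction lines (blue), glyphs and fitted labels into a pixel buffer.
#' Purely deterministic; the buffer is independent of any encoded format.
#'
#' @param zl a [ZoomLayout-class].
#' @param style a style list, see [defaultStyle()].
#' @return numeric array `[height, width, 3]`.
#' @export
renderImage <- function(zl, style = defaultStyle()) {
  if (!identical(style$font, "builtin5x7"))
    stop("font not available: '", style$font, "'", call. = FALSE)
  cl <- style$colors
  cv <- newCanvas(zl@width, zl@height, cl$background)

  regs <- zl@regions
  for (i in seq_len(nrow(regs))) {
    colr <- switch(regs$name[i],
                   extracellular = cl$extracellular,
                   outer_membrane = cl$membrane,
                   inner_membrane = cl$membrane,
                   periplasm = cl$periplasm,
                   NA)
    if (!is.na(colr))
      cvFillRect(cv, regs$px0[i] + 1, regs$py0[i] + 1, regs$px1[i], regs$py1[i], colr)
    if (regs$name[i] %in% c("unassigned_grid", "signal_strip"))
      cvStrokeRect(cv, regs$px0[i] + 1, regs$py0[i] + 1, regs$px1[i], regs$py1[i],
                   cl$regionBorder)
  }
  bx <- zl@clusterBoxes
  for (i in seq_len(nrow(bx))) {
    cvFillRect(cv, bx$px0[i] + 1, bx$py0[i] + 1, bx$px1[i], bx$py1[i], cl$cluster)
    cvStrokeRect(cv, bx$px0[i] + 1, bx$py0[i] + 1, bx$px1[i], bx$py1[i],
                 cl$clusterBorder)
  }
  sg <- zl@segments
  for (i in seq_len(nrow(sg)))
    cvLine(cv, sg$px0[i] + 1, sg$py0[i] + 1, sg$px1[i] + 1, sg$py1[i] + 1,
           cl$reaction)
  g <- zl@glyphs
  for (i in seq_len(nrow(g))) {
    colr <- glyphColor(style, g$gclass[i], g$shape[i])
    x <- g$px[i] + 1; y <- g$py[i] + 1; r <- g$psize[i]
    switch(g$shape[i],
           circle = cvCircle(cv, x, y, r, colr),
           triangle = cvTriangle(cv, x, y, r, colr),
           box = cvFillRect(cv, x - r, y - r, x + r, y + r, colr),
           tee = cvTee(cv, x, y, r, colr))
  }
  lb <- zl@labels
  for (i in seq_len(nrow(lb)))
    cvText(cv, lb$px[i] + 1, lb$py[i] + 1, lb$text[i], cl$label)
  cvCommit(cv)
}
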