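# Omics viewer: parse a tab-delimited datafile of per-gene / -reaction /
# -compound / -protein values, resolve row labels to drawn map elements, map
# the value range to a color spectrum, and emit one overlay per experiment
# column (an animation frame sequence). Base tiles are never touched: each
# frame is a separate overlay plane.

#' Parse a tab-delimited omics datafile
#'
#' Rows are labeled with gene, reaction, compound or protein identifiers;
#' value columns are tab separated. A header row is auto-detected (first row
#' with a non-numeric cell in the value columns) and supplies experiment
#' names. `#` comment lines are skipped; LF and CRLF both accepted;
#' non-numeric cells become missing values; duplicate labels keep the last
#' row (with a warning).
#'
#' @param path datafile path.
#' @param columns optional integer vector selecting value columns (1-based,
#'   counted among value columns).
#' @return an [OmicsDataset-class].
#' @export
parseOmicsFile <- function(path, columns = NULL) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("\r$", "", raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (!length(raw)) stop("datafile is empty", call. = FALSE)
  cells <- strsplit(raw, "\t", fixed = TRUE)
  ncol <- max(lengths(cells))
  if (ncol < 2) stop("datafile has zero value columns", call. = FALSE)
  toNum <- function(v) suppressWarnings(as.numeric(v))

  first <- cells[[1]]
  firstVals <- toNum(first[-1])
  hasHeader <- any(is.na(firstVals) & nzchar(first[-1]) &
                     !toupper(first[-1]) %in% c("NA", "NAN"))
  if (hasHeader) {
    experiments <- first[-1]
    cells <- cells[-1]
  } else {
    experiments <- sprintf("exp%d", seq_len(ncol - 1))
  }
  if (!length(cells)) stop("datafile has no data rows", call. = FALSE)

  labels <- vapply(cells, `[`, "", 1)
  vals <- t(vapply(cells, function(r) {
    v <- toNum(r[-1])
    length(v) <- ncol - 1  # ragged rows padded with missing
    v
  }, numeric(ncol - 1)))
  if (ncol == 2) vals <- matrix(vals, ncol = 1)
  colnames(vals) <- experiments

  if (anyDuplicated(labels)) {
    warning("duplicate labels (last occurrence wins): ",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
    keep <- !duplicated(labels, fromLast = TRUE)
    labels <- labels[keep]; vals <- vals[keep, , drop = FALSE]
  }
  if (!is.null(columns)) {
    if (any(columns < 1 | columns > ncol(vals)))
      stop("column selection out of range 1..", ncol(vals), call. = FALSE)
    vals <- vals[, columns, drop = FALSE]
    experiments <- experiments[columns]
  }
  new("OmicsDataset", labels = labels, values = vals,
      experiments = colnames(vals))
}

#' Resolve dataset rows to drawn map elements
#'
#' Gene and protein labels map to their reaction steps (via the gene-product
#' and enzyme-reaction expansion maps), reaction labels to themselves,
#' compound labels to their (possibly duplicated) compound glyphs. Labels are
#' matched by frame ID (case-sensitive) first, then case-insensitively by
#' name or synonym. Unresolvable labels are reported, never fatal.
#'
#' @param ds an [OmicsDataset-class].
#' @param map a [CellMap-class].
#' @return list with `mapping` (named list: label -> list(reactions,
#'   compounds)) and `unresolved` (character vector). Resolved + unresolved
#'   counts always equal the dataset row count.
#' @export
resolveRows <- function(ds, map) {
  idx <- map@index
  st <- idx@strings
  pgdb <- map@pgdb
  drawnRxns <- unique(map@master@segments$frameId)
  drawnCpds <- unique(map@master@glyphs$frameId)

  resolveLabel <- function(lab) {
    if (pgdbHas(pgdb, lab)) return(lab)
    hit <- st$frameId[st$key == tolower(lab) & st$field %in% c("name", "synonym")]
    if (length(hit)) hit[1] else NA_character_
  }

  mapping <- list(); unresolved <- character(0)
  for (lab in ds@labels) {
    id <- resolveLabel(lab)
    el <- list(reactions = character(0), compounds = character(0))
    if (!is.na(id)) {
      e <- entity(pgdb, id)
      if (e$kind == "reaction") el$reactions <- id
      else if (e$kind == "compound") el$compounds <- id
      else if (e$kind == "protein")
        el$reactions <- idx@enzymeReactions[[id]] %||% character(0)
      else if (e$kind == "gene")
        el$reactions <- idx@geneProducts[[id]]$reactions %||% character(0)
    }
    el$reactions <- intersect(el$reactions, drawnRxns)
    el$compounds <- intersect(el$compounds, drawnCpds)
    if (length(el$reactions) + length(el$compounds) > 0) mapping[[lab]] <- el
    else unresolved <- c(unresolved, lab)
  }
  list(mapping = mapping, unresolved = unresolved)
}

#' Fit a color map to a dataset
#'
#' One shared map for the whole animation: the domain is the global
#' [min, max] across all selected columns, so the same value receives the
#' same color in every frame. `log10` requires strictly positive values.
#'
#' @param ds an [OmicsDataset-class].
#' @param ramp ordered color stops (default yellow - orange - red).
#' @param transform "identity" or "log10".
#' @param missingColor color for resolved rows with a missing value.
#' @return a [ColorMap-class].
#' @export
fitColorMap <- function(ds, ramp = c("#FFFF00", "#FF8C00", "#FF0000"),
                        transform = c("identity", "log10"),
                        missingColor = "#9E9E9E") {
  transform <- match.arg(transform)
  v <- ds@values
  if (all(is.na(v))) stop("dataset has no non-missing values", call. = FALSE)
  if (transform == "log10") {
    bad <- which(apply(v <= 0, 1, any, na.rm = TRUE))
    if (length(bad))
      stop("log10 transform requires positive values; offending row(s): ",
           paste(ds@labels[bad], collapse = ", "), call. = FALSE)
    v <- log10(v)
  }
  new("ColorMap", ramp = ramp, domain = range(v, na.rm = TRUE),
      transform = transform, missingColor = missingColor)
}

#' Map values to colors
#'
#' Linear interpolation along the ramp over the fitted domain; values are
#' clamped to the domain; a degenerate (constant) domain maps everything to
#' the ramp midpoint; missing values get the missing color.
#'
#' @param cmap a [ColorMap-class].
#' @param v numeric vector of raw (untransformed) values.
#' @return character vector of hex colors.
#' @export
mapColor <- function(cmap, v) {
  out <- rep(cmap@missingColor, length(v))
  ok <- !is.na(v)
  if (!any(ok)) return(out)
  x <- v[ok]
  if (cmap@transform == "log10") x <- log10(x)
  d <- cmap@domain
  t <- if (d[2] > d[1]) pmin(pmax((x - d[1]) / (d[2] - d[1]), 0), 1) else rep(0.5, length(x))
  rgb <- grDevices::colorRamp(cmap@ramp)(t)
  out[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  out
}

#' Build the per-experiment overlay frames
#'
#' One overlay per selected column, in column order. Within a frame, every
#' map element of a resolved row is painted `mapColor(value)`; rows with a
#' missing value in that column paint their elements with the missing color.
#' A reaction receiving values from several rows takes their mean (with a
#' warning). Base tiles are never regenerated.
#'
#' @param ds an [OmicsDataset-class].
#' @param resolution result of [resolveRows()].
#' @param cmap a [ColorMap-class].
#' @param map a [CellMap-class].
#' @return an [OmicsFrameSet-class].
#' @export
buildFrames <- function(ds, resolution, cmap, map) {
  mapping <- resolution$mapping
  frames <- vector("list", ncol(ds@values))
  rowIdx <- match(names(mapping), ds@labels)
  allEls <- unlist(lapply(mapping, function(el) c(el$reactions, el$compounds)))
  conflicts <- unique(allEls[duplicated(allEls)])
  if (length(conflicts))
    warning("element(s) receiving values from multiple rows (mean taken): ",
            paste(conflicts, collapse = ", "))
  for (j in seq_len(ncol(ds@values))) {
    # per-element value accumulation (mean on conflict)
    vals <- list()
    for (k in seq_along(mapping)) {
      v <- ds@values[rowIdx[k], j]
      for (el in c(mapping[[k]]$reactions, mapping[[k]]$compounds))
        vals[[el]] <- c(vals[[el]], v)
    }
    elIds <- names(vals)
    elVal <- vapply(vals, function(x)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE), 0)
    colors <- mapColor(cmap, elVal)

    m <- map@master
    prim <- list()
    found <- list()
    for (i in seq_along(elIds)) {
      id <- elIds[i]
      seg <- m@segments[m@segments$frameId == id, , drop = FALSE]
      if (nrow(seg))
        prim[[length(prim) + 1L]] <- data.frame(
          shape = "line", x0 = seg$x0, y0 = seg$y0, x1 = seg$x1, y1 = seg$y1,
          frameId = id, color = colors[i], stringsAsFactors = FALSE)
      gly <- m@glyphs[m@glyphs$frameId == id & m@glyphs$kind == "compound", , drop = FALSE]
      if (nrow(gly))
        prim[[length(prim) + 1L]] <- data.frame(
          shape = "circle", x0 = gly$x - gly$size, y0 = gly$y - gly$size,
          x1 = gly$x + gly$size, y1 = gly$y + gly$size, frameId = id,
          color = colors[i], stringsAsFactors = FALSE)
      ax <- if (nrow(seg)) (seg$x0[1] + seg$x1[1]) / 2 else if (nrow(gly)) gly$x[1] else NA
      ay <- if (nrow(seg)) (seg$y0[1] + seg$y1[1]) / 2 else if (nrow(gly)) gly$y[1] else NA
      found[[length(found) + 1L]] <- data.frame(
        frameId = id, name = entity(map@pgdb, id)$name, x = ax, y = ay,
        value = unname(elVal[i]), stringsAsFactors = FALSE)
    }
    emptyPrim <- data.frame(shape = character(0), x0 = numeric(0), y0 = numeric(0),
                            x1 = numeric(0), y1 = numeric(0), frameId = character(0),
                            color = character(0), stringsAsFactors = FALSE)
    emptyFound <- data.frame(frameId = character(0), name = character(0),
                             x = numeric(0), y = numeric(0), value = numeric(0),
                             stringsAsFactors = FALSE)
    frames[[j]] <- new("Overlay", name = ds@experiments[j],
                       color = cmap@ramp[length(cmap@ramp)],
                       primitives = if (length(prim)) do.call(rbind, prim) else emptyPrim,
                       found = if (length(found)) do.call(rbind, found) else emptyFound,
                       active = j == 1L)
  }
  new("OmicsFrameSet", frames = frames, colormap = cmap,
      experiments = ds@experiments)
}

#' Composite an overlay onto a rendered level raster
#'
#' Draws the overlay's primitives (projected from master coordinates) over a
#' copy of the base raster. The base itself is never modified in place.
#'
#' @param img base raster array.
#' @param ov an [Overlay-class].
#' @param scale master units per pixel of the raster's level.
#' @return a new raster array.
#' @export
compositeOverlay <- function(img, ov, scale) {
  cv <- asCanvas(img + 0)  # force a private copy; the base stays untouched
  p <- ov@primitives
  for (i in seq_len(nrow(p))) {
    x0 <- roundHalfUp(p$x0[i] / scale) + 1; y0 <- roundHalfUp(p$y0[i] / scale) + 1
    x1 <- roundHalfUp(p$x1[i] / scale) + 1; y1 <- roundHalfUp(p$y1[i] / scale) + 1
    switch(p$shape[i],
      line = cvLine(cv, x0, y0, x1, y1, p$color[i], width = 3),
      circle = cvCircle(cv, (x0 + x1) %/% 2, (y0 + y1) %/% 2,
                        max(1, (x1 - x0) %/% 2) + 1, p$color[i]),
      rect = cvFillRect(cv, x0, y0, x1, y1, p$color[i]))
  }
  cvCommit(cv)
}

#' Render the color-key legend
#'
#' A horizontal ramp bar spanning exactly the fitted domain, annotated with
#' the domain bounds (and the transform, if not identity).
#'
#' @param cmap a [ColorMap-class].
#' @param width,height legend size in pixels.
#' @return a raster array.
#' @export
renderLegend <- function(cmap, width = 240L, height = 44L) {
  cv <- newCanvas(width, height, "#FFFFFF")
  x0 <- 10; x1 <- width - 10; yb0 <- 8; yb1 <- 24
  ts <- (seq(x0, x1) - x0) / (x1 - x0)
  rgb <- grDevices::colorRamp(cmap@ramp)(ts)
  for (k in seq_along(ts))
    cvFillRect(cv, x0 + k - 1, yb0, x0 + k - 1, yb1,
               grDevices::rgb(rgb[k, 1], rgb[k, 2], rgb[k, 3],
                              maxColorValue = 255))
  cvStrokeRect(cv, x0, yb0, x1, yb1, "#202020")
  fmt <- function(v) formatC(v, format = "g", digits = 4)
  lab0 <- fmt(cmap@domain[1]); lab1 <- fmt(cmap@domain[2])
  cvText(cv, x0, yb1 + 6, lab0, "#202020")
  cvText(cv, x1 - textWidth(lab1), yb1 + 6, lab1, "#202020")
  if (cmap@transform != "identity")
    cvText(cv, (x0 + x1) %/% 2 - textWidth(cmap@transform) %/% 2,
           yb1 + 6, cmap@transform, "#202020")
  cvCommit(cv)
}

#' Export an omics frame set
#'
#' Writes, per frame: the overlay document (YAML) and a composited raster
#' (base level image + overlay) as PNG; plus one legend image for the shared
#' color key. Deterministic: re-export is byte-identical.
#'
#' @param fs an [OmicsFrameSet-class].
#' @param zl the [ZoomLayout-class] of the target zoom level.
#' @param outdir output directory.
#' @param style rendering style for the base image.
#' @return character vector of files written, invisibly.
#' @export
exportFrames <- function(fs, zl, outdir, style = defaultStyle()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  base <- renderImage(zl, style)
  files <- character(0)
  for (j in seq_along(fs@frames)) {
    ov <- fs@frames[[j]]
    fo <- file.path(outdir, sprintf("frame-%02d-overlay.yaml", j))
    exportOverlay(ov, fo)
    img <- compositeOverlay(base, ov, zl@scale)
    fp <- file.path(outdir, sprintf("frame-%02d.png", j))
    png::writePNG(img, fp)
    files <- c(files, fo, fp)
  }
  fl <- file.path(outdir, "legend.png")
  png::writePNG(renderLegend(fs@colormap), fl)
  invisible(c(files, fl))
}
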