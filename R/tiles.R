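# Step 4 of the base-image pipeline: slice level rasters into fixed-size
# tiles (400x200 by default) and cache them on the file system, keyed
# root/organism/stamp/zoom/col_row.png. The stamp directory makes
# invalidation atomic: a modified network gets a new stamp directory and the
# old one is removed; an unmodified network is always a pure cache hit.

#' Slice a raster into fixed-size tiles
#'
#' Tile (c, r) holds pixels `[c*tileW, (c+1)*tileW) x [r*tileH, (r+1)*tileH)`
#' (0-based addressing); edge tiles are padded with the background color so
#' every tile is exactly `tileW x tileH`. Tile count is
#' `ceiling(W/tileW) * ceiling(H/tileH)`.
#'
#' @param img raster array `[h, w, 3]`.
#' @param tileW,tileH tile dimensions in pixels (defaults 400 x 200).
#' @param bg background color used for edge padding.
#' @return list of tiles, row-major; each is `list(col, row, pixels)`.
#' @export
sliceTiles <- function(img, tileW = 400L, tileH = 200L, bg = "#FFFEF5") {
  stopifnot(tileW > 0, tileH > 0)
  h <- dim(img)[1]; w <- dim(img)[2]
  ncol <- ceiling(w / tileW); nrow <- ceiling(h / tileH)
  tiles <- vector("list", ncol * nrow)
  k <- 0L
  for (r in seq_len(nrow) - 1L) {
    for (c in seq_len(ncol) - 1L) {
      px <- newRaster(tileW, tileH, bg)
      xs <- (c * tileW + 1):min((c + 1) * tileW, w)
      ys <- (r * tileH + 1):min((r + 1) * tileH, h)
      px[seq_along(ys), seq_along(xs), ] <- img[ys, xs, , drop = FALSE]
      k <- k + 1L
      tiles[[k]] <- list(col = c, row = r, pixels = px)
    }
  }
  tiles
}

#' Reassemble tiles into a raster
#'
#' Inverse of [sliceTiles()]: lays the tiles contiguously and crops to the
#' requested raster bounds. Used by the mosaic-identity checks.
#'
#' @param tiles list of tiles from [sliceTiles()].
#' @param width,height bounds of the original raster.
#' @param tileW,tileH tile dimensions.
#' @return raster array `[height, width, 3]`.
#' @export
assembleTiles <- function(tiles, width, height, tileW = 400L, tileH = 200L) {
  out <- array(0, dim = c(height, width, 3))
  for (t in tiles) {
    xs <- (t$col * tileW + 1):min((t$col + 1) * tileW, width)
    ys <- (t$row * tileH + 1):min((t$row + 1) * tileH, height)
    out[ys, xs, ] <- t$pixels[seq_along(ys), seq_along(xs), , drop = FALSE]
  }
  out
}

#' Create a tile cache
#'
#' @param root cache root directory (created if absent).
#' @param format encoded tile format; "png" is the supported encoder.
#' @return a [TileCache-class] with zeroed render/hit counters.
#' @export
tileCache <- function(root, format = "png") {
  format <- match.arg(format, "png")
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  counters <- new.env(parent = emptyenv())
  counters$renders <- 0L
  counters$hits <- 0L
  new("TileCache", root = root, format = format, counters = counters)
}

#' @rdname tileCache
#' @param cache a [TileCache-class].
#' @export
cacheCounters <- function(cache) as.list(cache@counters)

#' @rdname tileCache
#' @export
resetCounters <- function(cache) {
  cache@counters$renders <- 0L
  cache@counters$hits <- 0L
  invisible(cache)
}

#' Tile address constructor
#'
#' @param organismId organism identifier.
#' @param zoom zoom level index.
#' @param col,row 0-based tile column/row.
#' @return a tile address list.
#' @export
tileAddress <- function(organismId, zoom, col, row) {
  stopifnot(col >= 0, row >= 0)
  list(organismId = organismId, zoom = as.integer(zoom),
       col = as.integer(col), row = as.integer(row))
}

levelDir <- function(cache, organismId, stamp, zoom)
  file.path(cache@root, organismId, stamp, sprintf("z%d", zoom))

#' Generate (or reuse) the tiles of one zoom level
#'
#' Whole-level generation: on a cache miss the supplied `pipeline` closure is
#' invoked once for the level, every tile is sliced and persisted, and a
#' small metadata file records the raster dimensions. On a hit nothing is
#' rendered (the cache `hits` counter is bumped). Writing a new stamp removes
#' any older stamp directories for the organism.
#'
#' @param cache a [TileCache-class].
#' @param organismId organism identifier.
#' @param stamp the organism's current PGDB version stamp.
#' @param zoom zoom level index.
#' @param pipeline closure `function(zoom)` returning the level raster.
#' @param tileW,tileH tile dimensions.
#' @param bg background padding color.
#' @return the level directory path, invisibly.
#' @export
ensureLevel <- function(cache, organismId, stamp, zoom, pipeline,
                        tileW = 400L, tileH = 200L, bg = "#FFFEF5") {
  dir <- levelDir(cache, organismId, stamp, zoom)
  meta <- file.path(dir, "meta.json")
  if (file.exists(meta)) {
    cache@counters$hits <- cache@counters$hits + 1L
    return(invisible(dir))
  }
  orgDir <- file.path(cache@root, organismId)
  old <- setdiff(list.dirs(orgDir, recursive = FALSE, full.names = FALSE), stamp)
  unlink(file.path(orgDir, old), recursive = TRUE)
  img <- pipeline(zoom)
  cache@counters$renders <- cache@counters$renders + 1L
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiles <- sliceTiles(img, tileW, tileH, bg)
  for (t in tiles)
    png::writePNG(t$pixels, file.path(dir, sprintf("%d_%d.png", t$col, t$row)))
  jsonlite::write_json(
    list(width = dim(img)[2], height = dim(img)[1],
         tileW = tileW, tileH = tileH,
         cols = ceiling(dim(img)[2] / tileW), rows = ceiling(dim(img)[1] / tileH)),
    meta, auto_unbox = TRUE)
  writeLines(stamp, file.path(orgDir, "CURRENT"))
  invisible(dir)
}

#' Fetch one tile through the cache
#'
#' Returns the encoded tile bytes for an address, generating the whole level
#' on a first miss. The address is checked against the level's valid ranges;
#' out-of-bounds addresses raise an error stating those ranges. A repeated
#' call for the same address performs zero rendering.
#'
#' @param cache a [TileCache-class].
#' @param addr a [tileAddress()].
#' @param stamp current PGDB version stamp of the organism.
#' @param pipeline closure `function(zoom)` returning the level raster.
#' @param ... passed to [ensureLevel()].
#' @return raw vector of encoded tile bytes.
#' @export
getTile <- function(cache, addr, stamp, pipeline, ...) {
  dir <- ensureLevel(cache, addr$organismId, stamp, addr$zoom, pipeline, ...)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  if (addr$col >= meta$cols || addr$row >= meta$rows || addr$col < 0 || addr$row < 0)
    stop(sprintf("tile address out of bounds: col %d, row %d (valid: col 0..%d, row 0..%d)",
                 addr$col, addr$row, meta$cols - 1, meta$rows - 1), call. = FALSE)
  readBin(file.path(dir, sprintf("%d_%d.png", addr$col, addr$row)),
          "raw", n = file.size(file.path(dir, sprintf("%d_%d.png", addr$col, addr$row))))
}
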