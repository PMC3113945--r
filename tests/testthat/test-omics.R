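# Omics viewer: datafile parsing, row resolution, color mapping, frames.

writeTSV <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("parsing handles headers, missing cells, comments and CRLF", {
  ds <- parseOmicsFile(writeTSV(c("gene\texp1\texp2", "g1\t1.5\t2",
                                  "g2\tNA\t0.5")))
  expect_identical(ds@experiments, c("exp1", "exp2"))
  expect_identical(dim(ds@values), c(2L, 2L))
  expect_true(is.na(ds@values[2, 1]))
  expect_identical(ds@labels, c("g1", "g2"))

  # headerless file gets synthesized experiment names
  ds2 <- parseOmicsFile(writeTSV(c("g1\t1\t2\t3", "g2\t4\t5\t6")))
  expect_identical(ds2@experiments, c("exp1", "exp2", "exp3"))
  expect_identical(dim(ds2@values), c(2L, 3L))

  # comments and CRLF line endings
  ds3 <- parseOmicsFile(writeTSV(c("# a comment", "g1\t1.0\r", "g2\t2.0\r")))
  expect_identical(ds3@values[, 1], c(1, 2))

  # column selection
  ds4 <- parseOmicsFile(writeTSV(c("x\te1\te2\te3", "g1\t1\t2\t3")), columns = c(1, 3))
  expect_identical(ds4@experiments, c("e1", "e3"))
  expect_identical(unname(ds4@values[1, ]), c(1, 3))

  expect_error(parseOmicsFile(writeTSV(c("labelonly", "g1"))), "zero value columns")
  expect_warning(ds5 <- parseOmicsFile(writeTSV(c("g1\t1", "g1\t2"))), "duplicate")
  expect_identical(unname(ds5@values[1, 1]), 2)  # last wins
})

test_that("row resolution maps labels to reaction steps and compound glyphs", {
  map <- tinyMap()
  ds <- parseOmicsFile(writeTSV(c("label\te1",
                                  "G-1\t1",        # gene -> enzyme's reaction
                                  "alphokinase\t2",# protein by name
                                  "R-2\t3",        # reaction by frame ID
                                  "cofactorin\t4", # compound by name
                                  "xyzzy\t5")))    # unresolvable
  res <- resolveRows(ds, map)
  expect_identical(res$unresolved, "xyzzy")
  expect_length(res$mapping, 4)
  expect_identical(res$mapping[["G-1"]]$reactions, "R-1")
  expect_identical(res$mapping[["alphokinase"]]$reactions, "R-1")
  expect_identical(res$mapping[["R-2"]]$reactions, "R-2")
  expect_identical(res$mapping[["cofactorin"]]$compounds, "C-COF")
  # conservation
  expect_identical(length(res$mapping) + length(res$unresolved), length(ds@labels))
})

test_that("row resolution equals a brute-force traversal on the demo fixture", {
  map <- demoMap()
  pgdb <- demoPGDB()
  mk <- makeOmicsFile(pgdb, tempfile(fileext = ".tsv"), nRows = 30, nCols = 2,
                      seed = 5, missRate = 0, badLabelRate = 0)
  ds <- parseOmicsFile(mk$path)
  res <- resolveRows(ds, map)
  expect_length(res$unresolved, 0)
  for (lab in ds@labels) {
    e <- entity(pgdb, lab)
    expected <- switch(e$kind,
      reaction = lab,
      compound = character(0),
      protein = names(Filter(function(r) r$kind == "reaction" &&
                               lab %in% r$enzymes, pgdb@entities)),
      gene = {
        prots <- e$products
        sort(unique(unlist(lapply(prots, function(p)
          names(Filter(function(r) r$kind == "reaction" && p %in% r$enzymes,
                       pgdb@entities))))))
      })
    expect_setequal(res$mapping[[lab]]$reactions, expected)
  }
})

test_that("the color map is linear over the global domain with clamping", {
  ds <- parseOmicsFile(writeTSV(c("a\t0\t10", "b\t5\t2")))
  cm <- fitColorMap(ds)
  expect_identical(cm@domain, c(0, 10))
  # boundary identity: min -> first ramp color, max -> last
  expect_identical(mapColor(cm, 0), "#FFFF00")
  expect_identical(mapColor(cm, 10), "#FF0000")
  # linear interpolation oracle at the midpoint
  mid <- grDevices::colorRamp(c("#FFFF00", "#FF8C00", "#FF0000"))(0.5)
  expect_identical(mapColor(cm, 5),
                   grDevices::rgb(mid[1], mid[2], mid[3], maxColorValue = 255))
  # clamping
  expect_identical(mapColor(cm, -99), mapColor(cm, 0))
  expect_identical(mapColor(cm, 99), mapColor(cm, 10))
  # missing -> missing color
  expect_identical(mapColor(cm, NA), cm@missingColor)
})

test_that("degenerate and invalid datasets are handled per contract", {
  dsC <- parseOmicsFile(writeTSV(c("a\t3\t3", "b\t3\t3")))
  cmC <- fitColorMap(dsC)
  mid <- grDevices::colorRamp(cmC@ramp)(0.5)
  expect_identical(mapColor(cmC, 3),
                   grDevices::rgb(mid[1], mid[2], mid[3], maxColorValue = 255))

  dsM <- parseOmicsFile(writeTSV(c("a\tNA", "b\tNA")))
  expect_error(fitColorMap(dsM), "no non-missing")

  dsL <- parseOmicsFile(writeTSV(c("good\t1", "bad\t-2")))
  expect_error(fitColorMap(dsL, transform = "log10"), "bad")
  dsOK <- parseOmicsFile(writeTSV(c("a\t1", "b\t100")))
  cmL <- fitColorMap(dsOK, transform = "log10")
  expect_identical(cmL@domain, c(0, 2))
  expect_identical(mapColor(cmL, 10), mapColor(fitColorMap(dsOK), 50.5))
})

test_that("color monotonicity: larger values never map to an earlier ramp color", {
  ds <- parseOmicsFile(writeTSV(c("a\t0\t10")))
  cm <- fitColorMap(ds)
  vals <- seq(0, 10, by = 0.5)
  cols <- grDevices::col2rgb(mapColor(cm, vals))
  # along yellow -> orange -> red the green channel strictly decreases
  expect_true(all(diff(cols["green", ]) <= 0))
})

test_that("one overlay per experiment column, in column order, on a shared scale", {
  map <- tinyMap()
  ds <- parseOmicsFile(writeTSV(c("label\tt0\tt1\tt2",
                                  "G-1\t1\t5\t9",
                                  "R-2\t9\t5\tNA",
                                  "cofactorin\t3\tNA\t1")))
  res <- resolveRows(ds, map)
  cm <- fitColorMap(ds)
  fs <- buildFrames(ds, res, cm, map)
  expect_length(fs@frames, 3)
  expect_identical(fs@experiments, c("t0", "t1", "t2"))
  expect_identical(vapply(fs@frames, function(f) f@name, ""), c("t0", "t1", "t2"))

  # same value in different columns -> same color (shared color key)
  c1 <- fs@frames[[1]]@found
  c2 <- fs@frames[[2]]@found
  colOf <- function(fr, id) fr@primitives$color[fr@primitives$frameId == id][1]
  expect_identical(colOf(fs@frames[[2]], "R-1"),   # value 5 in t1
                   colOf(fs@frames[[2]], "R-2"))   # value 5 in t1
  expect_identical(colOf(fs@frames[[1]], "R-2"),   # 9 in t0
                   colOf(fs@frames[[3]], "R-1"))   # 9 in t2

  # missing value in a column -> missing color for that frame only
  expect_identical(colOf(fs@frames[[3]], "R-2"), cm@missingColor)
  expect_false(identical(colOf(fs@frames[[1]], "R-2"), cm@missingColor))

  # single column -> single frame
  fs1 <- buildFrames(parseOmicsFile(writeTSV(c("G-1\t2"))),
                     resolveRows(parseOmicsFile(writeTSV(c("G-1\t2"))), map),
                     cm, map)
  expect_length(fs1@frames, 1)
})

test_that("per-frame colored-element census matches the bookkeeping", {
  map <- demoMap()
  mk <- makeOmicsFile(demoPGDB(), tempfile(fileext = ".tsv"), nRows = 30,
                      nCols = 3, seed = 9, missRate = 0.2, badLabelRate = 0)
  ds <- parseOmicsFile(mk$path)
  res <- resolveRows(ds, map)
  fs <- suppressWarnings(buildFrames(ds, res, fitColorMap(ds), map))
  for (j in 1:3) {
    fr <- fs@frames[[j]]
    # oracle: elements receiving at least one non-missing value in column j
    expectEls <- unique(unlist(lapply(names(res$mapping), function(lab) {
      v <- ds@values[match(lab, ds@labels), j]
      if (is.na(v)) NULL else c(res$mapping[[lab]]$reactions,
                                res$mapping[[lab]]$compounds)
    })))
    colored <- fr@found$frameId[!is.na(fr@found$value)]
    expect_setequal(colored, expectEls)
  }
})

test_that("frame recoloring is independent across frames", {
  map <- tinyMap()
  ds <- parseOmicsFile(writeTSV(c("G-1\t1\t9")))
  res <- resolveRows(ds, map)
  cm <- fitColorMap(ds)
  fs <- buildFrames(ds, res, cm, map)
  f2Before <- fs@frames[[2]]@primitives
  fs@frames[[1]]@primitives$color <- "#000000"
  expect_identical(fs@frames[[2]]@primitives, f2Before)
})

test_that("export composites frames over the base, writes a faithful legend, deterministically", {
  map <- tinyMap()
  zl <- specializeLayout(map@master, 2)
  base <- renderImage(zl)

  # empty frame composites to exactly the base image
  emptyOv <- new("Overlay", name = "none", color = "#FF0000",
                 primitives = data.frame(shape = character(0), x0 = numeric(0),
                                         y0 = numeric(0), x1 = numeric(0),
                                         y1 = numeric(0), frameId = character(0),
                                         color = character(0)),
                 found = data.frame(), active = TRUE)
  expect_identical(compositeOverlay(base, emptyOv, zl@scale), base)

  ds <- parseOmicsFile(writeTSV(c("G-1\t1\t5", "cofactorin\t9\t2")))
  res <- resolveRows(ds, map)
  fs <- buildFrames(ds, res, fitColorMap(ds), map)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  exportFrames(fs, zl, out1)
  exportFrames(fs, zl, out2)
  expect_setequal(list.files(out1),
                  c("frame-01-overlay.yaml", "frame-01.png",
                    "frame-02-overlay.yaml", "frame-02.png", "legend.png"))
  for (f in list.files(out1))   # byte-identical re-export
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6), label = f)
  # a composited frame differs from the base; the base render is unchanged
  img <- png::readPNG(file.path(out1, "frame-01.png"))
  expect_false(identical(img, base))
  expect_identical(renderImage(zl), base)

  # legend bar spans the fitted domain with the ramp's end colors (checked
  # just inside the border) and runs monotonically yellow -> red
  leg <- renderLegend(fs@colormap)
  rampAt <- function(t) {
    v <- grDevices::colorRamp(fs@colormap@ramp)(t)
    as.numeric(grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255) |>
                 grDevices::col2rgb())
  }
  expect_equal(leg[16, 11, ] * 255, rampAt(1 / 220))     # first interior column
  expect_equal(leg[16, 229, ] * 255, rampAt(219 / 220))  # last interior column
  expect_true(all(diff(leg[16, 11:229, 2]) <= 0))        # monotone yellow->red
})
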