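# Master layout: region assignment, packing conventions, duplication,
# determinism and the structural invariants.

test_that("region assignment places each category in its column, central in between", {
  pgdb <- demoPGDB()
  reg <- assignRegions(pgdb)
  pws <- reg[reg$kind == "pathway", ]
  expect_setequal(pws$column[!is.na(pws$column)], c("left", "middle", "right"))
  m <- layoutMaster(pgdb)
  bx <- m@clusterBoxes
  left <- bx[bx$category == "anabolic_intermediary", ]
  mid <- bx[bx$category == "central", ]
  right <- bx[bx$category == "catabolic", ]
  expect_true(max(left$x1) < min(mid$x0))
  expect_true(max(mid$x1) < min(right$x0))
})

test_that("compartment takes precedence over pathway category", {
  for (cat in c("central", "catabolic", "anabolic_intermediary", "other", "signal")) {
    for (comp in c("periplasm", "inner_membrane", "outer_membrane")) {
      ents <- list(
        newCompound("C-1", "aose"), newCompound("C-2", "bose"),
        newReaction("R-1", "r one", c("C-1" = 1), c("C-2" = 1),
                    compartment = comp, pathways = "PWY"),
        newPathway("PWY", "some pathway", "R-1", category = cat))
      reg <- assignRegions(newPGDB("X", ents))
      expect_identical(reg$region[reg$frameId == "R-1"], comp,
                       label = paste(cat, comp))
    }
  }
})

test_that("a PGDB with only unassigned reactions yields a grid and no cluster boxes", {
  pgdb <- gridOnlyPGDB()
  reg <- assignRegions(pgdb)
  expect_true(all(reg$region[reg$kind == "reaction"] == "unassigned_grid"))
  m <- layoutMaster(pgdb)
  expect_identical(nrow(m@clusterBoxes), 0L)
  expect_setequal(unique(m@segments$region), "unassigned_grid")
})

test_that("the unassigned grid uses ceiling arithmetic, row-major", {
  expect_identical(gridDims(10, 4), c(3L, 4L))
  expect_identical(gridDims(0, 4), c(0L, 0L))
  expect_identical(gridDims(3, 4), c(1L, 3L))
  ents <- list()
  for (i in 1:11) ents <- c(ents, list(newCompound(sprintf("C-%02d", i), "xose")))
  for (i in 1:10)
    ents <- c(ents, list(newReaction(sprintf("R-%02d", i), "rxn",
                                     stats::setNames(1, sprintf("C-%02d", i)),
                                     stats::setNames(1, sprintf("C-%02d", i + 1)))))
  m <- layoutMaster(newPGDB("G", ents))
  # row-major: first four reactions share the first row band
  seg <- m@segments[order(m@segments$frameId), ]
  ys <- seg$y0
  expect_length(unique(ys), 3)          # 3 rows
  expect_identical(ys[1], ys[4])        # R-01..R-04 in row 1
  expect_true(ys[5] > ys[4])            # R-05 starts row 2
  xs <- seg$x0[1:4]
  expect_true(all(diff(xs) > 0))        # left-to-right within the row
})

test_that("pathway drawings are contained in their cluster box and region", {
  m <- demoMap()@master
  bx <- m@clusterBoxes
  seg <- m@segments[!is.na(m@segments$pathway), ]
  pwCluster <- list()
  for (i in seq_len(nrow(seg))) {
    hit <- bx$x0 <= seg$x0[i] & bx$x1 >= seg$x1[i] &
           bx$y0 <= seg$y0[i] & bx$y1 >= seg$y1[i]
    expect_true(any(hit), label = paste("segment of", seg$frameId[i], "in a box"))
  }
  gly <- m@glyphs[!is.na(m@glyphs$pathway) & m@glyphs$region == "cytoplasm", ]
  for (i in seq_len(nrow(gly))) {
    hit <- bx$x0 <= gly$x[i] & bx$x1 >= gly$x[i] &
           bx$y0 <= gly$y[i] & bx$y1 >= gly$y[i]
    expect_true(any(hit))
  }
})

test_that("an empty PGDB lays out regions only, with zero glyphs", {
  m <- layoutMaster(newPGDB("EMPTY", list()))
  expect_identical(nrow(m@glyphs), 0L)
  expect_identical(nrow(m@segments), 0L)
  expect_true(all(c("extracellular", "outer_membrane", "periplasm",
                    "inner_membrane", "cytoplasm") %in% m@regions$name))
  expect_true(m@canvasWidth > 0 && m@canvasHeight > 0)
})

test_that("metabolite duplication: shared compounds get one glyph per local use", {
  m <- tinyMap()@master
  # C-COF is a side substrate of R-1 (PWY-1) and R-3 (PWY-2) and product of
  # R-GRID: three distinct local occurrences, zero connecting edges
  cof <- m@glyphs[m@glyphs$frameId == "C-COF", ]
  expect_identical(nrow(cof), 3L)
  expect_length(unique(cof$x), 3L)
  # chain intermediate C-B is shared by R-1 and R-2 within PWY-1: one glyph
  expect_identical(nrow(m@glyphs[m@glyphs$frameId == "C-B", ]), 1L)
  # compound used once -> one glyph
  expect_identical(nrow(m@glyphs[m@glyphs$frameId == "C-D", ]), 1L)
})

test_that("glyph occurrence census matches a brute-force count on the fixture", {
  pgdb <- demoPGDB()
  m <- demoMap()@master
  # oracle: one glyph per (drawn reaction, side, compound) occurrence, minus
  # chain-shared intermediates (consecutive steps of one pathway chain), plus
  # membrane-reaction endpoints (first substrate/product only)
  seg <- m@segments
  drawn <- unique(seg$frameId)
  for (cid in c("COF-1", "COF-2", "CPD-001", "CPD-010")) {
    occ <- 0L
    for (rid in drawn) {
      r <- entity(pgdb, rid)
      if (r$compartment %in% c("inner_membrane", "outer_membrane")) {
        occ <- occ + (names(r$substrates)[1] == cid) + (names(r$products)[1] == cid)
      } else {
        occ <- occ + (cid %in% names(r$substrates)) + (cid %in% names(r$products))
      }
    }
    # subtract within-pathway chain sharing: consecutive reactions of a
    # pathway whose link compound is cid count once, not twice
    for (pw in entitiesOfKind(pgdb, "pathway")) {
      rxns <- pw$reactions[pw$reactions %in% seg$frameId[!is.na(seg$pathway) &
                                                          seg$pathway == pw$frameId]]
      if (length(rxns) < 2) next
      for (i in seq_len(length(rxns) - 1)) {
        prods <- names(entity(pgdb, rxns[i])$products)
        subs <- names(entity(pgdb, rxns[i + 1])$substrates)
        link <- intersect(prods, subs)
        if (length(link) && link[1] == cid) occ <- occ - 1L
      }
    }
    expect_identical(nrow(m@glyphs[m@glyphs$frameId == cid, ]), occ,
                     label = paste("glyph census for", cid))
  }
})

test_that("the master layout is deterministic (byte-identical serialization)", {
  j1 <- masterLayoutJSON(layoutMaster(demoPGDB()))
  j2 <- masterLayoutJSON(layoutMaster(makeOrganism(fixtureSpec(seed = 42L))))
  expect_identical(j1, j2)
  f <- withr::local_tempfile(fileext = ".json")
  writeMasterLayout(demoMap()@master, f)
  back <- readMasterLayout(f)
  expect_identical(masterLayoutJSON(back), masterLayoutJSON(demoMap()@master))
})

test_that("no two glyph bounding boxes overlap", {
  expect_identical(glyphOverlaps(demoMap()@master@glyphs), 0L)
  expect_identical(glyphOverlaps(tinyMap()@master@glyphs), 0L)
})

test_that("only transporters and membrane proteins sit on a membrane band", {
  m <- demoMap()@master
  pgdb <- demoPGDB()
  bands <- m@regions[m@regions$name %in% c("inner_membrane", "outer_membrane"), ]
  g <- m@glyphs
  for (i in seq_len(nrow(g))) {
    crosses <- any(g$x[i] >= bands$x0 & g$x[i] <= bands$x1 &
                   g$y[i] - g$size[i] < bands$y1 & g$y[i] + g$size[i] > bands$y0)
    if (crosses)
      expect_true(isTRUE(entity(pgdb, g$frameId[i])$isTransporter),
                  label = paste(g$frameId[i], "on a membrane band"))
  }
  # and every transporter glyph does intersect its band
  tr <- g[g$gclass == "glyph_transporter" &
          g$region %in% c("inner_membrane", "outer_membrane"), ]
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    b <- bands[bands$name == tr$region[i], ]
    expect_true(tr$y[i] - tr$size[i] < b$y1 && tr$y[i] + tr$size[i] > b$y0)
  }
})

test_that("pathways flow downward: substrates above products for >= 90% of steps", {
  pgdb <- demoPGDB()
  m <- demoMap()@master
  ok <- 0L; tot <- 0L
  for (pw in entitiesOfKind(pgdb, "pathway")) {
    for (rid in pw$reactions) {
      seg <- m@segments[m@segments$frameId == rid & !is.na(m@segments$pathway), ]
      if (!nrow(seg)) next
      r <- entity(pgdb, rid)
      subs <- m@glyphs[m@glyphs$frameId %in% names(r$substrates) &
                       m@glyphs$pathway %in% pw$frameId, ]
      prods <- m@glyphs[m@glyphs$frameId %in% names(r$products) &
                        m@glyphs$pathway %in% pw$frameId, ]
      subs <- subs[abs(subs$y - seg$y0[1]) <= 20, ]
      prods <- prods[abs(prods$y - seg$y1[1]) <= 20, ]
      if (!nrow(subs) || !nrow(prods)) next
      tot <- tot + 1L
      if (mean(subs$y) <= mean(prods$y)) ok <- ok + 1L
    }
  }
  expect_gt(tot, 10)
  expect_gte(ok / tot, 0.9)
})

test_that("every reaction is drawn exactly once", {
  pgdb <- demoPGDB()
  m <- demoMap()@master
  seg <- m@segments
  expect_setequal(unique(seg$frameId), names(entitiesOfKind(pgdb, "reaction")))
  # a reaction's segments all live in one region (one drawing site)
  for (rid in unique(seg$frameId))
    expect_length(unique(seg$region[seg$frameId == rid]), 1)
  # and in at most one pathway drawing
  for (rid in unique(seg$frameId))
    expect_lte(length(unique(stats::na.omit(seg$pathway[seg$frameId == rid]))), 1)
})

test_that("regions tile the canvas; grid and signal strip sit inside the cytoplasm", {
  m <- demoMap()@master
  r <- m@regions
  bands <- r[r$name %in% c("extracellular", "outer_membrane", "periplasm",
                           "inner_membrane", "cytoplasm"), ]
  bands <- bands[order(bands$y0), ]
  expect_identical(bands$y0[1], 0)
  expect_identical(bands$y1[nrow(bands)], m@canvasHeight)
  expect_true(all(bands$y1[-nrow(bands)] == bands$y0[-1]))  # no gaps/overlap
  cyto <- r[r$name == "cytoplasm", ]
  for (nm in c("unassigned_grid", "signal_strip")) {
    sub <- r[r$name == nm, ]
    expect_identical(nrow(sub), 1L)
    expect_true(sub$y0 >= cyto$y0 && sub$y1 <= cyto$y1 &&
                sub$x0 >= cyto$x0 && sub$x1 <= cyto$x1)
  }
})

test_that("a layout larger than the configured canvas errors with both sizes", {
  expect_error(layoutMaster(demoPGDB(), layoutParams(canvasMax = 300)),
               "canvas overflow.*300")
})
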