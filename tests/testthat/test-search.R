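# Highlight commands: oracle equivalence against linear scans, expansion
# semantics, overlay structure.

test_that("pathway search equals the linear-scan oracle and highlights pathway reactions", {
  map <- demoMap()
  pgdb <- demoPGDB()
  for (q in c("biosyn", "degradation", "pwy-cat", "backbone", "zzz-nothing")) {
    ov <- searchPathways(map, q, "substring")
    expect_identical(sort(ov@found$frameId), oracleSubstring(pgdb, "pathway", q),
                     label = paste("substring", q))
    # highlighted primitives = union of the matched pathways' reaction lines
    rxns <- unique(c(character(0), unlist(lapply(ov@found$frameId,
                                 function(id) entity(pgdb, id)$reactions))))
    expect_setequal(unique(ov@primitives$frameId),
                    intersect(rxns, map@master@segments$frameId))
  }
  ex <- searchPathways(map, "PWY-CAT-1", "exact")
  expect_identical(ex@found$frameId, "PWY-CAT-1")
})

test_that("reaction search modes equal their oracles", {
  map <- demoMap()
  pgdb <- demoPGDB()
  for (q in c("kinase", "reaction", "rxn-0")) {
    expect_identical(sort(searchReactions(map, q, "substring")@found$frameId),
                     oracleSubstring(pgdb, "reaction", q))
  }
  for (q in c("2.7.1", "2.7", "5.4.2.2", "1.1.1")) {
    expect_identical(sort(searchReactions(map, q, "ec")@found$frameId),
                     oracleEC(pgdb, q), label = paste("ec", q))
  }
  expect_error(searchReactions(map, "2.7.x", "ec"), "malformed EC")
  expect_error(searchReactions(map, "", "substring"), "empty query")
  # exact frame ID -> single hit
  expect_identical(searchReactions(map, "RXN-001", "exact")@found$frameId, "RXN-001")
})

test_that("reaction search by enzyme name equals the enzyme search restricted to reactions", {
  map <- demoMap()
  byEnz <- searchReactions(map, "kinase", "enzyme_name")
  enzOv <- searchEnzymes(map, "kinase", "substring")
  rxnsOfEnz <- unique(enzOv@primitives$frameId[
    vapply(enzOv@primitives$frameId,
           function(id) entity(demoPGDB(), id)$kind == "reaction", TRUE)])
  expect_setequal(byEnz@found$frameId, rxnsOfEnz)
})

test_that("gene search finds reactions, RNAs, transporters and enzymes", {
  map <- demoMap()
  pgdb <- demoPGDB()
  ov <- searchGenes(map, "arg", "substring")
  kinds <- vapply(ov@found$frameId, function(id) {
    e <- entity(pgdb, id)
    if (e$kind == "protein") {
      if (isTRUE(e$isTransporter)) "transporter" else "enzyme"
    } else e$kind
  }, "")
  expect_true(all(c("reaction", "rna", "transporter", "enzyme") %in% kinds))
  # expansion equals the brute-force gene -> products -> reactions traversal
  genes <- oracleSubstring(pgdb, "gene", "arg")
  expect_identical(sort(ov@found$frameId), oracleGeneExpansion(pgdb, genes))
})

test_that("gene file search reports unresolved identifiers without failing", {
  map <- demoMap()
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("G-001", "NO-SUCH-GENE"), f)
  ov <- searchGenes(map, f, "file")
  expect_identical(attr(ov@found, "unresolved"), "NO-SUCH-GENE")
  expect_identical(attr(ov@found, "genes"), "G-001")
  expect_identical(sort(ov@found$frameId), oracleGeneExpansion(demoPGDB(), "G-001"))
})

test_that("compound search highlights every duplicate glyph occurrence", {
  map <- tinyMap()
  ov <- searchCompounds(map, "cofactorin", "substring")
  expect_identical(nrow(ov@found), 1L)
  expect_identical(nrow(ov@primitives), 3L)   # three placed duplicates
  expect_true(all(ov@primitives$shape %in% c("circle", "rect")))
})

test_that("enzyme overlays include both protein glyphs and reaction polylines", {
  map <- tinyMap()
  ov <- searchEnzymes(map, "alphokinase", "substring")
  expect_identical(ov@found$frameId, "E-1")
  expect_true("line" %in% ov@primitives$shape)   # R-1's line
  expect_true(any(ov@primitives$shape == "rect" & ov@primitives$frameId == "E-1"))
  expect_true("R-1" %in% ov@primitives$frameId)
})

test_that("exact mode ignores synonyms; substring results contain exact results", {
  pgdb <- demoPGDB()
  map <- demoMap()
  syn <- NULL
  for (e in pgdb@entities)
    if (e$kind == "compound" && length(e$synonyms) &&
        !tolower(e$synonyms[1]) %in% tolower(vapply(
          entitiesOfKind(pgdb, "compound"), function(x) x$name, ""))) {
      syn <- e$synonyms[1]; break
    }
  expect_false(is.null(syn))
  expect_identical(nrow(searchCompounds(map, syn, "exact")@found), 0L)
  expect_gt(nrow(searchCompounds(map, syn, "substring")@found), 0L)
  for (q in c("demose", "RXN-001", "ose")) {
    for (fam in list(searchCompounds, searchReactions)) {
      ex <- fam(map, q, "exact")@found$frameId
      sub <- fam(map, q, "substring")@found$frameId
      expect_true(all(ex %in% sub), label = paste("monotonicity", q))
    }
  }
})

test_that("oracle equivalence holds on a large fixture across all families", {
  pgdb <- memo("bigPGDB", makeOrganism(fixtureSpec(
    seed = 99L, counts = list(catabolic = 12L, anabolic = 12L,
                              reactionsPerPathway = 6L, unassigned = 60L,
                              transporters = 10L, periplasmic = 6L))))
  map <- memo("bigMap", cellMap(pgdb))
  queries <- c("ase", "kin", "ol", "arg", "cpd-0", "tar")
  for (q in queries) {
    expect_identical(sort(searchCompounds(map, q, "substring")@found$frameId),
                     oracleSubstring(pgdb, "compound", q))
    expect_identical(sort(searchReactions(map, q, "substring")@found$frameId),
                     oracleSubstring(pgdb, "reaction", q))
    expect_identical(sort(searchPathways(map, q, "substring")@found$frameId),
                     oracleSubstring(pgdb, "pathway", q))
    genes <- oracleSubstring(pgdb, "gene", q)
    expect_identical(sort(searchGenes(map, q, "substring")@found$frameId),
                     oracleGeneExpansion(pgdb, genes), label = paste("genes", q))
  }
})

test_that("overlays are independent of the base tiles and of each other", {
  map <- tinyMap()
  zl <- specializeLayout(map@master, 2)
  before <- renderImage(zl)
  ov1 <- searchPathways(map, "degradation")
  ov2 <- searchCompounds(map, "cofactorin")
  expect_identical(renderImage(zl), before)   # base untouched
  p1 <- ov1@primitives
  ov2@active <- FALSE
  expect_identical(ov1@primitives, p1)        # deactivation is per-overlay
  expect_identical(ov1@name, "degradation")   # overlay named by the keyword
})

test_that("listOverlay orders by name then frame ID and anchors hit their object", {
  map <- demoMap()
  ov <- searchCompounds(map, "ose", "substring")
  lst <- listOverlay(ov)
  expect_identical(nrow(lst), nrow(ov@found))
  expect_false(is.unsorted(lst$name))
  nd <- buildNodeData(specializeLayout(map@master, 5))
  for (i in seq_len(min(nrow(lst), 20))) {
    expect_true(lst$frameId[i] %in% hitTest(nd, lst$x[i], lst$y[i]))
  }
  empty <- searchCompounds(map, "nothing-matches-this")
  expect_identical(nrow(listOverlay(empty)), 0L)
})

test_that("autocomplete returns prefix matches in name order, capped", {
  idx <- demoMap()@index
  ac <- autocomplete(idx, "de")
  expect_lte(nrow(ac), 20)
  expect_true(all(startsWith(ac$key, "de")))
  expect_false(is.unsorted(ac$key))
})

test_that("overlay export and SVG projection write well-formed documents", {
  map <- tinyMap()
  ov <- searchPathways(map, "degradation")
  f <- withr::local_tempfile(fileext = ".yaml")
  exportOverlay(ov, f)
  doc <- yaml::read_yaml(f)
  expect_identical(doc$name, "degradation")
  expect_length(doc$primitives, nrow(ov@primitives))
  svg <- withr::local_tempfile(fileext = ".svg")
  overlaySVG(ov, svg, level = 3)
  x <- xml2::read_xml(svg)
  expect_identical(xml2::xml_name(x), "svg")
  expect_length(xml2::xml_children(x), nrow(ov@primitives))
})
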