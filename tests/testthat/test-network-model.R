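# Native dialect I/O, stamping, SBML import/export, validation.

test_that("an empty network file loads to an empty PGDB with a valid stamp", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cellmapr_network: 1", "organism: EMPTY-ORG"), f)
  pgdb <- loadNetwork(f)
  expect_length(entityIds(pgdb), 0)
  expect_match(versionStamp(pgdb), "^[0-9a-f]{40}$")
})

test_that("write/load round-trips the fixture organism, stamp included", {
  pgdb <- demoPGDB()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeNetwork(pgdb, f)
  back <- loadNetwork(f)
  expect_identical(versionStamp(back), versionStamp(pgdb))
  expect_setequal(entityIds(back), entityIds(pgdb))
  expect_identical(back@entities[sort(entityIds(back))],
                   pgdb@entities[sort(entityIds(pgdb))])
})

test_that("the version stamp is invariant under entity reordering in the file", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeNetwork(tinyPGDB(), f)
  doc <- yaml::read_yaml(f)
  doc$compounds <- rev(doc$compounds)
  doc$reactions <- rev(doc$reactions)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, f2)
  expect_identical(versionStamp(loadNetwork(f2)), versionStamp(tinyPGDB()))
})

test_that("a stamp changes iff content changes", {
  p1 <- tinyPGDB()
  ents <- p1@entities
  ents[["C-A"]]$name <- "renamed alphose"
  p2 <- newPGDB(p1@organismId, unname(ents))
  expect_false(identical(versionStamp(p2), versionStamp(p1)))
  p3 <- newPGDB(p1@organismId, unname(p1@entities))
  expect_identical(versionStamp(p3), versionStamp(p1))
})

test_that("dangling references are rejected with the offending frame ID", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cellmapr_network: 1", "organism: BAD-ORG", "reactions:",
               "  - id: R-1", "    name: broken reaction",
               "    substrates: {CPD-X: 1}", "    products: {}"), f)
  expect_error(loadNetwork(f), "CPD-X")
})

test_that("schema violations name the field and record", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cellmapr_network: 1", "organism: BAD-ORG", "compounds:",
               "  - name: nameless"), f)
  expect_error(loadNetwork(f), "compounds record 1.*'id'")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("organism: X", f2)
  expect_error(loadNetwork(f2), "cellmapr_network")
})

test_that("SBML with 2 species and 1 ungrouped reaction imports as unassigned", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="MINI"><listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="S1" name="esone" compartment="c"/>',
    '<species id="S2" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="R1" compartment="c">',
    '<listOfReactants><speciesReference species="S1" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="S2"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), f)
  expect_error(loadSBML(f), "unmappable SBML compartment 'c'")
  pgdb <- loadSBML(f, compartmentMap = c(c = "cytosol"))
  expect_length(entitiesOfKind(pgdb, "compound"), 2)
  r <- entity(pgdb, "R1")
  expect_identical(r$pathways, character(0))
  expect_identical(r$substrates, c(S1 = 1))
  # default stoichiometry is 1; default compartment mapping also accepted
  expect_identical(r$products, c(S2 = 1))
  pgdb2 <- loadSBML(f, defaultCompartment = "cytosol")
  expect_identical(entity(pgdb2, "R1")$compartment, "cytosol")

  side <- withr::local_tempfile(fileext = ".tsv")
  writeLines("R1\tP", side)
  pgdb3 <- loadSBML(f, grouping = side, compartmentMap = c(c = "cytosol"))
  expect_identical(entity(pgdb3, "R1")$pathways, "P")
  expect_identical(entity(pgdb3, "P")$reactions, "R1")
})

test_that("SBML export then re-import preserves compound/reaction structure", {
  pgdb <- demoPGDB()
  f <- withr::local_tempfile(fileext = ".xml")
  exportSBML(pgdb, f)
  back <- loadSBML(f)
  expect_length(entitiesOfKind(back, "compound"),
                length(entitiesOfKind(pgdb, "compound")))
  expect_length(entitiesOfKind(back, "reaction"),
                length(entitiesOfKind(pgdb, "reaction")))
  expect_length(entitiesOfKind(back, "pathway"),
                length(entitiesOfKind(pgdb, "pathway")))
  for (rid in names(entitiesOfKind(pgdb, "reaction"))) {
    expect_identical(sort(names(entity(back, rid)$substrates)),
                     sort(names(entity(pgdb, rid)$substrates)))
    expect_identical(entity(back, rid)$compartment, entity(pgdb, rid)$compartment)
  }
})

test_that("validatePGDB is empty on a consistent fixture and finds injected faults", {
  expect_identical(nrow(validatePGDB(demoPGDB())), 0L)

  base <- tinyPGDB()
  mutate <- function(f) {
    ents <- base@entities
    ents <- f(ents)
    new("PGDB", organismId = "MUT", entities = ents, versionStamp = "x")
  }
  # pathway with zero reactions -> exactly one violation
  m1 <- mutate(function(e) { e[["PWY-2"]]$reactions <- character(0); e })
  rep1 <- validatePGDB(m1)
  expect_identical(rep1$rule, "empty_pathway")
  expect_identical(rep1$frameId, "PWY-2")

  # dangling reference
  m2 <- mutate(function(e) { e[["R-1"]]$enzymes <- "E-GONE"; e })
  rep2 <- validatePGDB(m2)
  expect_identical(rep2$rule, "dangling_reference")

  # non-positive stoichiometry
  m3 <- mutate(function(e) { e[["R-1"]]$substrates[["C-A"]] <- -1; e })
  expect_true("nonpositive_coefficient" %in% validatePGDB(m3)$rule)

  # transporter whose only reaction is cytosolic -> warning entry
  m4 <- mutate(function(e) { e[["R-TR"]]$compartment <- "cytosol"; e })
  rep4 <- validatePGDB(m4)
  expect_identical(rep4$rule, "transporter_in_cytosol")
  expect_identical(rep4$severity, "warning")
  expect_true(isCleanReport(rep4, allowWarnings = TRUE))
})

test_that("constructors enforce basic contracts", {
  expect_error(newReaction("R", "r", c(A = -1), c(B = 1)), "positive")
  expect_error(newCompound("C", ""), "name")
  expect_error(newPGDB("O", list(newCompound("C", "x"), newCompound("C", "y"))),
               "duplicate")
  expect_error(entity(tinyPGDB(), "NOPE"), "no entity")
})
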