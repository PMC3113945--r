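# Shared fixtures, memoized so the demo organism and its pipeline are built
# once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

demoPGDB <- function() memo("pgdb", makeOrganism(fixtureSpec(seed = 42L)))
demoMap <- function() memo("map", cellMap(demoPGDB()))
demoZls <- function() memo("zls", specializeAll(demoMap()@master))
demoImages <- function() memo("imgs", lapply(demoZls(), renderImage))

# a tiny hand-built network: 2-step chain pathway in each of two categories
# sharing one cofactor, a transporter, a periplasmic and a grid reaction
tinyPGDB <- function() memo("tiny", {
  ents <- list(
    newCompound("C-A", "alphose"), newCompound("C-B", "betose"),
    newCompound("C-C", "gammose"), newCompound("C-D", "deltose"),
    newCompound("C-E", "epsilose"), newCompound("C-COF", "cofactorin"),
    newCompound("C-X", "externose"), newCompound("C-P", "periplose"),
    newReaction("R-1", "alphose kinase reaction", c("C-A" = 1, "C-COF" = 1),
                c("C-B" = 1), ec = "2.7.1.1", enzymes = "E-1",
                pathways = "PWY-1"),
    newReaction("R-2", "betose mutase reaction", c("C-B" = 1), c("C-C" = 1),
                ec = "5.4.2.2", enzymes = "E-2", pathways = "PWY-1"),
    newReaction("R-3", "deltose synthase reaction", c("C-D" = 1, "C-COF" = 1),
                c("C-E" = 1), enzymes = "E-3", pathways = "PWY-2"),
    newReaction("R-GRID", "orphan reaction", c("C-E" = 1), c("C-COF" = 1)),
    newReaction("R-PERI", "periplose hydrolase reaction", c("C-P" = 1),
                c("C-A" = 1), compartment = "periplasm"),
    newReaction("R-TR", "transport of externose", c("C-X" = 1), c("C-A" = 1),
                enzymes = "T-1", compartment = "inner_membrane"),
    newProtein("E-1", "alphokinase", isEnzyme = TRUE, genes = "G-1"),
    newProtein("E-2", "betomutase", isEnzyme = TRUE, genes = "G-2"),
    newProtein("E-3", "deltosynthase", isEnzyme = TRUE, genes = "G-3"),
    newProtein("T-1", "externose permease", isTransporter = TRUE, genes = "G-4"),
    newRNA("RNA-1", "tRNA-arg", genes = "G-5"),
    newGene("G-1", "alkA", products = "E-1"),
    newGene("G-2", "betB", products = "E-2"),
    newGene("G-3", "delC", products = "E-3"),
    newGene("G-4", "argT", products = "T-1"),
    newGene("G-5", "argR", products = "RNA-1"),
    newPathway("PWY-1", "alphose degradation I", c("R-1", "R-2"),
               category = "catabolic", cluster = "sugar degradation"),
    newPathway("PWY-2", "epsilose biosynthesis", "R-3",
               category = "anabolic_intermediary",
               cluster = "amino-acid biosynthesis"))
  newPGDB("TINY-ORG", ents)
})

tinyMap <- function() memo("tinyMap", cellMap(tinyPGDB()))

# 5 pathway-less reactions only: the segment-census fixture
gridOnlyPGDB <- function() memo("grid5", {
  ents <- list()
  for (i in 1:6) ents <- c(ents, list(newCompound(sprintf("GC-%d", i),
                                                  sprintf("gridose-%d", i))))
  for (i in 1:5)
    ents <- c(ents, list(newReaction(sprintf("GR-%d", i),
                                     sprintf("grid reaction %d", i),
                                     stats::setNames(1, sprintf("GC-%d", i)),
                                     stats::setNames(1, sprintf("GC-%d", i + 1)))))
  newPGDB("GRID-ORG", ents)
})

# linear-scan search oracles, independent of the index implementation
oracleStrings <- function(e) c(e$name, e$synonyms, e$frameId)

oracleSubstring <- function(pgdb, kind, q) {
  hits <- Filter(function(e) e$kind == kind &&
                   any(grepl(tolower(q), tolower(oracleStrings(e)), fixed = TRUE)),
                 pgdb@entities)
  sort(unname(vapply(hits, function(e) e$frameId, "")))
}

oracleExact <- function(pgdb, kind, q) {
  hits <- Filter(function(e) e$kind == kind &&
                   (identical(e$frameId, q) || tolower(e$name) == tolower(q)),
                 pgdb@entities)
  sort(unname(vapply(hits, function(e) e$frameId, "")))
}

oracleEC <- function(pgdb, q) {
  hits <- Filter(function(e) e$kind == "reaction" &&
                   any(e$ec == q | startsWith(e$ec, paste0(q, "."))),
                 pgdb@entities)
  sort(unname(vapply(hits, function(e) e$frameId, "")))
}

oracleGeneExpansion <- function(pgdb, geneIds) {
  out <- character(0)
  for (gid in geneIds) {
    g <- pgdb@entities[[gid]]
    for (pid in g$products) {
      p <- pgdb@entities[[pid]]
      if (p$kind == "rna") out <- c(out, pid)
      if (p$kind == "protein") {
        rxns <- names(Filter(function(e) e$kind == "reaction" &&
                               pid %in% e$enzymes, pgdb@entities))
        if (isTRUE(p$isTransporter)) out <- c(out, pid)
        if (isTRUE(p$isEnzyme) || length(rxns)) out <- c(out, pid)
        out <- c(out, rxns)
      }
    }
  }
  sort(unique(out))
}

labelOverlaps <- function(zl) {
  lb <- zl@labels
  n <- 0L
  if (nrow(lb) > 1)
    for (i in seq_len(nrow(lb) - 1)) for (j in (i + 1):nrow(lb))
      if (lb$bx0[i] < lb$bx1[j] && lb$bx1[i] > lb$bx0[j] &&
          lb$by0[i] < lb$by1[j] && lb$by1[i] > lb$by0[j]) n <- n + 1L
  n
}

glyphOverlaps <- function(g) {
  n <- 0L
  if (nrow(g) > 1) {
    x0 <- g$x - g$size; x1 <- g$x + g$size
    y0 <- g$y - g$size; y1 <- g$y + g$size
    for (i in seq_len(nrow(g) - 1)) {
      j <- (i + 1):nrow(g)
      n <- n + sum(x0[i] < x1[j] & x1[i] > x0[j] & y0[i] < y1[j] & y1[i] > y0[j])
    }
  }
  n
}

drawnIds <- function(zl) c(zl@glyphs$glyphId, zl@segments$segId, zl@labels$labelId)
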