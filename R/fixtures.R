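# Deterministic synthetic-organism generator. Names are synthetic (no
# biological realism claims); the default demo organism exercises every map
# feature class: central / catabolic / anabolic / signal pathways, shared
# cofactors (metabolite duplication), an unassigned-reaction grid population,
# membrane transporters with an "arg"-named gene family (so a gene substring
# search finds reactions, RNAs, transporters and enzymes), periplasmic
# reactions, EC-numbered kinases, and tRNAs.

#' Create a fixture specification
#'
#' @param seed integer seed of the explicit counter-based random source.
#' @param counts named list overriding any of: pathways per category
#'   (`central`, `catabolic`, `anabolic`, `signal`), `reactionsPerPathway`,
#'   `unassigned`, `transporters`, `periplasmic`, `genesPerEnzyme`.
#' @param synonymDensity expected synonyms per named entity.
#' @param nameCollisionRate fraction of compounds reusing an existing name
#'   as a synonym (exercises ambiguous search hits).
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(seed = 42L, counts = list(), synonymDensity = 0.6,
                        nameCollisionRate = 0.05) {
  base <- list(central = 2L, catabolic = 3L, anabolic = 4L, signal = 2L,
               reactionsPerPathway = 4L, unassigned = 10L, transporters = 4L,
               periplasmic = 3L, genesPerEnzyme = 1L)
  base[names(counts)] <- counts
  stopifnot(all(unlist(base) >= 0), synonymDensity >= 0,
            nameCollisionRate >= 0, nameCollisionRate <= 1)
  new("FixtureSpec", seed = as.integer(seed), counts = base,
      synonymDensity = synonymDensity, nameCollisionRate = nameCollisionRate)
}

SYL1 <- c("dem", "vol", "tar", "mex", "sul", "pir", "gal", "ner", "kol", "fas")
SYL2 <- c("a", "o", "i", "u", "e")
SYL3 <- c("ate", "ol", "ine", "ose", "ide", "ane")

synthName <- function(rng, suffixes = SYL3) {
  paste0(lcgPick(rng, SYL1), lcgPick(rng, SYL2), lcgPick(rng, SYL1),
         lcgPick(rng, suffixes))
}

maybeSynonyms <- function(rng, spec, pool = character(0)) {
  n <- sum(lcgUnif(rng, 2) < spec@synonymDensity / 2)
  syn <- character(0)
  if (n > 0) syn <- vapply(seq_len(n), function(i) synthName(rng), "")
  if (length(pool) && lcgUnif(rng) < spec@nameCollisionRate)
    syn <- c(syn, lcgPick(rng, pool))
  unique(syn)
}

#' Generate a synthetic organism
#'
#' Builds a PGDB that passes [validatePGDB()] cleanly and populates every
#' diagram region. Deterministic: the same spec yields a byte-identical
#' network (and therefore the same version stamp).
#'
#' @param spec a [FixtureSpec-class].
#' @param organismId organism identifier of the generated PGDB.
#' @return a [PGDB-class].
#' @export
makeOrganism <- function(spec = fixtureSpec(), organismId = "DEMO-ORG") {
  rng <- lcgNew(spec@seed)
  cn <- spec@counts
  ents <- list()
  namePool <- character(0)
  addEnt <- function(e) ents[[length(ents) + 1L]] <<- e

  # shared cofactor pool: drives metabolite duplication across pathways
  cofactors <- sprintf("COF-%d", seq_len(4))
  for (i in seq_along(cofactors)) {
    nm <- synthName(rng)
    namePool <<- c(namePool, nm)
    addEnt(newCompound(cofactors[i], nm, synonyms = maybeSynonyms(rng, spec)))
  }

  ecPools <- list(central = "4.1.2", catabolic = "2.7.1",
                  anabolic = "1.1.1", signal = "2.7.13")
  enzCount <- 0L; geneCount <- 0L; rxnCount <- 0L; cpdCount <- 0L
  argGenes <- character(0)

  addEnzymeWithGene <- function(rxnId, category, argStem = NULL) {
    enzCount <<- enzCount + 1L
    eid <- sprintf("ENZ-%03d", enzCount)
    enm <- paste0(synthName(rng, "ase"), " ",
                  c(central = "synthase", catabolic = "kinase",
                    anabolic = "dehydrogenase", signal = "sensor",
                    grid = "mutase")[[category]])
    addEnt(newProtein(eid, enm, synonyms = maybeSynonyms(rng, spec),
                      isEnzyme = TRUE,
                      genes = vapply(seq_len(cn$genesPerEnzyme), function(k) {
                        geneCount <<- geneCount + 1L
                        gid <- sprintf("G-%03d", geneCount)
                        gnm <- if (!is.null(argStem)) {
                          argGenes <<- c(argGenes, gid)
                          argStem
                        } else paste0(lcgPick(rng, letters[1:20]),
                                      lcgPick(rng, SYL1), LETTERS[lcgInt(rng, 26)])
                        addEnt(newGene(gid, gnm, products = eid))
                        gid
                      }, "")))
    eid
  }

  makePathway <- function(category, pwIndex, cluster) {
    nrx <- cn$reactionsPerPathway
    if (nrx == 0) return(invisible(NULL))
    pwId <- sprintf("PWY-%s-%d", toupper(substr(category, 1, 3)), pwIndex)
    # chain compounds
    chain <- vapply(seq_len(nrx + 1), function(i) {
      cpdCount <<- cpdCount + 1L
      cid <- sprintf("CPD-%03d", cpdCount)
      nm <- synthName(rng)
      namePool <<- c(namePool, nm)
      addEnt(newCompound(cid, nm, synonyms = maybeSynonyms(rng, spec, namePool),
                         formula = sprintf("C%dH%dO%d", lcgInt(rng, 12),
                                           lcgInt(rng, 24), lcgInt(rng, 8))))
      cid
    }, "")
    rxns <- vapply(seq_len(nrx), function(i) {
      rxnCount <<- rxnCount + 1L
      rid <- sprintf("RXN-%03d", rxnCount)
      subs <- stats::setNames(1, chain[i])
      prods <- stats::setNames(1, chain[i + 1])
      if (lcgUnif(rng) < 0.5) subs <- c(subs, stats::setNames(1, lcgPick(rng, cofactors)))
      if (lcgUnif(rng) < 0.5) {
        cof <- lcgPick(rng, setdiff(cofactors, names(subs)))
        prods <- c(prods, stats::setNames(2, cof))
      }
      withEc <- lcgUnif(rng) < 0.8
      argStem <- if (category == "catabolic" && i == 1 && pwIndex == 1) "argA" else NULL
      enz <- addEnzymeWithGene(rid, category, argStem)
      addEnt(newReaction(rid, paste0(synthName(rng), " ",
                                     c(central = "aldolase", catabolic = "kinase",
                                       anabolic = "reductase", signal = "kinase")[[category]],
                                     " reaction"),
                         substrates = subs, products = prods,
                         synonyms = maybeSynonyms(rng, spec),
                         ec = if (withEc) sprintf("%s.%d", ecPools[[category]],
                                                  rxnCount) else character(0),
                         enzymes = enz, compartment = "cytosol", pathways = pwId))
      rid
    }, "")
    pwName <- switch(category,
      central = c("glycolysis-like backbone", "citrate-cycle-like loop")[
        min(pwIndex, 2)],
      catabolic = paste0(entityNameOf(chain[1]), " degradation ",
                         as.character(as.roman(pwIndex))),
      anabolic = paste0(entityNameOf(chain[nrx + 1]), " biosynthesis ",
                        as.character(as.roman(pwIndex))),
      signal = paste0("two-component signaling ", pwIndex))
    addEnt(newPathway(pwId, pwName, reactions = rxns,
                      synonyms = maybeSynonyms(rng, spec),
                      category = if (category == "anabolic")
                        "anabolic_intermediary" else category,
                      cluster = cluster))
    invisible(pwId)
  }
  entityNameOf <- function(id)
    ents[[which(vapply(ents, function(e) e$frameId, "") == id)[1]]]$name

  for (i in seq_len(cn$central))
    makePathway("central", i, "central metabolism")
  for (i in seq_len(cn$catabolic))
    makePathway("catabolic", i,
                if (i <= 2) "sugar degradation" else "amine degradation")
  for (i in seq_len(cn$anabolic))
    makePathway("anabolic", i,
                if (i <= 2) "amino-acid biosynthesis" else "cofactor biosynthesis")
  for (i in seq_len(cn$signal))
    makePathway("signal", i, "two-component systems")

  # unassigned reactions: pairs over the cofactor pool, half enzyme-bearing
  for (i in seq_len(cn$unassigned)) {
    rxnCount <- rxnCount + 1L
    rid <- sprintf("RXN-%03d", rxnCount)
    cpdCount <- cpdCount + 1L
    cid <- sprintf("CPD-%03d", cpdCount)
    nm <- synthName(rng)
    addEnt(newCompound(cid, nm, synonyms = maybeSynonyms(rng, spec)))
    enz <- if (i %% 2 == 0) addEnzymeWithGene(rid, "grid") else character(0)
    addEnt(newReaction(rid, paste0(nm, " mutase reaction"),
                       substrates = stats::setNames(1, cid),
                       products = stats::setNames(1, lcgPick(rng, cofactors)),
                       ec = if (i %% 3 == 0) sprintf("5.4.2.%d", i) else character(0),
                       enzymes = enz, compartment = "cytosol"))
  }

  # transporters: membrane reactions moving an external compound inward;
  # the first transporter gene is named argT, and an argR-named gene
  # produces a tRNA, so "arg" searches span all four element classes
  for (i in seq_len(cn$transporters)) {
    cpdCount <- cpdCount + 1L
    ext <- sprintf("CPD-%03d", cpdCount)
    addEnt(newCompound(ext, paste0("external ", synthName(rng))))
    rxnCount <- rxnCount + 1L
    rid <- sprintf("TRXN-%03d", rxnCount)
    tid <- sprintf("TPT-%02d", i)
    geneCount <- geneCount + 1L
    gid <- sprintf("G-%03d", geneCount)
    gnm <- if (i == 1) "argT" else paste0(lcgPick(rng, letters[1:20]),
                                          lcgPick(rng, SYL1), "T")
    if (i == 1) argGenes <- c(argGenes, gid)
    addEnt(newGene(gid, gnm, products = tid))
    addEnt(newProtein(tid, paste0(synthName(rng), " permease"),
                      isTransporter = TRUE, genes = gid))
    addEnt(newReaction(rid, paste0("transport of ", entityNameOf(ext)),
                       substrates = stats::setNames(1, ext),
                       products = stats::setNames(1, lcgPick(rng, cofactors)),
                       enzymes = tid,
                       compartment = if (i %% 2 == 0) "outer_membrane"
                                     else "inner_membrane"))
  }

  # periplasmic reactions
  for (i in seq_len(cn$periplasmic)) {
    cpdCount <- cpdCount + 1L
    ca <- sprintf("CPD-%03d", cpdCount)
    addEnt(newCompound(ca, paste0("periplasmic ", synthName(rng))))
    rxnCount <- rxnCount + 1L
    rid <- sprintf("PRXN-%03d", rxnCount)
    addEnt(newReaction(rid, paste0(synthName(rng), " hydrolase reaction"),
                       substrates = stats::setNames(1, ca),
                       products = stats::setNames(1, lcgPick(rng, cofactors)),
                       ec = sprintf("3.2.1.%d", i),
                       compartment = "periplasm"))
  }

  # tRNAs; the first is encoded by an "arg"-named gene
  if (cn$transporters > 0 || cn$central > 0) {
    for (i in seq_len(2)) {
      rid <- sprintf("TRNA-%02d", i)
      geneCount <- geneCount + 1L
      gid <- sprintf("G-%03d", geneCount)
      gnm <- if (i == 1) "argR" else paste0(lcgPick(rng, letters[1:20]), "R")
      if (i == 1) argGenes <- c(argGenes, gid)
      addEnt(newGene(gid, gnm, products = rid))
      addEnt(newRNA(rid, paste0("tRNA-", c("arg", "vol")[i]), genes = gid))
    }
  }

  newPGDB(organismId, ents)
}

#' Write a synthetic omics datafile
#'
#' Row labels are drawn (with the explicit RNG) from the PGDB's genes,
#' reactions, compounds and proteins; `badLabelRate` of the rows get
#' injected unknown labels; values are log-normal (meanlog 1, sdlog 1);
#' `missRate` of the cells are blanked to "NA". Reproducible by seed.
#'
#' @param pgdb a [PGDB-class].
#' @param path output file path.
#' @param nRows,nCols table shape (`nCols` experiment columns).
#' @param seed RNG seed.
#' @param missRate,badLabelRate rates in [0, 1].
#' @return invisible list with the injected `badLabels` and the written path.
#' @export
makeOmicsFile <- function(pgdb, path, nRows = 40L, nCols = 3L, seed = 7L,
                          missRate = 0.05, badLabelRate = 0) {
  stopifnot(missRate >= 0, missRate <= 1, badLabelRate >= 0, badLabelRate <= 1)
  rng <- lcgNew(seed)
  # labels that resolve to drawn elements: reactions and compounds directly,
  # proteins via their reactions, genes via protein products with reactions
  enzRxn <- list()
  for (e in entitiesOfKind(pgdb, "reaction"))
    for (en in e$enzymes) enzRxn[[en]] <- c(enzRxn[[en]], e$frameId)
  pool <- names(pgdb@entities)[vapply(pgdb@entities, function(e) {
    switch(e$kind,
           reaction = TRUE, compound = TRUE,
           protein = !is.null(enzRxn[[e$frameId]]),
           gene = any(vapply(e$products, function(p)
             !is.null(enzRxn[[p]]), TRUE)),
           FALSE)
  }, TRUE)]
  pool <- sort(pool)
  nBad <- round(nRows * badLabelRate)
  labels <- character(nRows)
  badAt <- if (nBad > 0) seq(1, nRows, length.out = nBad) else integer(0)
  badAt <- unique(round(badAt))
  badLabels <- sprintf("unknown-label-%02d", seq_along(badAt))
  bi <- 0L
  for (i in seq_len(nRows)) {
    if (i %in% badAt) {
      bi <- bi + 1L
      labels[i] <- badLabels[bi]
    } else labels[i] <- lcgPick(rng, pool)
  }
  # keep labels unique so row bookkeeping is exact (duplicates are a parser
  # concern, tested separately)
  dup <- duplicated(labels)
  k <- 0L
  while (any(dup)) {
    for (i in which(dup)) labels[i] <- lcgPick(rng, pool)
    k <- k + 1L; if (k > 100) { labels <- make.unique(labels); break }
    dup <- duplicated(labels)
  }
  vals <- matrix(exp(1 + lcgNorm(rng, nRows * nCols)), nrow = nRows)
  cells <- matrix(formatC(vals, format = "g", digits = 6), nrow = nRows)
  if (missRate > 0) {
    miss <- matrix(lcgUnif(rng, nRows * nCols) < missRate, nrow = nRows)
    cells[miss] <- "NA"
  }
  header <- paste(c("label", sprintf("exp%d", seq_len(nCols))), collapse = "\t")
  rows <- vapply(seq_len(nRows), function(i)
    paste(c(labels[i], cells[i, ]), collapse = "\t"), "")
  writeLines(c("# synthetic omics datafile", header, rows), path)
  invisible(list(path = path, badLabels = badLabels[seq_len(bi)],
                 labels = labels))
}

#' Write the demo bundle
#'
#' Native network file + omics sample + expected-output digests for the
#' default demo organism; the walkthrough input used by the docs and the
#' end-to-end tests.
#'
#' @param dir output directory.
#' @param spec a [FixtureSpec-class].
#' @return invisible list with the bundle paths and the PGDB.
#' @export
writeDemoBundle <- function(dir, spec = fixtureSpec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pgdb <- makeOrganism(spec)
  net <- file.path(dir, "network.yaml")
  writeNetwork(pgdb, net)
  om <- file.path(dir, "omics.tsv")
  makeOmicsFile(pgdb, om, nRows = 40L, nCols = 3L, seed = spec@seed + 1L,
                missRate = 0.05, badLabelRate = 0.1)
  master <- layoutMaster(pgdb)
  dig <- list(stamp = pgdb@versionStamp,
              master = digest::digest(masterLayoutJSON(master), algo = "sha1",
                                      serialize = FALSE))
  jsonlite::write_json(dig, file.path(dir, "digests.json"), auto_unbox = TRUE)
  invisible(list(network = net, omics = om, digests = file.path(dir, "digests.json"),
                 pgdb = pgdb))
}
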