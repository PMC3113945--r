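# cellmapr

Batch generation of organism-specific, semantically zoomable metabolic map
diagrams ("cellular overviews") from a metabolic network description, with
search/highlight overlays, tooltip data, and painting of omics datasets onto
the map.

Systems biologists publishing a metabolic reconstruction — or serving one
through a slippy-map web client — need a full-organism diagram that follows
the field's drawing conventions: glycolysis/TCA-style central pathways in
the middle column separating catabolism (right) from anabolism and
intermediary metabolism (left), pathways grouped into shaded clusters and
flowing top-to-bottom, transporters embedded in the membranes, periplasmic
reactions between the two membranes of the Gram-negative template, and a
rectangular grid of reactions not assigned to any pathway. `cellmapr`
produces that diagram as a deterministic tile pyramid plus the sidecar data
a client needs to make it interactive.

## What it computes

Given a network (native YAML dialect or SBML, with pathway grouping from
Level 3 `groups` or a sidecar file), the pipeline runs in four steps:

1. **Master layout** — one zoom-independent placement of every drawable
   object, in master units (1 unit = 1 px at the deepest zoom). A
   deterministic slot-packing layout: clusters packed per category column,
   pathways within a cluster by descending reaction count, reaction chains
   drawn downward. Highly connected metabolites are *duplicated* — every
   reaction draws its own substrate/product glyphs (shared only along a
   pathway's linear chain), because drawing all metabolite connections
   would make the diagram unreadable.
2. **Semantic zoom** — six levels, scale halving per level. The feature
   policy is monotone: level 0 shows glyphs, blue reaction lines and
   cluster shading; enzymes appear from level 2 (never at the lowest
   level); pathway, compound, enzyme/gene names and EC numbers appear at
   successive levels. Labels that do not fit are dropped, never truncated.
3. **Rasterization** — one deterministic pixel buffer per level (built-in
   bitmap font, no platform font stack), format-independent.
4. **Tiling** — each level is sliced into 400 x 200 tiles addressed
   `(level, col, row)`, cached on the file system under a content-hash
   *version stamp*; tiles are regenerated only when the network changes.

On top of the base map: **node data** (per-zoom clickable geometry per
object) and **frame data** (tooltip text + links); five **highlight**
command families (pathways, reactions — including EC-prefix and
enzyme-name modes —, genes, enzymes, compounds) returning named overlays
with found-object lists; and the **omics viewer**, which maps a
tab-delimited table of per-gene/reaction/compound/protein values onto
reaction lines and compound glyphs through a shared yellow-orange-red color
ramp, one overlay frame per experiment column (an animation).

## Worked example

The package ships a deterministic synthetic-organism generator, so the
whole pipeline runs with no external data:

```r
library(cellmapr)

pgdb <- makeOrganism(fixtureSpec(seed = 42))
pgdb
#> PGDB for organism DEMO-ORG
#>   stamp: c9ac42b5acee
#>   compound: 76, reaction: 61, pathway: 11, protein: 53, rna: 2, gene: 55

res <- buildMap(pgdb, "demo-map")   # layout -> 6 levels -> tiles -> client data
res$counters
#> $renders
#> [1] 6        # six level rasters rendered and sliced into tiles
#> $hits
#> [1] 0        # re-running buildMap on the unchanged network gives 6 hits, 0 renders

ov <- searchGenes(res$map, "arg")   # gene search expands to display elements
listOverlay(ov)
#>    frameId                             name   x   y
#> 2  RXN-009       galovoline kinase reaction 502 522
#> 3   TPT-01              nerovoline permease  60 141
#> 1  ENZ-009                sulosulase kinase 530 522
#> 5 TRXN-055 transport of external demomexate  60 119
#> 4  TRNA-01                         tRNA-arg  12 192
```

The `arg` gene family resolves to a reaction, a transporter, an enzyme, a
transport reaction and a tRNA — the four element classes a gene search
covers — each with the master-coordinate anchor used for its location
marker. `demo-map/` now holds `masterlayout.json`, `tiles/DEMO-ORG/<stamp>/z0..z5/`
(PNG tiles, 400 x 200 each), and `clientdata/` with `nodedata-z*.json` and
`framedata.json`.

Omics painting uses the shipped sample datafile:

```r
ds <- parseOmicsFile(system.file("extdata", "sample-omics.tsv", package = "cellmapr"))
ds@experiments
#> [1] "t0"  "t10" "t30"
```

followed by `resolveRows()`, `fitColorMap()`, `buildFrames()` (three
overlay frames, one per column, on one shared color key) and
`exportFrames()` (composited PNG + overlay document per frame, plus the
legend).

A thin command-line wrapper covers the same operations
(`inst/cli/cellmapr`): `build-map`, `tiles`, `search`, `omics` and `demo`.

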