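---
title: "Methods: layout, semantic zoom, tiling and omics painting in cellmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layout, semantic zoom, tiling and omics painting in cellmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmapr)
```

`cellmapr` turns a pathway/genome-style network description into a
published map bundle: a six-level tile pyramid, clickable node data,
tooltip frame data, search overlays and omics animation frames. This
vignette is the package's own account of how each stage works, which
choices were genuinely open, and what the synthetic test organism does and
does not demonstrate.

## The network model

A `PGDB` holds six entity kinds — compounds, reactions, pathways, proteins,
RNAs, genes — keyed by unique frame IDs. Frame IDs are database keys and
match case-sensitively; names and synonyms are human text and match
case-insensitively. This asymmetry is applied uniformly in search, in omics
row resolution and in the gene-file mode.

The native dialect is a versioned YAML schema (`cellmapr_network: 1`, one
list section per kind; see `inst/extdata/sample-network.yaml` for a
complete example). YAML was chosen over an ad-hoc format because the
structure is nested but small, and a standard parser removes a whole class
of quoting bugs. SBML Level 2/3 import covers the core subset
(compartments, species, reactions, stoichiometry) plus pathway grouping
from the Level 3 `groups` extension or a two-column sidecar; SBML
compartments are translated to the fixed vocabulary
{cytosol, periplasm, inner_membrane, outer_membrane} through an explicit
mapping — we refuse to guess an unmapped compartment unless a default is
configured.

The **version stamp** is the sha1 of a canonicalized serialization:
entities sorted by frame ID, set-valued fields sorted, pathway reaction
order preserved (it is the drawn chain, hence meaningful). The stamp is
therefore invariant under reordering of the input file and changes exactly
when content changes; it is the sole cache-invalidation key.

Pathway categories (`central`, `catabolic`, `anabolic_intermediary`,
`signal`, `other`) must be supplied in the input. Classifying pathways as
catabolic versus anabolic automatically is a curation judgment, not
something a layout tool should infer from stoichiometry; we deliberately
require it rather than guess.

## Master layout

Layout is a deterministic slot-packing procedure in *master units* — one
unit equals one pixel at the deepest zoom level; origin top-left, y grows
downward. The canvas is capped at 24,000 x 24,000 units (organism-scale
maps reach above 20,000 pixels at top zoom).

Horizontal bands from the top: extracellular (44 u), outer membrane
(22 u), periplasm (64 u), inner membrane (22 u), then cytoplasm.
Cytoplasmic pathway clusters are packed into three columns — anabolic and
intermediary metabolism left, central metabolism middle, catabolic right —
so the central column strictly separates the two sides. Within a column,
clusters stack vertically in cluster-name order; within a cluster,
pathways pack left-to-right by descending reaction count (ties broken by
frame ID). Signal-transduction pathways occupy a strip along the bottom
left; this is a region placement only — their internal drawing uses the
same chain grammar as metabolic pathways, with no signaling-specific
glyphs. Reactions in no pathway form a row-major rectangular grid (4
columns by default) to the right of the catabolic column. Compartment
takes precedence over pathway category: a periplasmic or membrane reaction
is drawn in its band even if its pathway lives in the cytoplasm.

Each pathway is drawn as a vertical chain: one 40-unit step per reaction,
a single blue line per reaction, circle glyphs for main-chain metabolites,
triangles for side substrates/products, a green box per enzyme, teed icons
for tRNAs, and a box spanning the membrane for each transporter. The
"main" substrate/product of a step is the compound that links it to the
neighboring step when one exists, so linear chains share their
intermediate glyphs; *all other sharing duplicates the metabolite glyph*
and no edges are ever drawn between duplicates. Internally every reaction
first emits its own local glyph occurrences (chain-shared ones at
identical coordinates) and `duplicateMetabolites()` collapses exact
coincidences — which makes the "one glyph per local occurrence, shared
only along a chain" rule a checkable identity rather than a side effect.

A reaction listed by several pathways is drawn once, in the
lexicographically first of them; the other pathways' overlays still
highlight the same drawn line. Transport reactions are drawn as short
stubs on either side of the membrane band rather than one line through the
transporter box, so the box and the line remain separately clickable.

The visual grammar (which shape encodes which object class) follows the
conventional map iconography but the exact assignment is a package
convention, documented here, not an externally fixed standard.

## Semantic zoom and the label-fit rule

Six levels, scale factor 2 between adjacent levels (level 0 renders at 32
units/px, level 5 at 1:1). Six is the published depth for maps of this
kind; the factor of 2 is the tile-map convention. The feature policy maps
each element class to the lowest level at which it appears:

| class | appears from |
|---|---|
| compound/transporter/RNA glyphs, reaction lines, cluster shading | 0 |
| cluster and pathway names | 1 |
| enzyme glyphs | 2 |
| compound names | 3 |
| enzyme, gene and RNA names | 4 |
| EC numbers | 5 |

Only two rows of this table are externally fixed — enzymes must be absent
at the lowest level, and names appear "at higher magnification" — the rest
is the package default and fully configurable through `zoomPolicy()`.

Pixel geometry is `floor(x / scale + 0.5)` (half-up), applied once at
specialization. Labels render at a fixed 5x7-pixel font size at every
level; a label is **dropped, never truncated**, if its text box would
overlap a glyph or an already-placed label, processed greedily in a fixed
order. Placements cascade upward: a label placed at level *k* is kept at
every higher level. Because anchor distances double while label boxes stay
constant, two labels that fit at one level cannot collide at the next, so
the cascade preserves label-label non-overlap *and* makes the drawn-element
set provably monotone in the zoom index. (An inherited label can in
principle brush a glyph that grew with the scale; glyph-label contact is
cosmetic and accepted.)

## Rasterization and tiling

Rendering writes into a numeric `[height, width, 3]` buffer with
package-internal primitives (Bresenham lines, scanline discs/triangles, a
built-in 5x7 bitmap font). No graphics device or platform font is
involved: the buffer is byte-deterministic and independent of the encoded
format, which is what makes the pixel-exact mosaic and cache tests
meaningful. Internally drawing accumulates pixel writes and commits them
in three vectorized assignments (last write wins), which keeps rendering
linear in drawn pixels rather than in buffer copies.

Tiles are 400 x 200 pixels; edge tiles are padded with the background so
every tile has full size. Tile `(c, r)` of a level holds exactly the pixel
block `[c*400, (c+1)*400) x [r*200, (r+1)*200)`, so laying tiles
contiguously and cropping reproduces the level raster bit-for-bit. The
cache lives at `root/organism/stamp/z<level>/col_row.png`: embedding the
stamp makes invalidation atomic (write the new stamp directory, delete the
old). A first miss generates the *whole level* — the per-level pipeline is
the natural unit and amortizes rendering — and a hit performs zero
rendering, which the render/hit counters expose for testing. PNG is the
encoded format: it is lossless, byte-stable, and sidesteps the palette
quantization that an indexed format would reintroduce; the pixel buffer
itself is format-agnostic.

## Node data, frame data, search

`buildNodeData()` maps every drawn element to one primitive in level pixel
coordinates (circles for circular glyphs, rectangles otherwise, polylines
with a 3-pixel half-width hit corridor for reaction lines — a tolerance we
fixed, as none is externally specified). Hit geometry is reliable at high
zoom; at the coarsest levels anchor spacing falls below the corridor width
and neighboring lines legitimately co-answer a query. `buildFrameData()`
assembles deterministic tooltip text from entity fields (class, synonyms,
formula, EC numbers, pathway membership, gene/product relations) plus link
targets; the field list is a documented package template.

Search overlays store primitives in *master* coordinates and are projected
to a level at display/export time, so one search serves all levels. The
five families follow fixed expansion rules: pathways highlight their
reactions; reactions offer exact, substring, EC (full number or dotted
prefix: `1.1.1` matches `1.1.1.1` but not `1.1.11`) and enzyme-name modes;
genes expand through their products to reactions, RNAs, transporters and
enzymes; enzymes highlight their protein glyphs and their reactions;
compounds highlight every duplicate glyph. Every mode is tested for
equality against an exhaustive linear scan with the same predicate.
Highlight colors per family are package defaults (none are externally
fixed) and configurable per call.

## Omics viewer

Datafiles are tab-delimited tables whose rows are labeled with gene,
reaction, compound or protein identifiers; a header row is auto-detected
as "first row with a non-numeric value cell", `#` lines are comments, and
non-numeric cells are missing values. Gene and protein labels map to their
reaction steps, reactions to themselves, compounds to their glyph
duplicates; unresolved labels are reported, never fatal, and resolved +
unresolved always equals the row count.

One color map serves the whole animation: the domain is the global
min/max over all selected columns. Per-column scaling would recolor each
frame on its own scale and make frames incomparable under the single
color key shown with the animation, so the global choice is deliberate.
The default ramp is yellow-orange-red with gray for missing values (the
spectrum itself is a package default; any monotone ramp can be
configured), interpolated linearly with clamping; a constant dataset maps
to the ramp midpoint; `log10` requires strictly positive values and names
the offending row otherwise. A reaction receiving values from several rows
takes their mean, with a warning. Each experiment column becomes one
overlay frame, in column order; compositing draws over a *copy* of the
base raster — base tiles are never regenerated by omics painting, which
the render counters verify.

## The synthetic organism

`makeOrganism()` generates the demo organism from an explicit
counter-based random source (a Park-Miller multiplicative congruential
generator threaded through a state object — exact in doubles, immune to
R's global RNG state, reproducible across platforms). The default spec
draws 2 central, 3 catabolic, 4 anabolic and 2 signal pathways of 4
reactions each, 10 unassigned reactions, 4 transporters, 3 periplasmic
reactions, a 4-compound shared cofactor pool (forcing metabolite
duplication), EC numbers on most reactions, one gene per enzyme, an
"arg"-named gene family spanning enzyme, transporter and tRNA products,
and synthetic names at 0.6 synonyms per entity with a 5% name-collision
rate. These counts were chosen once to exercise every region, glyph class
and search mode of the map at a size where the full pyramid renders in
seconds; they make no biological-realism claim.

What passing tests on this organism show: the geometric, cache and search
contracts hold on a network with every structural feature class present.
What they do not show: behavior under curated layouts, organisms with
thousands of pathways, pathologically long names, or non-chain pathway
topologies (branched pathways are drawn in listed order, so their chains
share fewer glyphs than a curated drawing would). The search-oracle checks
additionally run on a generated organism of roughly 5,000 entities; the
test suite and the acceptance script state these problem sizes explicitly
as their chosen study conditions.

## Numerical and degenerate-input choices

* Rounding is half-up, once, at specialization; all later drawing is
  integer arithmetic.
* Empty networks are valid: the layout degenerates to regions only, every
  level renders a background raster of the computed size, and all exports
  produce valid empty documents.
* Organisms with a single membrane are expressed by a zero-height
  periplasm band (set `periplasmH = 0` and one membrane height to 0 in
  `layoutParams()`); the region contract is unchanged.
* Ties everywhere break on frame ID (sorted order), which is what makes
  the serialized master layout byte-identical across runs.
* `validatePGDB()` is report-only; constructors reject only what cannot be
  represented (duplicate/dangling IDs, non-positive stoichiometry), so
  mutation-style tests can build deliberately broken networks with
  `check = FALSE` and see exactly the injected findings.

## Known limitations

* The layout optimizes for convention-compliance and determinism, not for
  minimal crossings or area; a curated drawing of the same organism will
  be more compact.
* GIF tiles are not emitted (no lossless, dependency-free GIF encoder is
  worth the palette nondeterminism); any slippy-map client consumes the
  PNG tree identically.
* Signal-transduction pathways receive region placement and chain drawing
  only.
* The HTTP scheme of omics datafile locators is parsed and typed but
  fetching is delegated to the caller (`file://` is handled natively), so
  all tests run offline.
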