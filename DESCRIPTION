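Package: cellmapr
Title: Tiled, Semantically Zoomable Metabolic Map Diagrams with Search
    and Omics Overlays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates organism-specific cellular-overview diagrams from a
    metabolic network description (native YAML dialect or SBML): a
    deterministic region-based master layout following pathway-map drawing
    conventions (central glycolysis/TCA column, catabolic right, anabolic
    left, membrane-embedded transporters, periplasmic band, unassigned
    reaction grid), a six-level semantic-zoom pyramid rendered to rasters
    and sliced into 400x200 tiles with a stamp-keyed file-system cache,
    per-zoom clickable node data and tooltip frame data, five families of
    search/highlight commands producing named overlays, and an omics viewer
    that paints tab-delimited expression datasets onto reactions and
    compounds as per-experiment animation frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    xml2,
    png,
    digest
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
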