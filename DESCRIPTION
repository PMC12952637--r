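Package: boulderreef
Title: Geomorphometry and Macroalgal Vegetation Analysis for Man-Made Boulder Reefs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing macroalgal colonisation of man-made boulder
    reefs mapped by underwater photogrammetry. Reads and georeferences
    triangulated seafloor meshes (PLY/OBJ), computes per-boulder geomorphic
    indicators (relative height within a fixed-radius neighbourhood and
    box-counting surface complexity) with edge exclusion, classifies
    five-species presence/absence records into vegetation community types and
    ordinal scores, and runs the stratified statistical battery (Welch's
    t-tests, Pearson correlations) linking vegetation to bottom type and
    geomorphology. Includes a deterministic synthetic seafloor and
    species-presence simulator so the whole pipeline is testable without
    survey data.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
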