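Package: drillguide
Title: Semi-Automatic Surgical Template Design from Anatomical Triangle
    Meshes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Designs patient-specific surgical guide templates from
    CT-derived anatomical triangle meshes.  Given an STL surface, a
    user-indicated closed point loop, a template thickness and planned
    drill axes, the package segments the tissue-contacting inner surface
    by clipping the mesh along the zero set of a signed per-vertex
    distance field, extracts a constant-thickness outer surface by
    contouring a sampled distance field of the inner patch, zips the two
    open surfaces into a watertight shell with a ruled surface chosen by
    a shortest-path label-setting dynamic program, and merges annular
    drilling tubes into the shell via oriented-bounding-box collision
    detection and union-style merging.  Includes binary/ASCII STL
    readers and writers, deterministic synthetic anatomy fixtures, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
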