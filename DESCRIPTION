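Package: schemacells
Title: Detection and Characterization of Schema Cells in Neural Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-unit and population analyses for detecting neurons whose
    trial-type firing profiles generalize across two structurally identical
    virtual mazes in a dual figure-of-eight odor-sequence task. Provides
    peri-event epoch rate extraction from spike trains, cross-maze
    correlation classification of units into schema, nonschema and noncoding
    categories, structured permutation nulls attributing generalized firing
    to trial epoch, reward or sequence position, within- and across-maze
    linear decoding of trial type from single cells and pseudo-ensembles,
    population-geometry comparisons (low-dimensional embedding with
    Procrustes alignment, canonical-variable clustering with silhouettes,
    and non-negative tensor decomposition), and a synthetic-session
    generator with known ground-truth tuning for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    cluster,
    vegan,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
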