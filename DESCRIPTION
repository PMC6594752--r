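Package: vcdme
Title: Methylome Comparison and DME-Target Analysis for the Pollen Vegetative Cell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed Fisher-exact differential-methylation analysis of
    bisulfite cytosine reports, seed/merge/filter calling of CG-hypomethylated
    DME target regions, strict DME sites with most-demethylated-cytosine
    anchors, H1 hyperDMRs, metaplot (ends and anchor-aligned) profiling
    stratified by H3K9me2, and classification of vegetative-cell-activated
    transposable elements into four mechanistic groups by their dependence on
    DME demethylation and histone H1 depletion. Includes a synthetic methylome
    generator with planted hypomethylation valleys and truth tables so every
    stage of the pipeline can be benchmarked at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
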