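Package: MosaicAncestry
Title: Ancestral Genome Reconstruction from Local-Ancestry Mosaics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a proxy gene pool for an ancestral population from
    present-day admixed genomes. Replicate local-ancestry paintings are
    reduced to consensus target-ancestry segments, a balanced candidate
    haplotype library is assembled into mosaic haplotypes under a chunk-length
    cap and a minimum-coverage mask, and the reconstructed panel anchors
    downstream population-genetic inference: balanced Hudson FST, the
    relative-difference statistic, outgroup f3 drift sharing, differentiation
    based selection screens, a rare strong-effect-variant gene screen with a
    familial-aggregation test, Ne-trajectory divergence dating, and
    linguistic distance trees. A synthetic-data module with known ancestry
    tracts provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors,
    ape,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Genetics, Coverage
RoxygenNote: 7.3.3
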