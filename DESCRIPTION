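Package: simbal
Title: Locating Functional-Specificity Regions in Proteins from Genomic Context
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the SIMBAL workflow (Sites Inferred by Metabolic
    Background Assertion Labeling) for locating short signature regions that
    confer functional specificity within a protein family. A training-set
    builder partitions a target protein family into YES/NO/FAR sets using
    profile-HMM hits and gene-neighborhood distance rules evaluated per
    genome; a scan engine scores every subsequence of a query protein by the
    binomial-tail enrichment of YES-labeled sequences among its ranked
    homology hits; post-processing tools smooth the score landscape by
    inheritance from longer containing subsequences and extrapolate scores to
    single residues; results are rendered as triangular heat maps. Includes a
    seeded synthetic-fixture generator with planted sequence signatures so the
    whole pipeline can be exercised without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
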