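Package: cgrtyper
Title: Chaos Game Representation of Genome-Wide Variant Genotypes for
    Species and Cultivar Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts multi-sample variant genotypes into pseudo-DNA
    sequences, renders them as greyscale chaos game representation (CGR)
    images, and classifies samples by species or cultivar with
    class-weighted models under four integration strategies
    (chromosome-wise, early integration, late integration by majority
    vote, and whole genome).  Performance is measured by balanced
    accuracy and compared against sequence-similarity baselines
    (pairwise-identity nearest neighbour, k-mer Jaccard nearest
    neighbour, and a precomputed-kernel support vector machine).  A
    hierarchical-divergence simulator generates labelled pseudo-sequence
    collections so that the full pipeline is reproducible without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    kernlab,
    png,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
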