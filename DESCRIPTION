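Package: promotif
Title: Gene Module Discovery from Promoter Transcription-Factor
    Binding-Site Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clusters differentially regulated genes by the transcription
    factor (TF) binding-site composition of their promoters. Promoter windows
    around each transcription start site are scanned on both strands with
    log-odds position weight matrices under a Markov background model
    estimated from the scanned sequences; exact score-distribution p-values
    are controlled at a configurable false discovery rate, overlapping hits
    for the same TF are collapsed, and the resulting gene-by-TF count matrix
    is clustered with k-means to reveal gene modules under shared predicted
    regulatory control. Cluster-specific candidate regulators are prioritized
    by Fisher exact tests on the binarized matrix, gene-signature enrichment
    is tested per module, and a randomization control re-runs the pipeline on
    a gene-label-shuffled hit table. A self-contained simulator generates toy
    genomes with planted regulatory modules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    cluster,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
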