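Package: knemap
Title: Knowledge-Driven Network Mapping of Transcriptomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fuses multiple prior-knowledge gene-similarity layers
    (protein interactions, pathway co-membership, shared disease or
    chemical associations, homology) into a single weighted gene network,
    partitions it into small communities by agglomerative clustering, and
    summarises each transcriptomic exposure as the distribution of its 200
    most deregulated genes over those communities. Includes three baseline
    exposure representations (binary deregulated-gene vectors, fold-change
    score vectors and preranked enrichment vectors), benchmark procedures
    for class retrieval, structure-based ranking agreement, noise
    robustness, steady-state stability and cross-dataset matching, and
    seeded synthetic-data generators with planted structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    fgsea,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
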