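Package: hdcminer
Title: Mining Histidine Decarboxylase Operons and Histamine-Secreting
    Bacteria in Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects histidine decarboxylase (hdcA) and antiporter gene
    clusters in annotated bacterial genomes from profile-HMM hit tables,
    classifies cluster architectures (hdcB, hisRS, three-component
    arginine/histidine decarboxylation systems, duplicated antiporters),
    aggregates cluster presence to species-level prevalence to flag
    histamine-secreting species, and tests whether such species are
    over-represented among disease-enriched taxa in case-control
    microbiome studies using a one-tailed two-proportion Z-test with
    continuity correction. Includes operon read-depth quantification in
    counts per million mapped reads with one-sided rank-sum comparison,
    and seeded synthetic-data generators (annotated genomes with planted
    operons, overdispersed count tables with planted effects) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse
Config/testthat/edition: 3
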