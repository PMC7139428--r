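Package: mirnethub
Title: Signed miRNA-Target Network Analysis from Small-RNA Counts to
    qPCR Validation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline from a cardiac small-RNA
    count matrix to prioritized, validation-ready mRNA targets.
    Provides two-group negative binomial differential expression of
    mature miRNAs with trimmed-mean-of-M-values (TMM) normalization,
    likelihood ratio tests and Benjamini-Hochberg correction;
    integration of predicted and curated miRNA-target interaction
    tables under strict score cutoffs; construction of a signed
    bipartite miRNA-mRNA network with per-target degree and node
    strength and target-hub detection; hypergeometric Gene Ontology
    over-representation with fold enrichment; a hub-selection rule
    combining node strength with top enrichment; and 2^-ddCp relative
    quantification statistics for qRT-PCR validation with in-silico
    amplicon checks. A synthetic-data generator with planted ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
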