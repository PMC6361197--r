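Package: lncnet
Title: Two-Group Differential Expression and Thresholded lncRNA-mRNA
    Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-group (tumour versus normal)
    normalized expression matrices carrying both long non-coding RNAs and
    mRNAs. Implements volcano-style differential-expression screening
    (fold change and Student's t-test thresholds), hierarchical clustering
    of samples and transcripts, construction of thresholded Pearson
    lncRNA-mRNA co-expression networks with exact correlation P values and
    topology summaries (degrees, edge signs, connected components,
    Cytoscape-loadable exports), hypergeometric over-representation
    analysis against GMT gene-set collections, and 2^-ddCt relative
    quantification of qRT-PCR cycle thresholds with concordance checks
    against array calls. Includes a seeded latent-factor simulator that
    plants differential expression and co-expression blocks with
    machine-readable ground truth, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
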