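Package: grnstep
Title: Stepwise Gene Regulatory Network Inference from Targeted qPCR Panels
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers candidate gene regulatory networks from targeted qPCR
    expression panels by a stepwise procedure: co-expression-based candidate
    selection from a neighbor database, delta-delta-Cq relative quantification,
    paired-t consistency screening of elongated-versus-short fin regions across
    fins and regeneration stages, module extension, promoter motif enrichment
    with matching against a position-weight-matrix library to nominate upstream
    transcription factors, and Pearson correlation network assembly. Ships a
    synthetic-data generator that plants a ground-truth TF-target network so
    every stage is testable by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    lme4,
    jsonlite,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
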