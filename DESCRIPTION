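Package: spongenet
Title: Inference of lncRNA-Driven miRNA-Sponge Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs competing endogenous RNA (ceRNA) networks in which
    long non-coding RNAs act as miRNA sponges for mRNAs. Candidate
    lncRNA-mRNA pairs are scored by hypergeometric enrichment of their
    shared miRNA interaction evidence, observational causal effects are
    estimated with the PC-stable algorithm followed by local IDA
    (intervention calculus when the DAG is absent), network edges are
    called by Fisher z-transform correlation significance under
    Benjamini-Hochberg false discovery control, and hub lncRNAs are
    selected by node degree. A linear-Gaussian sponge-system simulator
    with latent miRNA regulators and corruptible interaction-evidence
    tables supports calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
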