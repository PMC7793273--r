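Package: nfyregulome
Title: Co-Association Analysis of the NF-Y Regulome from ChIP-Seq Peak Summits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterizing the regulome of the CCAAT-binding
    transcription factor NF-Y from ENCODE-style ChIP-seq data: replicate
    curation of peak-summit datasets, summit-overlap co-association scoring
    under a Poisson accessible-region null, CCAAT motif enrichment (global,
    local) and motif-to-CCAAT positional bias, a four-group partner
    classification, chromatin-state and target-gene annotation with pathway
    over-representation, and pairwise Fisher statistics of co-regulation in
    differential-expression data. A synthetic-data module generates every
    input with planted ground truth so the whole pipeline can be exercised
    and validated end-to-end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
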