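Package: switchnet
Title: Signed Co-Expression Networks and Target Transcription Factor
    Discovery for Aphid-Infested Switchgrass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed weighted gene co-expression networks from
    RNA-seq count matrices and walks them through the defense-response
    analysis used for aphid-infested switchgrass: topological overlap,
    module detection with eigengene merging, a three-criterion target
    transcription-factor cascade (top-decile module membership,
    75th-percentile peak expression, profile-matched differential
    expression), per-TF top-1% TOM subnetworks, Fisher's-exact pathway
    enrichment against the network background, and paired
    transcript/metabolite pathway-occupancy statistics. Ships a
    synthetic-data generator that plants module profiles, hub TFs,
    pathway enrichments and metabolite sets so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
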