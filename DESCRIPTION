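Package: gelquant
Title: Agarose Gel Smear Quantification, ChIP-qPCR Standard Curves and
    Peak Concordance
Version: 0.1.0
Authors@R:
    person("gelquant", "developers", email = "gelquant@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of ethidium-bromide-stained agarose gel
    images of sheared DNA: ladder-calibrated migration-to-size mapping,
    per-lane smear curves, mean fragment size and the fraction of signal
    inside a target size window, with waterfall summaries across lanes.
    Also provides ChIP-qPCR standard-curve quantification (amplification
    efficiency, fraction of input, Student t significance encoding),
    broadPeak filtering and interval-overlap concordance with TSS mark
    assignment and expression stratification, and a seeded synthetic gel
    simulator that supplies ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jpeg,
    jsonlite,
    optparse,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
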