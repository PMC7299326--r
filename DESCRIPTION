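Package: pibs
Title: Dyadic Brain-Transcriptomic and Behavioral Synchrony Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify transcriptomic and behavioral synchronization
    between the two opponents of a fighting pair. Implements TMM-normalized
    expression values, per-gene expression-distance statistics between all
    sample dyads, exact permutation tests comparing paired against unpaired
    dyads, assignment of synchronized genes to specific fighting pairs via an
    unpaired-distance percentile baseline, hypergeometric set-overlap and
    over-representation statistics, and sliding-window summaries of dyadic
    fighting behavior. A negative-binomial count simulator with pair-shared
    expression effects and a mouth-lock-gated behavioral event simulator
    provide ground-truth data for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
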