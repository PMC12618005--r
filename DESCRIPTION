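Package: cavesleep
Title: Sleep Scoring, DNA-Repair Readouts and Expression Responses for
    Cavefish UV Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studies linking sleep and the DNA-damage
    response in Astyanax mexicanus surface fish and cavefish. Scores sleep
    bouts (consolidated immobility of 60 s or more below a 6 mm/s velocity
    cut-off) from locomotor velocity traces and derives windowed sleep
    metrics, binned 24 h sleep profiles and per-epoch sleep/wake transition
    probabilities; computes the host-cell-reactivation relative expression
    statistic (%RE, from F = N x MFI / S) on gated flow-cytometry event
    tables; quantifies fluorescence by average-intensity z-projection, gut
    ROI means and per-nucleus means over label masks; and implements the
    downstream expression computations (Benjamini-Hochberg adjustment,
    population response classification, DEG counting, signed -log10(p)
    gene ranking, preranked gene-set enrichment with a permutation null,
    and delta-delta-Ct fold changes). Seeded synthetic-data generators for
    all four input kinds make every stage testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    knitr
Config/testthat/edition: 3
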