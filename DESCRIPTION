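Package: sortscreen
Title: Variant Scoring and Structural Inference for Binned Sort-Seq Deep
    Mutational Scans
Version: 0.1.0
Authors@R:
    person("Sortscreen", "Developers", email = "sortscreen@example.org",
           role = c("aut", "cre"))
Description: Analysis of multiplexed assays of variant effect that sort a
    barcoded site-saturation library into fluorescence quartile bins and
    deeply sequence each bin (sort-seq / VAMP-seq designs). Provides barcode
    subassembly consensus calling against a coding reference, per-bin barcode
    counting with Phred quality filtering, frequency-weighted variant scores
    min-max normalized to nonsense and synonymous anchor distributions with
    replicate-based confidence intervals, five-way abundance/activity
    classification, sliding-window substitution-class profiles for
    transmembrane topology inference, positional hierarchical clustering and
    specific-activity active-site calling, and local secondary-structure
    calling from residue-pair coupling strengths. A generative model of the
    binned-sort experiment supports end-to-end testing without access to raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
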