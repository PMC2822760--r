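Package: acghsig
Title: Deletion-Signature Discovery in Array CGH Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-imbalance analysis for array comparative genomic
    hybridization (aCGH) cohorts measured as simple test/reference
    fluorescence ratios. Provides iterative outlier-resistant estimation
    of per-sample noise, ternary copy-number calling at multiples of the
    per-sample standard deviation, an adjacent-probe recurrence screen
    with masking of known copy-number-variant regions, a two-class
    permutation Significance Analysis of Microarrays (SAM) with
    delta-gap probe selection, hierarchical clustering of samples, and
    region-level deletion-signature classification, together with a
    synthetic cohort generator that plants clonal-fraction-attenuated
    aberrations and records a matching truth set for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
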