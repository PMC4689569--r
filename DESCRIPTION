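Package: codonbias
Title: Gene-Specific Codon Usage Bias and Codon-Biased Translation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for codon-biased translation: gene-specific
    codon usage scoring against the genome average with hypergeometric
    enrichment calls, detection of physical codon clustering (sliding-window
    profiles, overlapping codon-run counts, composition-preserving shuffle
    nulls), SILAC-style differential proteomics with replicate filtering,
    resampling null distributions for codon-enriched protein groups with
    co-enrichment, mRNA-level and abundance-matched controls, and gene-level
    ribosome-pausing integration from footprint/mRNA (FP/T) abundance ratios.
    Includes a synthetic-data generator that plants known codon-enrichment,
    down-regulation and pausing effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
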