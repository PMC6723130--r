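Package: umivar
Title: UMI-Consensus Amplicon Sequencing and Position-Specific Background
    Filtering for Ultra-Rare Variant Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects somatic variants down to roughly 1/10,000 allele
    frequency in targeted amplicon deep sequencing. Paired-end reads carrying
    12-bp unique molecular identifiers (UMIs) at both ends are merged with
    mismatch masking, binned by barcode with mismatch tolerance, and collapsed
    into one consensus sequence per captured molecule; per-position
    substitutions are then called from capture-level pileups and filtered
    against an empirically derived, position- and substitution-specific
    background model in which each background rate is a Student's t
    distribution over control-sample allele frequencies, with a generic
    trinucleotide-context fallback. Includes a ground-truthed library
    simulator (single-molecule capture, round-resolved PCR errors, sequencing
    errors) so the whole stack is testable without external data, plus
    analyses for allele phasing, linked-SNP filtering, dilution-series
    evaluation and longitudinal variant tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
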