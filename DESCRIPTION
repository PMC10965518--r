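Package: svsnv
Title: Proximity-Stratified Co-Analysis of Somatic SNVs and Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the interplay between somatic single
    nucleotide variants (SNVs) and structural variant (SV) breakpoints in
    whole-genome call sets. Builds pyrimidine-normalised 96-channel
    trinucleotide mutation spectra, stratifies SNVs by distance to SV
    breakends, compares observed near-breakpoint SNV counts with their
    expectation under uniform random placement, decomposes SNV load into
    SV-dependent (slope) and SV-independent (intercept) components by
    linear regression over tiling genomic windows, and attributes spectra
    to reference SBS signatures by non-negative least-squares refitting.
    Includes a reproducible simulator of paired SV/SNV call sets with
    exported ground truth so that every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
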