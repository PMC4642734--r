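Package: meltamp
Title: Amplicon Design with DNA Melting Profiles for Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs PCR amplicons around DNA variants for melting-based
    genotyping (denaturing capillary electrophoresis and high-resolution
    melting). For each variant it selects a primer pair under Primer3-style
    constraints, verifies primer specificity by in-silico PCR against the
    genome, optionally attaches a GC-rich clamp on the thermodynamically
    appropriate side, and computes per-base equilibrium melting profiles of
    both alleles from a Poland-Scheraga partition function with
    nearest-neighbor stacking and Fixman-Freire loop-entropy acceleration,
    together with the urea-corrected analysis temperature.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
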