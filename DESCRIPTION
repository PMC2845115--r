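Package: hotplex
Title: Multiplexed Single-Base-Extension MALDI-TOF Mutation Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hotspot somatic mutation profiling with multiplexed
    single-base-extension (SBE) genotyping read out by MALDI-TOF mass
    spectrometry. Models assay panels and their analyte masses, simulates
    spectra with allele-proportional peak areas and realistic artifacts
    (unextended primer, salt adducts, baseline noise, tumor purity dilution),
    detects and integrates peaks, quantifies mutant allele fractions from
    peak areas, resolves complex multi-position codon assays, and summarises
    cohorts: per-mutation and per-gene frequencies, double-mutation
    co-occurrence against independence, mutant-allele-ratio comparisons,
    primary tumor / lymph-node concordance, and frequency-driven re-plexing
    of assay subsets into the minimum number of mass-resolvable pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
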