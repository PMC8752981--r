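Package: featsig
Title: Feature-Driven Mutational Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds 96-channel trinucleotide somatic mutation spectra from MAF or
    VCF calls against a reference genome, estimates per-sample exposures of known
    mutational signatures by constrained non-negative refitting, derives de novo
    signatures as positive/negative differential trinucleotide frequencies between
    feature-stratified genome groups (expression percentiles, mutation status, or
    continuous scores such as homologous-recombination-deficiency and hypoxia
    scores), estimates per-genome levels of a derived signature pair by
    Moore-Penrose metagene projection onto normalized spectra, and provides the
    correlative layer (Pearson correlation tables, median-split four-class
    stratification, Welch t-tests) plus a seeded synthetic cohort generator for
    end-to-end validation without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    pracma,
    data.table,
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR
Config/testthat/edition: 3
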