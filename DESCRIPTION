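Package: qsrare
Title: Rarefaction and Diversity for Viral Quasispecies Haplotype Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Library-size normalization ("rarefaction") for viral
    quasispecies haplotype abundance data. Provides subsampling of
    haplotype count tables with and without replacement, a repeated
    resampling harness with median/IQR/SD summaries, closed-form
    expectations for the number of haplotypes observed under each
    scheme (including the hypergeometric rarefaction equation),
    Hill-number diversity profiles and quasispecies-specific
    read-fraction indices (singleton fraction, rare haplotype load),
    and deterministic generators for benchmark quasispecies
    structures (all-singletons, single-dominant, prominent
    haplotypes, no-rare, flat).
License: MIT + file LICENSE
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan
Encoding: UTF-8
Config/testthat/edition: 3
biocViews: Sequencing, Metagenomics, Normalization
RoxygenNote: 7.3.3
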