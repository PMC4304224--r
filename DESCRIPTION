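Package: pdpcr
Title: In Silico Thermocycling for Parallel-DNA PCR
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence algebra and an in-silico thermocycler for parallel-DNA
    PCR (PD-PCR), a scheme in which the first primer anneals to a
    single-stranded template in parallel orientation (reverse Watson-Crick
    pairing) so that the amplified duplex has polarity opposite to the
    template. Provides validated DNA sequence transforms (reverse,
    complement, antiparallel and parallel complement), primer binding-site
    search in both pairing orientations with a duplex-mode-aware Wallace
    melting temperature, a deterministic denature/anneal/extend cycle
    simulator with exact copy bookkeeping, amplicon and threshold-cycle
    reporting, a 2^-dCt helper, primer designers for the conventional and
    PD-PCR schemes, FASTA and JSON/TSV I/O, and a seeded synthetic template
    generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
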