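Package: dominsert
Title: Programmed Domain-Insertion Library Design and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design engine for saturated, programmed domain-insertion
    libraries built from synthesized oligo pools and multi-step Golden Gate
    (type-IIS) cloning. Divides a target open reading frame into
    codon-aligned fragments with unique 4-nt assembly overhangs, emits one
    barcoded oligo per insertion position carrying a replaceable genetic
    handle, designs inverse-PCR backbone primers and subpool amplification
    primers under nearest-neighbor melting-temperature and specificity
    constraints, and verifies every design by in silico type-IIS
    digestion/ligation. Also implements library-quality statistics for
    insertion libraries (normalized insertions per residue, ECDF/KS bias
    comparison, coverage curves, reading-frame/direction enrichment, 1-bp
    deletion frequencies, insertion-context matrices) and domain-insertion
    permissibility scoring from sorted-population sequencing counts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
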