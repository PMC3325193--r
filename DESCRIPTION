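Package: chondromics
Title: Comparative Analysis of Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative analysis of plant mitochondrial
    (chondrome) annotations: genome partition accounting (exon, intron and
    intergenic-spacer fractions), detection of retroposed pseudogene
    fragments in intergenic spacers with origin classification, inference
    of C-to-U and U-to-C RNA editing by codon reconstitution and by
    comparison against unedited references, maximal direct and inverted
    repeat and microsatellite screening, and signed gene-order synteny
    comparison with a DCJ-based rearrangement-event estimate.  Includes a
    synthetic circular-genome generator that plants every structure the
    pipeline detects together with a ground-truth manifest, so the whole
    analysis is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
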