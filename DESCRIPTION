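Package: tgeclass
Title: Classification and Peptide-Level Confirmation of Translated Genomic Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies sample-specific open reading frames (translated genomic
    elements, TGEs) against a reference proteome into known proteins, known
    isoforms, known proteins with polymorphisms, novel isoforms and novel TGEs;
    extracts per-residue polymorphism events (SAP/SSAP, ALT/SALT, insertions,
    deletions, splice-scale variations) from local protein alignments; maps
    identified peptides onto variant regions; and decides variant-versus-reference
    presence with a detectability-calibrated scoring model. Includes an in-silico
    tryptic digestion engine, target-decoy q-value computation, a synthetic
    fixture generator with ground-truth labels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    xml2,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
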