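Package: pprkp
Title: Design and Evaluation of Synthetic PPR DYW:KP U-to-C RNA Editing Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating programmable U-to-C RNA editing
    factors of the pentatricopeptide repeat (PPR) DYW:KP family. The package
    covers the full computational workflow: ingestion and filtering of PPR
    motif annotations and DYW deaminase domains, plurality consensus design of
    PLS scaffolds, PPR-code retargeting and binding-site prediction,
    mismatch-tolerant transcriptome off-target scanning with sequence logos
    and neighbouring-nucleotide preference statistics, editing-efficiency
    quantification from Sanger peak areas with empirical noise zeroing, and
    RNA-editing site calling from treated/control pileups (Fisher exact test
    with Benjamini-Hochberg correction, coverage/frequency/substitution-class
    filters, control and SNP subtraction). A synthetic-data module generates
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
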