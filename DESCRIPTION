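Package: tmejscan
Title: Repair Junction Analysis and TMEJ Signature Detection for Cas9 Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing chromosomal double-strand-break repair
    outcomes from Cas9 amplicon sequencing. Reconstructs repair junctions by
    exact anchor matching around the cut site (deletion lengths, insertions,
    microhomologies), filters ambiguity- and amplification-artifact reads,
    identifies the polymerase theta-mediated end joining (TMEJ) deletion
    signature by differential depletion in Polq-deficient samples with
    Benjamini-Hochberg control of the false discovery rate, and classifies
    repair products into TMEJ, NHEJ, and other categories. Also implements the
    quantification arithmetic for signature qPCR (delta-delta Ct), droplet
    digital PCR Poisson concentration estimates, exonuclease-sensitivity
    end-resection fractions, gene-targeting band fractions, and clonogenic
    survival, plus a fully deterministic synthetic-data generator producing
    reads, junction tables, and assay tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
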