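Package: provirseq
Title: Halovirus Genome Characterization and Detection of Induced Proviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sequence-level characterization of small archaeal virus genomes and
    detection of induced (excised, circularized) proviruses from read evidence.
    Provides circular-genome k-mer censuses with maximal-order Markov odds for
    motif avoidance, windowed AT/GC skew profiles, gene-architecture statistics
    (overlap and spacing of CDS), exact direct-repeat and -1 ribosomal
    frameshift slippery-site detection, tape-measure-protein tail-length
    prediction, att-site discovery against tRNA 3' ends with integrate/excise
    coordinate arithmetic, a scanner for bridging CDS that span the attP
    junction of circularized elements, and read-level induction evidence
    (circular contigs, junction-spanning reads, coverage ratios). A synthetic
    data generator produces genomes, lysogens and read sets with a truth ledger
    so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    BiocGenerics,
    optparse,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
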