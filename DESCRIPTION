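Package: screenforge
Title: Pooled CRISPR Knockout Screen Analysis for Erythroid Differentiation Studies
Version: 0.1.0
Authors@R:
    person("Screenforge", "Developers", email = "maintainer@screenforge.dev",
           role = c("aut", "cre"))
Description: A reusable pipeline for pooled CRISPR-Cas9 knockout screen
    analysis of the kind used in marker-sorted differentiation screens:
    anchor-based sgRNA spacer extraction from FASTQ reads, 8-nt barcode
    demultiplexing, reads-per-million and log2(x+1) normalization,
    median-corrected guide-level log fold changes, gene scores as guide
    averages, and concordance-based hit calling (>= 3 of 4 guides shifting
    in the same direction).  Companion quantification helpers cover
    2^-ddCt relative expression, ChIP dCt enrichment against input,
    first-order protein half-life estimation from cycloheximide-chase
    time courses, differential-expression filtering at fold-change and
    p-value thresholds, and hypergeometric gene-set overlap.  A synthetic
    data generator produces Brunello-like libraries, structured screen
    reads with known ground truth, qPCR Ct tables and decay series so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
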