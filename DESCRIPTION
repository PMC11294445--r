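Package: wolbpan
Title: Comparative Genomics of Endosymbiont Strain Sets: Pangenome,
    Secretome, Entropy and Synteny Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale comparative-genomics toolkit for sets of closely
    related bacterial endosymbiont strains (Wolbachia-like genomes).
    Implements read hygiene with the gap-compressed mismatch-ratio filter,
    GC content and GC-skew window profiles over circular genomes,
    reciprocal-best-hit orthogroup inference with presence-absence
    variation matrices and single-copy-ortholog supermatrix export,
    signal-peptide/transmembrane secretome classification by hydropathy
    heuristics or external predictor tables, per-column Shannon-entropy
    variability scoring of orthogroup alignments, and k-mer anchor synteny
    block detection with breakpoint reporting. A synthetic strain-set
    generator with a complete ground-truth manifest makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    ape,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
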