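Package: tetelim
Title: Simulation and Analysis of Programmed DNA Elimination Statistics in Tetrahymena
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative side of programmed DNA elimination
    studies in the ciliate Tetrahymena: simulation of micronuclear genomes
    partitioned into MAC-destined segments and internal eliminated sequences
    (IESs), whole-genome and ChIP sequencing read simulation with a
    micronuclear contamination fraction, the per-IES retention index (RI)
    computed from normalized read counts, fold-enrichment tracks and the
    compiled modeled-IES metagene over 1-5 kb IES loci, phospho-site set
    merging and net-charge modelling of HP1-like protein mutants, and
    equilibrium RNA-binding (EMSA) titration simulation with
    depletion-corrected dissociation-constant estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
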