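Package: mitomosaic
Title: Assembly Finishing and Mosaic-Content Analysis of Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for finishing plant mitochondrial genome assemblies from
    contigs and for quantifying the mosaic content of the finished genomes.
    Contigs are classified against organellar references, repeat copy numbers
    are estimated from sequencing coverage, contig ends interrupted by
    mitochondrial plastid insertions (MTPTs) are paired via their plastome
    coordinates, and chromosomes are traversed out of the resulting junction
    graph. Downstream modules quantify dispersed repeats, MTPT content, open
    reading frames and GC, extract genus-specific sequences (GSS) from a
    multi-genome comparison set and attribute them against a labelled homology
    collection, screen for plasmid-like circles and mitovirus-like regions,
    and compute per-genome summary statistics. A truth-carrying simulator
    generates circular mitogenomes with planted repeats, MTPTs, horizontally
    transferred segments and fragmentation-with-coverage contig sets so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
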