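Package: paleomic
Title: Discriminating Fossil from Living Microorganisms in Ancient Permafrost Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and measurement toolkit for paleogenomics of microbial
    communities in perennially frozen sediment. Simulates post-mortem DNA
    taphonomy (fragmentation, cytosine deamination with 5'-overhang enrichment,
    blocking lesions), intracellular/extracellular DNA partitioning, in-vitro
    enzymatic repair and library sequencing with full ground truth; measures
    position-specific C-to-T mis-incorporation profiles from alignments, the
    effect of repair on windowed genome completeness, an aspartic-acid
    racemization clock (Arrhenius kinetics), and a peak-to-trough replication
    index; and integrates the per-genome evidence into living/fossil calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
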