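Package: polyevolve
Title: Simulation and Comparative-Genomics Analysis of Polyploid Genome Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whole-genome duplication (WGD) and allopolyploid
    genome evolution at gene-order resolution: a genome-evolution simulator
    (WGDs, chromosome fission/fusion/inversion, family-biased gene loss,
    synonymous-site sequence divergence, transposable-element bursts, and
    population resequencing with a truth ledger), synteny anchor chaining by
    sparse dynamic programming, Nei-Gojobori (NG86) Ka/Ks estimation, Ks peak
    mixture fitting and anchored molecular-clock dating, subgenome phasing by
    differential k-mers, TE divergence landscapes, homoeolog quartet retention
    and fractionation statistics, ancestral-karyotype painting with
    fission/fusion bookkeeping, and population diversity (variant filtering,
    nucleotide diversity, neighbor-joining trees, PCA, plastome comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mclust,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
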