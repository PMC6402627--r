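Package: oryzapop
Title: Population Genomics of Crop Domestication Bottlenecks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing domestication bottlenecks and geographic
    diversification from whole-genome SNP data, motivated by the population
    genomics of African rice (Oryza glaberrima) and its wild progenitor
    (Oryza barthii). Provides a coalescent generator of synthetic two-species
    data sets (selfing wild progenitor, bottlenecked and re-expanded
    domesticate, stepping-stone geography, planted selective sweeps and a
    diverged outgroup) with a machine-readable truth log; VCF input/output and
    Ts:Tv-guided hard filtering; windowed nucleotide diversity, Watterson's
    theta and Tajima's D; outgroup polarization and the unfolded site
    frequency spectrum with its neutral expectation; an LD-based omega
    selective-sweep scan; LD pruning, PCA, Wright-form F_ST, KING-robust
    kinship and isolation-by-distance regression; and whole-genome plus
    gene-haplotype neighbour-joining trees with detection of segregating
    single-subpopulation haplotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    vcfR,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Coverage, Phylogenetics, Sequencing
RoxygenNote: 7.3.3
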