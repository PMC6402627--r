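# Small deterministic fixtures shared across test files.

# GenotypeData built directly from a code matrix (variants x samples)
toyGeno <- function(gt, pos = NULL, chrom = "chr1", ref = NULL, alt = NULL,
                    samples = NULL, annotations = NULL,
                    functional_class = NULL) {
    gt <- as.matrix(gt)
    nv <- nrow(gt)
    if (is.null(pos)) pos <- seq_len(nv) * 100L
    if (is.null(ref)) ref <- rep("A", nv)
    if (is.null(alt)) alt <- rep("G", nv)
    makeGenotypeData(gt, rep(chrom, length.out = nv), pos, ref, alt,
                     samples = samples, annotations = annotations,
                     functional_class = functional_class)
}

# neutral single-population configuration used by several calibration tests
neutralConfig <- function(seed, nDip = 10, genomeLength = 2e5, ne = 5e4,
                          blockBp = 25000) {
    simConfig(nWild = nDip, nDom = 0L, nWildDemes = 1L, selfingRate = 0,
              ne = ne, genomeLength = genomeLength, nChromosomes = 1L,
              missingnessRate = 0, outgroupDivergence = 0,
              blockBp = blockBp, seed = seed)
}

# a modest default-history simulation, cached per test file
defaultSim <- local({
    cache <- new.env()
    function(seed = 1) {
        key <- as.character(seed)
        if (is.null(cache[[key]]))
            cache[[key]] <- simulateHistory(
                simConfig(seed = seed, genomeLength = 2e5, nChromosomes = 1L))
        cache[[key]]
    }
})
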