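#' Default deme geography for the two-species generator
#'
#' One row per deme: a 1-D stepping-stone chain per species laid out along
#' the West African coast and inland range.  Wild demes mirror the OB-A..OB-D
#' clusters, domesticated demes the OG-I..OG-V clusters; chain order follows
#' geography so that migration neighbours are also geographic neighbours.
#'
#' @return `data.frame` with columns `deme`, `species`, `name`, `lat`, `lon`.
#' @export
defaultDemeGeography <- function() {
    data.frame(
        deme = 1:9,
        species = rep(c("wild", "dom"), c(4, 5)),
        name = c("OB-C", "OB-B", "OB-A", "OB-D",
                 "OG-I", "OG-III", "OG-II", "OG-V", "OG-IV"),
        lat  = c(13.5,  8.5, 14.0, 10.0, 15.5, 11.0,  8.0, 14.0,  6.5),
        lon  = c(-14.5, -10.0,  0.5,  5.0, -16.0, -13.0, -11.5, -5.0,  8.0),
        stringsAsFactors = FALSE)
}

#' Configuration of the synthetic two-species history
#'
#' Parameters of the coalescent generator: a selfing wild progenitor split
#' into stepping-stone demes, and a domesticate founded from one wild deme
#' through a severe bottleneck followed by exponential recovery.  Defaults
#' emulate the African rice system at desk scale: ancestral effective size
#' `ne = 1e5`, grass-like mutation rate `mu = 6.5e-9` per site per
#' generation, selfing rate 0.95 (inbreeding F = s/(2-s) ~ 0.90, matching
#' the species' ~5-9% observed heterozygosity), domestication ~3000
#' generations ago with the founding population reduced to 3% of `ne`,
#' 4 wild + 5 domesticated demes.
#'
#' @slot nWild,nDom diploid sample counts per species.
#' @slot nWildDemes,nDomDemes deme counts (stepping-stone chains).
#' @slot genomeLength,nChromosomes total genome size in bp and chromosome
#'   count (equal-sized chromosomes).
#' @slot ne ancestral diploid effective population size.
#' @slot mu per-site per-generation mutation rate.
#' @slot selfingRate probability of self-fertilisation in [0,1].
#' @slot bottleneckTime,bottleneckSeverity founding time of the domesticate
#'   in generations, and founding size as a fraction of `ne` (the default
#'   3e-4 of Ne = 1e5 is a founding stock of ~30 plants).
#' @slot bottleneckDuration length of the founding pinch in generations;
#'   all domesticate lineages pass through this single founding population.
#' @slot recoveredNe present-day domesticate effective size after the
#'   post-domestication expansion; the size history declines exponentially
#'   backward from `recoveredNe` to `bottleneckSeverity * ne` at the
#'   founding time.
#' @slot sweeps list of planted hard sweeps, each
#'   `list(chrom=, pos=, s=, pop=)` with `pop` in `"dom"`/`"wild"`.
#' @slot outgroupDivergence expected substitutions per site on the outgroup
#'   branch.
#' @slot migrationWild,migrationDom per-generation stepping-stone migration
#'   rates between adjacent demes.
#' @slot wildSplitTime generations ago at which the wild demes merge into
#'   the panmictic ancestor.
#' @slot blockBp size of the independent non-recombining blocks.
#' @slot missingnessRate per-genotype no-call probability.
#' @slot introgression list of planted local introgressions, each
#'   `list(chrom=, start=, end=, targetSubpop=, sourceSubpop=)`.
#' @slot demeCoords deme geography table, see [defaultDemeGeography()].
#' @slot seed integer RNG seed; a fixed seed gives byte-identical bundles.
#' @seealso [simConfig()], [simulateHistory()]
#' @export
setClass("SimConfig", representation(
    nWild = "integer", nDom = "integer",
    nWildDemes = "integer", nDomDemes = "integer",
    genomeLength = "numeric", nChromosomes = "integer",
    ne = "numeric", mu = "numeric", selfingRate = "numeric",
    bottleneckTime = "numeric", bottleneckSeverity = "numeric",
    bottleneckDuration = "numeric", recoveredNe = "numeric",
    sweeps = "list", outgroupDivergence = "numeric",
    migrationWild = "numeric", migrationDom = "numeric",
    wildSplitTime = "numeric", blockBp = "numeric",
    missingnessRate = "numeric", introgression = "list",
    demeCoords = "data.frame", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    inUnit <- function(x) all(x >= 0 & x <= 1)
    if (!inUnit(object@selfingRate)) msg <- c(msg, "selfingRate must be in [0,1]")
    if (!inUnit(object@bottleneckSeverity))
        msg <- c(msg, "bottleneckSeverity must be in [0,1]")
    if (!inUnit(object@missingnessRate))
        msg <- c(msg, "missingnessRate must be in [0,1]")
    if (!inUnit(c(object@migrationWild, object@migrationDom)))
        msg <- c(msg, "migration rates must be in [0,1]")
    if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
    if (object@genomeLength <= 0) msg <- c(msg, "genomeLength must be > 0")
    if (object@ne <= 0 || object@recoveredNe <= 0)
        msg <- c(msg, "effective sizes must be > 0")
    if (object@nWild < 1L || object@nDom < 0L)
        msg <- c(msg, "need at least one wild sample and nDom >= 0")
    if (nrow(object@demeCoords) < object@nWildDemes + object@nDomDemes)
        msg <- c(msg, "demeCoords must cover all demes")
    if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' See [SimConfig-class] for the meaning and defaults of every parameter.
#'
#' @param nWild,nDom diploid sample counts.
#' @param nWildDemes,nDomDemes deme counts.
#' @param genomeLength,nChromosomes genome size (bp) and chromosome count.
#' @param ne,mu,selfingRate ancestral size, mutation rate, selfing rate.
#' @param bottleneckTime,bottleneckSeverity domesticate founding time
#'   (generations) and founding fraction of `ne`.
#' @param bottleneckDuration founding-pinch duration in generations.
#' @param recoveredNe present-day (expanded) domesticate effective size.
#' @param sweeps,introgression planted selection / introgression events.
#' @param outgroupDivergence outgroup branch length (substitutions/site).
#' @param migrationWild,migrationDom stepping-stone migration rates.
#' @param wildSplitTime wild deme merge time (generations).
#' @param blockBp non-recombining block size (bp).
#' @param missingnessRate no-call rate.
#' @param demeCoords deme geography table.
#' @param seed integer seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nWild = 8, nDom = 10, genomeLength = 1e5, seed = 7)
#' @export
simConfig <- function(nWild = 40L, nDom = 50L,
                      nWildDemes = 4L, nDomDemes = 5L,
                      genomeLength = 5e5, nChromosomes = 2L,
                      ne = 1e5, mu = 6.5e-9, selfingRate = 0.95,
                      bottleneckTime = 3000, bottleneckSeverity = 3e-4,
                      bottleneckDuration = 100, recoveredNe = 2e6,
                      sweeps = list(), outgroupDivergence = 0.03,
                      migrationWild = 2.5e-6, migrationDom = 2e-3,
                      wildSplitTime = 5e4, blockBp = 25000,
                      missingnessRate = 0.02, introgression = list(),
                      demeCoords = defaultDemeGeography(), seed = 1L) {
    new("SimConfig",
        nWild = as.integer(nWild), nDom = as.integer(nDom),
        nWildDemes = as.integer(nWildDemes), nDomDemes = as.integer(nDomDemes),
        genomeLength = genomeLength, nChromosomes = as.integer(nChromosomes),
        ne = ne, mu = mu, selfingRate = selfingRate,
        bottleneckTime = bottleneckTime,
        bottleneckSeverity = bottleneckSeverity,
        bottleneckDuration = bottleneckDuration, recoveredNe = recoveredNe,
        sweeps = sweeps, outgroupDivergence = outgroupDivergence,
        migrationWild = migrationWild, migrationDom = migrationDom,
        wildSplitTime = wildSplitTime, blockBp = blockBp,
        missingnessRate = missingnessRate, introgression = introgression,
        demeCoords = demeCoords, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nWild, "wild +", object@nDom,
        "domesticated diploids\n")
    cat(sprintf("  genome %g bp on %d chromosome(s), Ne=%g, mu=%g, selfing %.2f\n",
                object@genomeLength, object@nChromosomes, object@ne,
                object@mu, object@selfingRate))
    cat(sprintf("  bottleneck: %.0f gens ago to %.1f%% of Ne; %d sweeps, %d introgressions; seed %d\n",
                object@bottleneckTime, 100 * object@bottleneckSeverity,
                length(object@sweeps), length(object@introgression),
                object@seed))
})
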