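#' Simulate a two-species domestication data set
#'
#' Runs the structured-coalescent generator described by a [SimConfig-class]:
#' a selfing wild progenitor subdivided into stepping-stone demes and a
#' domesticate founded from one wild deme through a severe bottleneck with
#' exponential recovery.  Chromosomes are composed of independent
#' non-recombining blocks; mutations are dropped on each block genealogy
#' under the infinite-sites model.  Hard sweeps are imposed post hoc by
#' resampling the beneficial haplotype to near-fixation in the target
#' population and homogenizing linked variation inside a decay window; local
#' introgression copies gene-region haplotypes from a donor deme into a
#' single recipient subpopulation.
#'
#' @param config a [SimConfig-class] object.
#' @return A list with elements
#'   \describe{
#'     \item{geno}{[GenotypeData-class] with genotype codes, positions,
#'       alleles, call-quality annotations, functional classes and the
#'       per-sample table (species, subpop, lat, lon, coverage).}
#'     \item{samples}{the per-sample table as a `data.frame` (also in
#'       `colData(geno)`).}
#'     \item{truth}{machine-readable truth log: sweep positions, per-species
#'       theta, subpopulation labels, per-variant ancestral/derived alleles,
#'       the outgroup allele and whether it mutated on the outgroup branch,
#'       functional classes, the full phased haplotype matrix, and any
#'       planted introgression.}
#'     \item{features}{GFF-style gene table (one gene per sweep and per
#'       introgression plus evenly spaced filler genes).}
#'   }
#' @examples
#' sim <- simulateHistory(simConfig(nWild = 6, nDom = 8, genomeLength = 5e4,
#'                                  nChromosomes = 1L, seed = 3))
#' sim$geno
#' @export
simulateHistory <- function(config) {
    stopifnot(methods::is(config, "SimConfig"))
    methods::validObject(config)
    set.seed(config@seed)
    dem <- .buildDemography(config)
    nw <- config@nWild
    ndm <- config@nDom
    n <- nw + ndm
    wDeme <- sort(rep_len(seq_len(config@nWildDemes), nw))
    dDeme <- if (ndm > 0L)
        config@nWildDemes + sort(rep_len(seq_len(config@nDomDemes), ndm))
    else integer()
    sampleDeme <- c(wDeme, dDeme)
    geo <- config@demeCoords
    species <- geo$species[sampleDeme]
    subpop <- geo$name[sampleDeme]
    ids <- paste0(gsub("-", "", subpop), "_",
                  sprintf("%03d", stats::ave(seq_len(n), sampleDeme,
                                             FUN = seq_along)))

    # selfing: with probability F an individual's two haplotypes are the
    # same coalescent lineage (identical by descent)
    Fcoef <- config@selfingRate / (2 - config@selfingRate)
    selfed <- stats::runif(n) < Fcoef
    linOfHap <- integer(2L * n)
    demeOfLin <- integer(0)
    nlin <- 0L
    for (i in seq_len(n)) {
        nlin <- nlin + 1L
        demeOfLin[nlin] <- sampleDeme[i]
        linOfHap[2L * i - 1L] <- nlin
        if (selfed[i]) {
            linOfHap[2L * i] <- nlin
        } else {
            nlin <- nlin + 1L
            demeOfLin[nlin] <- sampleDeme[i]
            linOfHap[2L * i] <- nlin
        }
    }

    chromLen <- ceiling(config@genomeLength / config@nChromosomes)
    chroms <- paste0("chr", seq_len(config@nChromosomes))
    posL <- list(); chromL <- list(); hapL <- list()
    for (ci in seq_along(chroms)) {
        starts <- seq(1, chromLen, by = config@blockBp)
        cpos <- integer(0)
        cmat <- NULL
        for (bs in starts) {
            bw <- min(config@blockBp, chromLen - bs + 1)
            seg <- .simBlockSegments(demeOfLin, dem$epochs)
            if (!length(seg$len)) next
            totLen <- sum(seg$len)
            nmut <- stats::rpois(1L, dem$thetaSite / 2 * bw * totLen)
            nmut <- min(nmut, bw)          # infinite sites within the block
            if (nmut == 0L) next
            segIdx <- sample.int(length(seg$len), nmut, replace = TRUE,
                                 prob = seg$len)
            p <- bs - 1L + sample.int(bw, nmut)
            m <- matrix(0L, nmut, nlin)
            for (k in seq_len(nmut)) m[k, seg$leaves[[segIdx[k]]]] <- 1L
            cpos <- c(cpos, p)
            cmat <- rbind(cmat, m)
        }
        if (length(cpos)) {
            o <- order(cpos)
            posL[[ci]] <- cpos[o]
            hapL[[ci]] <- cmat[o, , drop = FALSE][, linOfHap, drop = FALSE]
        } else {
            posL[[ci]] <- integer(0)
            hapL[[ci]] <- matrix(0L, 0L, 2L * n)
        }
        chromL[[ci]] <- rep(chroms[ci], length(posL[[ci]]))
    }
    pos <- unlist(posL)
    chrom <- unlist(chromL)
    H <- do.call(rbind, hapL)           # derived-allele indicators, 2n cols
    nv <- length(pos)

    # planted hard sweeps: a fraction `freq` (default 1, a completed hard
    # sweep) of target individuals become carriers of the beneficial
    # haplotype inside the decay window.  Each flank escapes
    # homogenization independently per individual (recombinational escape),
    # which leaves strong LD within each flank but none across the sweep
    # centre — the footprint the omega statistic detects.
    sweepTruth <- data.frame(chrom = character(), pos = integer(),
                             pop = character(), stringsAsFactors = FALSE)
    for (sw in config@sweeps) {
        win <- if (!is.null(sw$window)) sw$window else 25000
        esc <- if (!is.null(sw$escape)) sw$escape else 0.15
        targInd <- which(species == if (identical(sw$pop, "wild")) "wild"
                         else "dom")
        regL <- which(chrom == sw$chrom & pos >= sw$pos - win & pos < sw$pos)
        regR <- which(chrom == sw$chrom & pos >= sw$pos &
                      pos <= sw$pos + win)
        reg <- c(regL, regR)
        if (!length(reg) || !length(targInd)) next
        focal <- reg[which.min(abs(pos[reg] - sw$pos))]
        targHaps <- as.vector(rbind(2L * targInd - 1L, 2L * targInd))
        carriers <- targHaps[H[focal, targHaps] == 1L]
        donor <- if (length(carriers)) carriers[1L] else targHaps[1L]
        frq <- if (!is.null(sw$freq)) sw$freq else 1.0
        nrec <- ceiling(frq * length(targInd))
        rec <- targInd[sample.int(length(targInd), nrec)]
        # per flank, survivors of the sweep are the beneficial haplotype or
        # a single early recombinant lineage (frequency `esc`)
        alt2 <- setdiff(targHaps, donor)
        hapL <- cbind(H[regL, donor],
                      H[regL, alt2[sample.int(length(alt2), 1L)]])
        hapR <- cbind(H[regR, donor],
                      H[regR, alt2[sample.int(length(alt2), 1L)]])
        for (i in rec) {
            if (length(regL)) {
                src <- 1L + (stats::runif(1L) < esc)
                H[regL, 2L * i - 1L] <- hapL[, src]
                H[regL, 2L * i] <- hapL[, src]
            }
            if (length(regR)) {
                src <- 1L + (stats::runif(1L) < esc)
                H[regR, 2L * i - 1L] <- hapR[, src]
                H[regR, 2L * i] <- hapR[, src]
            }
        }
        # the beneficial allele itself is carried by every selected individual
        H[focal, as.vector(rbind(2L * rec - 1L, 2L * rec))] <- 1L
        sweepTruth <- rbind(sweepTruth,
                            data.frame(chrom = sw$chrom, pos = sw$pos,
                                       pop = sw$pop, stringsAsFactors = FALSE))
    }

    # planted introgression: recipient individuals take both haplotypes in
    # the region from a random donor haplotype of the source subpopulation
    introTruth <- data.frame(chrom = character(), start = integer(),
                             end = integer(), target = character(),
                             source = character(), stringsAsFactors = FALSE)
    for (ig in config@introgression) {
        targInd <- which(subpop == ig$targetSubpop)
        srcInd <- which(subpop == ig$sourceSubpop)
        reg <- which(chrom == ig$chrom & pos >= ig$start & pos <= ig$end)
        if (!length(reg) || !length(targInd) || !length(srcInd)) next
        srcHaps <- as.vector(rbind(2L * srcInd - 1L, 2L * srcInd))
        donor <- srcHaps[sample.int(length(srcHaps), 1L)]
        for (i in targInd) {
            H[reg, 2L * i - 1L] <- H[reg, donor]
            H[reg, 2L * i] <- H[reg, donor]
        }
        introTruth <- rbind(introTruth,
                            data.frame(chrom = ig$chrom, start = ig$start,
                                       end = ig$end, target = ig$targetSubpop,
                                       source = ig$sourceSubpop,
                                       stringsAsFactors = FALSE))
    }

    # allele labels: the derived allele is the alternate with probability 1/2
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    derivedIsAlt <- stats::runif(nv) < 0.5
    ancestral <- ifelse(derivedIsAlt, ref, alt)
    derived <- ifelse(derivedIsAlt, alt, ref)

    dd <- H[, seq(1L, 2L * n, by = 2L), drop = FALSE] +
          H[, seq(2L, 2L * n, by = 2L), drop = FALSE]   # derived dosage
    gt <- dd
    if (nv) gt[!derivedIsAlt, ] <- 2L - gt[!derivedIsAlt, , drop = FALSE]
    storage.mode(gt) <- "integer"

    # outgroup allele: ancestral base, possibly substituted on the branch
    outMut <- stats::runif(nv) < config@outgroupDivergence
    outgroup <- ancestral
    if (any(outMut))
        outgroup[outMut] <- vapply(ancestral[outMut], function(b)
            sample(setdiff(bases, b), 1L), character(1))

    annotations <- data.frame(
        DP = pmax(1, round(stats::rnorm(nv, 10 * n, 2 * n))),
        QD = round(stats::rgamma(nv, shape = 8, rate = 0.4), 2),
        MQ = round(pmin(60, stats::rnorm(nv, 59, 1.5)), 2),
        MQRankSum = round(stats::rnorm(nv), 3),
        ReadPosRankSum = round(stats::rnorm(nv), 3),
        FS = round(stats::rexp(nv, rate = 0.5), 3))
    functionalClass <- sample(FUNCTIONAL_CLASSES, nv, replace = TRUE,
                              prob = c(0.70, 0.25, 0.05))

    # per-genotype missingness
    if (config@missingnessRate > 0 && nv) {
        mask <- matrix(stats::runif(nv * n) < config@missingnessRate, nv, n)
        gt[mask] <- NA_integer_
    }

    samples <- data.frame(
        id = ids, species = species, subpop = subpop,
        lat = round(geo$lat[sampleDeme] + stats::runif(n, -0.8, 0.8), 4),
        lon = round(geo$lon[sampleDeme] + stats::runif(n, -0.8, 0.8), 4),
        coverage = round(stats::rlnorm(n, log(12), 0.35), 1),
        stringsAsFactors = FALSE)
    rownames(samples) <- ids

    geno <- makeGenotypeData(gt, chrom, pos, ref, alt, samples = samples,
                             annotations = annotations,
                             functional_class = functionalClass)

    features <- .makeFeatures(config, chroms, chromLen, sweepTruth, introTruth)
    qmat <- .makeQMatrix(sampleDeme, geo, n)

    theta <- c(wild = dem$thetaSite,
               dom = if (ndm > 0L) 4 * (config@ne / config@nDomDemes) /
                         (1 + Fcoef) * config@mu else NA_real_)
    truth <- list(
        sweeps = sweepTruth,
        theta = theta,
        subpop = stats::setNames(subpop, ids),
        species = stats::setNames(species, ids),
        ancestral_allele = ancestral,
        derived_allele = derived,
        outgroup_allele = outgroup,
        outgroup_mutated = outMut,
        functional_class = functionalClass,
        chrom = chrom, pos = pos,
        haplotypes = H, selfed = selfed,
        qmatrix = qmat,
        introgression = introTruth)
    list(geno = geno, samples = samples, truth = truth, features = features)
}

# gene table: one gene centred on each sweep, one spanning each
# introgression, plus evenly spaced filler genes (width 3 kb)
.makeFeatures <- function(config, chroms, chromLen, sweepTruth, introTruth) {
    feats <- list()
    gid <- 0L
    add <- function(chrom, start, end) {
        gid <<- gid + 1L
        feats[[gid]] <<- data.frame(
            chrom = chrom, start = max(1L, as.integer(start)),
            end = as.integer(end), id = sprintf("GENE%03d", gid),
            stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(sweepTruth)))
        add(sweepTruth$chrom[k], sweepTruth$pos[k] - 1500L,
            sweepTruth$pos[k] + 1500L)
    for (k in seq_len(nrow(introTruth)))
        add(introTruth$chrom[k], introTruth$start[k], introTruth$end[k])
    nFill <- max(0L, 10L - gid)
    if (nFill > 0L) {
        per <- ceiling(nFill / length(chroms))
        for (ch in chroms) {
            at <- round(seq(0.15, 0.85, length.out = per) * chromLen)
            for (p in at) if (gid < 10L) add(ch, p - 1500L, p + 1500L)
        }
    }
    do.call(rbind, feats)
}

# ancestry fractions concentrated on the sample's own deme (Dirichlet)
.makeQMatrix <- function(sampleDeme, geo, n) {
    K <- max(sampleDeme)
    q <- matrix(0, n, K)
    for (i in seq_len(n)) {
        a <- rep(0.05, K)
        a[sampleDeme[i]] <- 8
        g <- stats::rgamma(K, shape = a)
        q[i, ] <- g / sum(g)
    }
    colnames(q) <- paste0("Q", seq_len(K))
    q
}

#' Map variants to an outgroup alignment with quality flags
#'
#' Emulates the whole-genome alignment step of outgroup polarization: each
#' variant receives the outgroup allele recorded in the truth log, plus
#' alignment-quality flags (not aligned to the outgroup; a gap within 5 bp
#' of the SNP; mapped to multiple outgroup regions) drawn independently with
#' the given fractions.  Unaligned positions carry no outgroup allele.
#'
#' @param truth truth log from [simulateHistory()].
#' @param unalignedFrac,gapFrac,multimapFrac flag probabilities; must sum to
#'   at most 1.
#' @param seed integer seed for the flag assignment.
#' @return `data.frame` with columns `chrom`, `pos`, `outgroup_allele`,
#'   `unaligned`, `gap5`, `multimap`.
#' @examples
#' sim <- simulateHistory(simConfig(nWild = 4, nDom = 4, genomeLength = 2e4,
#'                                  nChromosomes = 1L, seed = 2))
#' map <- makeOutgroupMap(sim$truth, 0.3, 0.1, 0.1, seed = 9)
#' @export
makeOutgroupMap <- function(truth, unalignedFrac = 0, gapFrac = 0,
                            multimapFrac = 0, seed = 1L) {
    fr <- c(unalignedFrac, gapFrac, multimapFrac)
    if (any(fr < 0) || sum(fr) > 1)
        stop("flag fractions must be nonnegative and sum to at most 1")
    nv <- length(truth$pos)
    set.seed(as.integer(seed))
    cls <- sample.int(4L, nv, replace = TRUE,
                      prob = c(fr, 1 - sum(fr)))
    map <- data.frame(
        chrom = truth$chrom, pos = truth$pos,
        outgroup_allele = ifelse(cls == 1L, NA_character_,
                                 truth$outgroup_allele),
        unaligned = cls == 1L, gap5 = cls == 2L, multimap = cls == 3L,
        stringsAsFactors = FALSE)
    map
}
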