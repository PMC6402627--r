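# literal per-site evaluation of the genotype-pair dissimilarity: alleles
# of each diploid are compared under both pairings and the better one taken
bruteGenomeDistance <- function(gx, gy) {
    alleles <- function(g) switch(as.character(g), `0` = c(0, 0),
                                  `1` = c(0, 1), `2` = c(1, 1))
    ok <- !is.na(gx) & !is.na(gy)
    terms <- mapply(function(a, b) {
        x <- alleles(a); y <- alleles(b)
        m1 <- (x[1] == y[1]) + (x[2] == y[2])
        m2 <- (x[1] == y[2]) + (x[2] == y[1])
        1 - max(m1, m2) / 2
    }, gx[ok], gy[ok])
    list(d = mean(terms), L = sum(ok))
}

test_that("genomic distance follows the genotype-pair formula", {
    expect_equal(genomeDistance(c(0L, 1L, 2L), c(0L, 1L, 2L))$d, 0)
    expect_equal(genomeDistance(c(0L, 0L), c(2L, 2L))$d, 1)
    expect_equal(genomeDistance(c(0L), c(1L))$d, 0.5)   # hom-ref vs het
    expect_error(genomeDistance(c(NA_integer_), c(1L)), "no sites")
    set.seed(9)
    for (k in 1:20) {
        gx <- sample(c(0:2, NA), 30, replace = TRUE)
        gy <- sample(c(0:2, NA), 30, replace = TRUE)
        if (!any(!is.na(gx) & !is.na(gy))) next
        got <- genomeDistance(gx, gy)
        want <- bruteGenomeDistance(gx, gy)
        expect_equal(got$d, want$d, tolerance = 1e-12)
        expect_equal(got$L, want$L)
    }
})

test_that("distance matrices are metrics on complete data", {
    set.seed(10)
    gt <- matrix(sample(0:2, 50 * 8, replace = TRUE), 50, 8)
    gd <- toyGeno(gt * 1L, samples = data.frame(row.names = paste0("s", 1:8)))
    dm <- genomeDistanceMatrix(gd)$d
    expect_equal(diag(dm), setNames(rep(0, 8), paste0("s", 1:8)))
    expect_equal(dm, t(dm))
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
        expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
    # per-pair loop oracle on a 6 x 50 fixture
    gd6 <- gd[, 1:6]
    dm6 <- genomeDistanceMatrix(gd6)
    for (i in 1:5) for (j in (i + 1):6) {
        want <- bruteGenomeDistance(gt[, i], gt[, j])
        expect_equal(unname(dm6$d[i, j]), want$d, tolerance = 1e-12)
        expect_equal(unname(dm6$L[i, j]), want$L)
    }
    # missing data changes L but keeps symmetry
    gtm <- gt; gtm[sample(length(gtm), 80)] <- NA
    dmm <- genomeDistanceMatrix(toyGeno(gtm * 1L))
    expect_equal(dmm$d, t(dmm$d))
    expect_true(any(dmm$L[upper.tri(dmm$L)] < 50))
})

test_that("neighbour joining recovers additive trees exactly", {
    # ((A:1,B:2):1,(C:3,D:4)) as pairwise path lengths
    d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    d["A", "B"] <- d["B", "A"] <- 3
    d["A", "C"] <- d["C", "A"] <- 5
    d["A", "D"] <- d["D", "A"] <- 6
    d["B", "C"] <- d["C", "B"] <- 6
    d["B", "D"] <- d["D", "B"] <- 7
    d["C", "D"] <- d["D", "C"] <- 7
    tr <- njTree(d)
    expect_equal(unname(as.matrix(stats::cophenetic(tr))[rownames(d),
                                                         colnames(d)]),
                 unname(d), tolerance = 1e-9)
    # 3 taxa: closed-form three-point solution
    d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
                 dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    tr3 <- njTree(d3)
    co3 <- as.matrix(stats::cophenetic(tr3))[c("x", "y", "z"),
                                             c("x", "y", "z")]
    expect_equal(unname(co3), unname(d3), tolerance = 1e-9)
    # star: equal distances give zero internal branches
    ds <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    diag(ds) <- 0
    trs <- njTree(ds)
    inner <- trs$edge[, 2] > length(trs$tip.label)
    expect_true(all(abs(trs$edge.length[inner]) < 1e-9))
    expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("Newick round-trips preserve trees", {
    p <- file.path(tempdir(), "t.nwk")
    writeNewickTree(ape::read.tree(text = "(A:1,B:1);"), p)
    expect_equal(readNewickTree(p)$tip.label, c("A", "B"))
    set.seed(12)
    tr <- ape::rtree(50)
    writeNewickTree(tr, p)
    back <- readNewickTree(p)
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE,
                                     tolerance = 1e-9))
    bad <- file.path(tempdir(), "bad.nwk")
    writeLines("(((", bad)
    expect_error(suppressWarnings(readNewickTree(bad)))
})

test_that("gene haplotypes follow the naive phasing rule", {
    gt <- rbind(c(0L, 2L, 1L),
                c(2L, 2L, 0L),
                c(0L, 0L, 1L))
    gd <- toyGeno(gt, pos = c(1000L, 2000L, 3000L),
                  ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                  samples = data.frame(row.names = c("u", "v", "w")))
    hp <- extractGeneHaplotypes(gd, data.frame(chrom = "chr1", start = 500,
                                               end = 3500, id = "G"),
                                flankBp = 0)
    expect_equal(sum(hp$groups$count), 6L)             # 2 x samples
    expect_equal(unname(hp$sequences["u_1"]), "AGG")
    expect_equal(unname(hp$sequences["u_2"]), "AGG")   # all hom: identical
    expect_equal(unname(hp$sequences["w_1"]), "ACG")   # het: ref to hap 1
    expect_equal(unname(hp$sequences["w_2"]), "TCA")
    # identical samples share a group; ranks by descending count
    gt2 <- matrix(0L, 2, 4)
    gd2 <- toyGeno(gt2, pos = c(100L, 200L))
    hp2 <- extractGeneHaplotypes(gd2, data.frame(chrom = "chr1", start = 1,
                                                 end = 300, id = "G2"),
                                 flankBp = 0)
    expect_equal(nrow(hp2$groups), 1L)
    expect_equal(hp2$groups$count, 8L)
    expect_warning(extractGeneHaplotypes(gd2, data.frame(chrom = "chr9",
                                                         start = 1, end = 2,
                                                         id = "GX")),
                   "no variants")
})

test_that("p-distance uses pairwise deletion", {
    expect_equal(pDistance(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
    expect_equal(pDistance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
    expect_equal(pDistance(c(a = "AA?A", b = "ATAA"))["a", "b"], 1 / 3)
    expect_error(pDistance(c(a = "??", b = "AA")), "zero comparable")
    # no missing data: p-distance equals Hamming / length
    set.seed(13)
    seqs <- vapply(1:5, function(i)
        paste(sample(c("A", "C"), 30, replace = TRUE), collapse = ""),
        character(1))
    names(seqs) <- paste0("s", 1:5)
    d <- pDistance(seqs)
    m <- do.call(rbind, strsplit(seqs, ""))
    for (i in 1:4) for (j in (i + 1):5)
        expect_equal(unname(d[i, j]), mean(m[i, ] != m[j, ]))
})

test_that("segregating haplotypes are flagged only for planted introgression", {
    cfg <- simConfig(seed = 5, genomeLength = 3e5, nChromosomes = 1L,
                     introgression = list(list(chrom = "chr1",
                                               start = 133000, end = 167000,
                                               targetSubpop = "OG-IV",
                                               sourceSubpop = "OB-D")))
    sim <- simulateHistory(cfg)
    gene <- data.frame(chrom = "chr1", start = 140000, end = 160000,
                       id = "GENEX")
    hp <- extractGeneHaplotypes(sim$geno, gene, flankBp = 5000)
    sm <- sampleInfo(sim$geno)
    subpop <- setNames(sm$subpop, sm$id)
    species <- setNames(sm$species, sm$id)
    geneTree <- pDistanceTree(hp$sequences)
    genomeTree <- njTree(genomeDistanceMatrix(sim$geno)$d)
    det <- detectSegregatingHaplotypes(geneTree, genomeTree, subpop,
                                       species, hp$groups)
    expect_true(any(det$flagged & grepl("OG-IV", det$subpops)))
    # rule (i): flagged groups have single-subpopulation domesticates
    for (k in which(det$flagged)) {
        mem <- sub("_[12]$", "", strsplit(det$members[k], ",")[[1]])
        domSub <- unique(subpop[mem[species[mem] == "dom"]])
        expect_equal(length(domSub), 1L)
    }
    # introgression-free control on a different gene: no flags
    gene2 <- data.frame(chrom = "chr1", start = 40000, end = 60000,
                        id = "GENEY")
    hp2 <- extractGeneHaplotypes(sim$geno, gene2, flankBp = 5000)
    det2 <- detectSegregatingHaplotypes(pDistanceTree(hp2$sequences),
                                        genomeTree, subpop, species,
                                        hp2$groups)
    expect_false(any(det2$flagged))
    badSub <- subpop; badSub[1] <- NA
    expect_error(detectSegregatingHaplotypes(geneTree, genomeTree, badSub,
                                             species, hp$groups),
                 "unlabeled")
})
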