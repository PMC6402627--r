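test_that("LD pruning keeps exactly one of duplicated SNPs and is idempotent", {
    set.seed(3)
    base <- matrix(sample(0:2, 40, replace = TRUE), 4, 10)
    gt <- rbind(base[1, ], base[1, ], base[2, ], base[3, ], base[4, ])
    gd <- toyGeno(gt)
    keep <- ldPrune(gd, 0.25, windowSnps = 5, stepSnps = 1)
    expect_equal(sum(keep %in% c(1, 2)), 1L)          # one duplicate retained
    # independent columns all retained
    ortho <- toyGeno(rbind(c(0, 2, 1, 2, 1, 0) * 1L,
                           c(1, 2, 2, 0, 1, 0) * 1L,
                           c(2, 2, 0, 1, 2, 0) * 1L))
    r2 <- suppressWarnings(cor(t(genotypes(ortho))))^2
    stopifnot(all(r2[upper.tri(r2)] < 0.25))
    expect_equal(ldPrune(ortho, 0.25, 3, 1), 1:3)
    # exhaustive verification on a 20-SNP fixture with an LD block
    set.seed(11)
    blk <- matrix(rep(sample(0:2, 12, replace = TRUE), 6), 6, 12,
                  byrow = TRUE) + matrix(rbinom(72, 1, 0.05), 6, 12)
    blk[blk > 2] <- 2
    noise <- matrix(sample(0:2, 14 * 12, replace = TRUE), 14, 12)
    gd20 <- toyGeno(rbind(blk, noise) * 1L)
    kept <- ldPrune(gd20, 0.25, windowSnps = 20, stepSnps = 5)
    g <- genotypes(gd20)[kept, , drop = FALSE]
    r2k <- suppressWarnings(cor(t(g)))^2
    expect_true(all(r2k[upper.tri(r2k)] <= 0.25 | is.na(r2k[upper.tri(r2k)])))
    expect_equal(ldPrune(gd20[kept, ], 0.25, 20, 5), seq_along(kept))
})

test_that("PCA separates duplicated clusters and matches an eigen oracle", {
    a <- rep(c(0L, 2L), c(25, 25))
    gt <- cbind(a, a, a, 2L - a, 2L - a, 2L - a)
    gd <- toyGeno(gt, samples = data.frame(row.names = paste0("s", 1:6)))
    pc <- pcaGenotypes(gd, k = 3)
    expect_lt(max(abs(pc$scores[1:3, 1] - pc$scores[1, 1])), 1e-8)
    expect_lt(max(abs(pc$scores[4:6, 1] - pc$scores[4, 1])), 1e-8)
    expect_true(sign(pc$scores[1, 1]) != sign(pc$scores[4, 1]))
    # orthogonality of scores
    cv <- crossprod(scale(pc$scores, center = TRUE, scale = FALSE))
    expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
    # variance explained equals eigenvalue ratios of the covariance matrix
    set.seed(5)
    X <- matrix(sample(0:2, 500, replace = TRUE), 50, 10)   # 50 var x 10 sam
    gdr <- toyGeno(X * 1L)
    pr <- pcaGenotypes(gdr, k = 5)
    ev <- eigen(cov(t(X)), symmetric = TRUE)$values
    expect_equal(pr$varExplained, (ev / sum(ev))[1:5], tolerance = 1e-8)
})

test_that("PC-geography correlation follows the closed-form t-test", {
    lat <- c(5, 8, 11, 3, 14, 9, 12, 6, 10, 7)
    lon <- rnorm(10)
    scores <- cbind(lat, rnorm(10))
    res <- pcGeoCorrelation(scores, data.frame(lat = lat, lon = lon))
    expect_equal(res$r_lat[1], 1)
    expect_equal(res$p_lat[1], 0)
    r <- cor(scores[, 2], lat)
    tv <- r * sqrt(8 / (1 - r^2))
    expect_equal(res$t_lat[2], tv, tolerance = 1e-12)
    expect_equal(res$p_lat[2], 2 * pt(-abs(tv), 8), tolerance = 1e-12)
    # orthogonal scores: r = 0, p = 1
    sc0 <- cbind(c(-1, 1, -1, 1), rep(1, 4) + c(-1, 1, -1, 1) * 0)
    res0 <- pcGeoCorrelation(cbind(c(-1, 1, 1, -1)),
                             data.frame(lat = c(1, 1, -1, -1),
                                        lon = c(0, 0, 0, 0)))
    expect_equal(res0$r_lat[1], 0)
    expect_equal(res0$p_lat[1], 1)
    expect_error(pcGeoCorrelation(cbind(1:2),
                                  data.frame(lat = 1:2, lon = 1:2)), ">= 3")
})

test_that("ancestry assignment uses a strict majority", {
    q <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
    colnames(q) <- c("K1", "K2")
    expect_equal(assignSubpops(q), c("K1", NA, "K2"))
    expect_error(assignSubpops(rbind(c(0.7, 0.7))), "sum to 1")
    sim <- defaultSim(2)
    qm <- sim$truth$qmatrix
    lab <- assignSubpops(qm)
    demeName <- defaultDemeGeography()$name
    truthLab <- sampleInfo(sim$geno)$subpop
    assigned <- !is.na(lab)
    expect_gt(mean(assigned), 0.9)
    expect_equal(demeName[as.integer(sub("Q", "", lab[assigned]))],
                 truthLab[assigned])
})

test_that("the printed variance form of FST matches hand arithmetic", {
    # two demes, frequencies 0.2 and 0.8, equal sizes
    mk <- function(p, n) {          # n diploids at alt frequency p, no hets
        c(rep(2L, round(p * n)), rep(0L, n - round(p * n)))
    }
    gt <- rbind(c(mk(0.2, 10), mk(0.8, 10)))
    gd <- toyGeno(gt, samples = data.frame(row.names = paste0("s", 1:20)))
    res <- fst(gd, 1:10, 11:20)
    expect_equal(res$weighted, 0.09 / 0.25, tolerance = 1e-12)
    # identical frequencies -> 0; fixed difference -> 1
    same <- toyGeno(rbind(c(mk(0.5, 10), mk(0.5, 10))))
    expect_equal(fst(same, 1:10, 11:20)$weighted, 0)
    fixd <- toyGeno(rbind(c(mk(0, 10), mk(1, 10))))
    expect_equal(fst(fixd, 1:10, 11:20)$weighted, 1)
    expect_equal(fst(fixd, 1:10, 11:20)$classification, "very great")
    expect_equal(fst(same, 1:10, 1:10)$weighted, 0)   # self-comparison
    expect_error(fst(same, integer(), 1:10), "empty")
    # Weir-Cockerham mode runs and agrees on sign
    wc <- fst(gd, 1:10, 11:20, method = "weir_cockerham")
    expect_true(wc$weighted > 0 && wc$weighted <= 1)
})

test_that("FST grows with divergence time", {
    meanFst <- function(split) mean(vapply(1:3, function(s) {
        cfg <- simConfig(seed = s + split, nWild = 20, nDom = 0,
                         nWildDemes = 2L, migrationWild = 0,
                         wildSplitTime = split, genomeLength = 1e5,
                         nChromosomes = 1L, missingnessRate = 0)
        sim <- simulateHistory(cfg)
        sm <- sampleInfo(sim$geno)
        fst(sim$geno, which(sm$subpop == sm$subpop[1]),
            which(sm$subpop != sm$subpop[1]))$weighted
    }, numeric(1)))
    expect_lt(meanFst(5e3), meanFst(8e4))
})

test_that("cline splits and balanced subsampling are deterministic", {
    sm <- data.frame(id = sprintf("s%02d", 1:40),
                     lat = rep(c(12, 10.9, 11, 9), 10),
                     lon = rep(c(-5, -7, -6, -3), 10),
                     subpop = rep(c("A", "B"), each = 20),
                     coverage = seq(40, 1))
    cb <- clineAndBalance(sm, nPerGroup = 15, seed = 4)
    expect_equal(cb$ns_group[1:4], c("north", "south", "north", "south"))
    expect_equal(cb$ew_group[1:4], c("east", "west", "east", "east"))
    expect_equal(sum(cb$selected[cb$subpop == "A"]), 15L)
    cb2 <- clineAndBalance(sm, nPerGroup = 15, seed = 4)
    expect_identical(cb$selected, cb2$selected)       # same seed, same draw
    hc <- clineAndBalance(sm, nPerGroup = 15, seed = 1,
                          preferHighCoverage = TRUE)
    expect_true(all(sm$coverage[hc$selected & sm$subpop == "A"] >=
                    sort(sm$coverage[sm$subpop == "A"],
                         decreasing = TRUE)[15]))
    expect_warning(clineAndBalance(sm[1:10, ], nPerGroup = 15), "smaller")
})

test_that("KING-robust kinship has its diagnostic fixed points", {
    g <- c(0L, 1L, 2L, 1L, 0L, NA)
    expect_equal(kingKinship(g, g), 0.5)
    # opposing homozygotes with hets elsewhere -> negative
    gi <- c(0L, 0L, 0L, 1L)
    gj <- c(2L, 2L, 2L, 1L)
    expect_lt(kingKinship(gi, gj), 0)
    expect_equal(kingKinship(gi, gj), kingKinship(gj, gi))
    expect_true(is.na(kingKinship(c(0L, 2L), c(2L, 0L))))  # no hets
    expect_error(kingKinship(c(NA_integer_), c(1L)), "shared")
})

test_that("Haversine distances obey spherical geometry", {
    expect_equal(haversineKm(10, 10, 10, 10), 0)
    expect_equal(haversineKm(0, 0, 0, 180), pi * 6378, tolerance = 1e-6)
    expect_equal(haversineKm(0, 0, 0, 1), pi / 180 * 6378, tolerance = 1e-6)
    set.seed(8)
    for (k in 1:20) {
        p <- matrix(c(runif(3, -90, 90), runif(3, -180, 180)), 3, 2)
        dab <- haversineKm(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
        dba <- haversineKm(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
        dac <- haversineKm(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
        dcb <- haversineKm(p[3, 1], p[3, 2], p[2, 1], p[2, 2])
        expect_equal(dab, dba, tolerance = 1e-9)
        expect_lte(dab, dac + dcb + 1e-9)
    }
    expect_error(haversineKm(95, 0, 0, 0), "out of range")
})

test_that("IBD regression excludes distance outliers by the IQR rule", {
    km <- c(seq(10, 100, by = 10), 5000)
    phi <- 0.3 - 0.001 * km
    pairs <- data.frame(i = "a", j = "b", phi = phi, km = km)
    res <- ibdRegression(pairs)
    expect_equal(res$excluded, 1L)
    expect_equal(res$slope, -0.001, tolerance = 1e-12)
    expect_equal(res$r, -1, tolerance = 1e-12)
    same <- data.frame(phi = c(0.1, 0.2, 0.3), km = c(5, 5, 5))
    expect_true(is.na(ibdRegression(same)$slope))
})
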