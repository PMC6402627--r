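test_that("VCF writing and reading round-trips genotype codes", {
    sim <- defaultSim(1)
    path <- file.path(tempdir(), "rt.vcf")
    writeGenotypeVcf(sim$geno, path)
    back <- readGenotypeVcf(path)
    expect_identical(unname(genotypes(back)), unname(genotypes(sim$geno)))
    vi <- variantInfo(back)
    expect_identical(vi$pos, variantInfo(sim$geno)$pos)
    expect_identical(vi$functional_class,
                     variantInfo(sim$geno)$functional_class)
    # positions strictly increasing per chromosome
    for (ch in unique(vi$chrom))
        expect_false(is.unsorted(vi$pos[vi$chrom == ch], strictly = TRUE))
})

test_that("an empty matrix writes a valid header-only VCF", {
    gd <- makeGenotypeData(matrix(integer(), 0, 3), character(), integer(),
                           character(), character(),
                           samples = data.frame(row.names = c("a", "b", "c")))
    path <- file.path(tempdir(), "empty.vcf")
    writeGenotypeVcf(gd, path)
    ln <- readLines(path)
    expect_true(all(startsWith(ln, "#")))
    expect_match(ln[1], "VCFv4.2")
})

test_that("multi-allelic and non-SNP records are excluded with a count", {
    path <- file.path(tempdir(), "multi.vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
        "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
        "chr1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
        "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1"), path)
    expect_warning(gd <- readGenotypeVcf(path), "2 non-biallelic")
    expect_equal(nrow(genotypes(gd)), 1L)
    expect_equal(unname(genotypes(gd)[1, ]), c(0L, 1L, 2L))
    expect_equal(S4Vectors::metadata(gd)$excluded, 2L)
})

test_that("substitutions are classified by purine/pyrimidine identity", {
    expect_equal(classifySubstitution("A", "G"), "transition")
    expect_equal(classifySubstitution("C", "T"), "transition")
    expect_equal(classifySubstitution("A", "T"), "transversion")
    expect_equal(classifySubstitution("G", "C"), "transversion")
    # {A->G, C->T, A->C, G->T}: 2 transitions / 2 transversions = 1.0
    cls <- classifySubstitution(c("A", "C", "A", "G"),
                                c("G", "T", "C", "T"))
    expect_equal(sum(cls == "transition") / sum(cls == "transversion"), 1.0)
    expect_error(classifySubstitution("A", "N"), "A/C/G/T")
    expect_error(classifySubstitution("A", "A"), "differ")
})

test_that("Ts:Tv profile partitions annotated variants", {
    gd <- toyGeno(matrix(1L, 4, 3),
                  ref = c("A", "C", "T", "A"),
                  alt = c("G", "T", "C", "T"),   # 3 transitions, 1 transversion
                  annotations = data.frame(QD = c(10, 11, 12, 13)))
    prof <- tstvProfile(gd, "QD", nBins = 1L)
    expect_equal(nrow(prof), 1L)
    expect_equal(prof$n_snps, 4L)
    expect_equal(prof$tstv, 3.0)

    gd2 <- toyGeno(matrix(1L, 4, 3),
                   ref = c("A", "A", "A", "A"), alt = rep("G", 4),
                   annotations = data.frame(QD = c(1, 2, 3, NA)))
    prof2 <- tstvProfile(gd2, "QD", nBins = 2L)
    expect_equal(sum(prof2$n_snps), 3L)            # annotated only
    expect_equal(attr(prof2, "n_unannotated"), 1L)
    expect_true(all(is.na(prof2$tstv)))            # no transversions
    expect_error(tstvProfile(gd2, "nonesuch"), "unknown annotation")
})

test_that("hard filters remove variants and account for every removal", {
    ann <- data.frame(DP = c(10, 10, 100, 10, 10, 10),
                      QD = c(20, 1, 20, 20, 20, 20),
                      MQ = c(59, 59, 59, 30, 59, 59),
                      MQRankSum = c(0, 0, 0, 0, -9, 0),
                      ReadPosRankSum = 0, FS = c(1, 1, 1, 1, 1, 80))
    gt <- matrix(1L, 6, 10)
    gt[5, ] <- c(rep(1L, 7), NA, NA, NA)   # 30% missing
    gd <- toyGeno(gt, annotations = ann)
    spec <- filterSpec(DP = c(0, 50), QD = c(2, Inf), MQ = c(40, Inf),
                       MQRankSum = c(-4, 4), ReadPosRankSum = c(-8, 8),
                       FS = c(-Inf, 60), maxMissing = 0.2)
    res <- applyFilters(gd, spec)
    # exhaustive row-by-row oracle
    keepOracle <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
    expect_equal(nrow(genotypes(res$geno)), sum(keepOracle))
    expect_equal(sum(res$removed) + nrow(genotypes(res$geno)), 6L)
    # first-failing-filter attribution: variant 5 fails MQRankSum before
    # missingness
    expect_equal(unname(res$removed["MQRankSum"]), 1L)
    expect_equal(unname(res$removed["missingness"]), 0L)

    again <- applyFilters(res$geno, spec)           # idempotent
    expect_equal(genotypes(again$geno), genotypes(res$geno))
    expect_equal(sum(again$removed), 0L)

    allPass <- applyFilters(gd, filterSpec(QD = c(-Inf, Inf),
                                           MQ = c(-Inf, Inf),
                                           MQRankSum = c(-Inf, Inf),
                                           ReadPosRankSum = c(-Inf, Inf),
                                           FS = c(-Inf, Inf), maxMissing = 1))
    expect_equal(nrow(genotypes(allPass$geno)), 6L)
})

test_that("missing-data filter uses the no-call fraction", {
    gt <- matrix(0L, 1, 10)
    gt[1, 1:3] <- NA                                # 0.3 > 0.2
    gd <- toyGeno(gt)
    res <- applyFilters(gd, filterSpec(maxMissing = 0.2))
    expect_equal(nrow(genotypes(res$geno)), 0L)
    expect_equal(unname(res$removed["missingness"]), 1L)
})

test_that("per-sample statistics follow the declared definitions", {
    gt <- cbind(s1 = c(0L, 1L, 2L, NA), s2 = c(NA, NA, NA, NA))
    gd <- toyGeno(gt, samples = data.frame(row.names = c("s1", "s2")))
    st <- sampleStats(gd, depths = c(3.9, 10))
    expect_equal(st$call_rate, c(0.75, 0))
    expect_equal(st$heterozygosity[1], 1 / 3)
    expect_true(is.na(st$heterozygosity[2]))
    expect_equal(st$low_coverage, c(TRUE, FALSE))   # strict < 4
    st2 <- sampleStats(gd, depths = c(4, 4))
    expect_false(any(st2$low_coverage))
})
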