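#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

GT_CODES <- c(0L, 1L, 2L)
ANNOTATION_KEYS <- c("DP", "QD", "MQ", "MQRankSum", "ReadPosRankSum", "FS")
FUNCTIONAL_CLASSES <- c("noncoding", "synonymous", "nonsynonymous")

#' Container for biallelic SNP genotypes
#'
#' `GenotypeData` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' The single assay `"GT"` holds diploid genotype codes (variants in rows,
#' samples in columns): 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = no call.  `rowRanges()` carries one
#' width-1 range per variant with metadata columns `ref`, `alt`, the
#' call-quality annotations (`DP`, `QD`, `MQ`, `MQRankSum`, `ReadPosRankSum`,
#' `FS`) and `functional_class` (noncoding / synonymous / nonsynonymous).
#' `colData()` carries the per-accession sample table (`species`, `subpop`,
#' `lat`, `lon`, `coverage` where known).
#'
#' @seealso [makeGenotypeData()], [readGenotypeVcf()], [simulateHistory()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- character()
    if (!("GT" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'GT' is required")
    else {
        gt <- SummarizedExperiment::assay(object, "GT")
        if (!all(gt[!is.na(gt)] %in% GT_CODES))
            msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    mc <- S4Vectors::mcols(rr)
    if (!all(c("ref", "alt") %in% colnames(mc)))
        msg <- c(msg, "rowRanges must carry 'ref' and 'alt' metadata columns")
    else {
        ok <- mc$ref %in% c("A", "C", "G", "T") & mc$alt %in% c("A", "C", "G", "T")
        if (length(ok) && !all(ok))
            msg <- c(msg, "ref/alt must be single bases (biallelic SNPs)")
        if (length(ok) && any(mc$ref == mc$alt))
            msg <- c(msg, "ref and alt alleles must differ")
    }
    # positions non-decreasing within chromosome (strictly increasing after QC)
    if (length(rr) > 1L) {
        byc <- split(GenomicRanges::start(rr),
                     as.character(GenomicRanges::seqnames(rr)))
        if (any(vapply(byc, function(p) is.unsorted(p, strictly = FALSE),
                       logical(1))))
            msg <- c(msg, "positions must be sorted within chromosome")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param genotypes integer matrix of genotype codes, variants x samples.
#' @param chrom,pos,ref,alt per-variant chromosome, 1-based position and
#'   alleles.
#' @param samples `data.frame` or `DataFrame` of per-sample metadata, one row
#'   per column of `genotypes`; rownames (or column `id`) give sample ids.
#' @param annotations optional `data.frame` of per-variant INFO annotations
#'   (columns among `DP`, `QD`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `FS`).
#' @param functional_class optional per-variant functional label.
#' @return A [GenotypeData-class] object.
#' @examples
#' gd <- makeGenotypeData(matrix(c(0L, 1L, 2L), 1, 3), "chr1", 100L, "A", "G",
#'                        samples = data.frame(row.names = c("s1", "s2", "s3")))
#' genotypes(gd)
#' @export
makeGenotypeData <- function(genotypes, chrom, pos, ref, alt,
                             samples = NULL, annotations = NULL,
                             functional_class = NULL) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    nv <- nrow(genotypes)
    rr <- GRanges(seqnames = as.character(chrom),
                  ranges = IRanges(start = as.integer(pos), width = 1L))
    mcols(rr)$ref <- as.character(ref)
    mcols(rr)$alt <- as.character(alt)
    for (k in ANNOTATION_KEYS)
        mcols(rr)[[k]] <- if (!is.null(annotations) && k %in% colnames(annotations))
            as.numeric(annotations[[k]]) else rep(NA_real_, nv)
    mcols(rr)$functional_class <- if (is.null(functional_class))
        rep(NA_character_, nv) else as.character(functional_class)
    if (is.null(samples))
        samples <- data.frame(row.names = paste0("S", seq_len(ncol(genotypes))))
    samples <- as(samples, "DataFrame")
    if ("id" %in% colnames(samples) && is.null(rownames(samples)))
        rownames(samples) <- samples$id
    if (is.null(rownames(samples)))
        rownames(samples) <- paste0("S", seq_len(nrow(samples)))
    colnames(genotypes) <- rownames(samples)
    rownames(genotypes) <- NULL
    se <- SummarizedExperiment(assays = list(GT = genotypes),
                               rowRanges = rr, colData = samples)
    new("GenotypeData", se)
}

#' @describeIn makeGenotypeData The genotype code matrix (variants x samples).
#' @param x a `GenotypeData` object.
#' @export
genotypes <- function(x) SummarizedExperiment::assay(x, "GT")

#' @describeIn makeGenotypeData Per-variant table: chrom, pos, ref, alt,
#'   annotations and functional class, as a `data.frame`.
#' @export
variantInfo <- function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(S4Vectors::mcols(rr)))
}

#' @describeIn makeGenotypeData Per-sample metadata as a `data.frame` with an
#'   `id` column.
#' @export
sampleInfo <- function(x) {
    df <- as.data.frame(SummarizedExperiment::colData(x))
    cbind(id = rownames(df), df, stringsAsFactors = FALSE)
}

setMethod("show", "GenotypeData", function(object) {
    gt <- genotypes(object)
    cat("GenotypeData:", nrow(gt), "biallelic SNPs x", ncol(gt), "samples\n")
    chr <- table(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(object))))
    cat("  chromosomes:", paste0(names(chr), " (", chr, ")", collapse = ", "),
        "\n")
    miss <- mean(is.na(gt))
    cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
    sp <- SummarizedExperiment::colData(object)$species
    if (!is.null(sp))
        cat("  species:", paste(names(table(sp)), table(sp), collapse = ", "),
            "\n")
})

#' Subset variants of a GenotypeData object
#'
#' Convenience wrapper keeping class and metadata; standard `[` from
#' SummarizedExperiment also works.
#' @param x a `GenotypeData`.
#' @param i variant (row) index.
#' @param j sample (column) index.
#' @return A `GenotypeData`.
#' @export
subsetVariants <- function(x, i = NULL, j = NULL) {
    if (is.null(i)) i <- seq_len(nrow(x))
    if (is.null(j)) j <- seq_len(ncol(x))
    x[i, j]
}
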