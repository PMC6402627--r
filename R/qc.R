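#' Classify a substitution as transition or transversion
#'
#' Purine-purine (A<->G) and pyrimidine-pyrimidine (C<->T) changes are
#' transitions; all other base pairs are transversions.  Functional
#' constraint favours transitions, so the Ts:Tv ratio of a call set is used
#' as an enrichment proxy for true SNPs when tuning hard filters.
#'
#' @param ref,alt single bases in A/C/G/T (vectorized); `ref != alt`.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @examples
#' classifySubstitution("A", "G")  # transition
#' classifySubstitution("A", "T")  # transversion
#' @export
classifySubstitution <- function(ref, alt) {
    ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    if (!all(ok)) stop("alleles must be single bases in A/C/G/T")
    if (any(ref == alt)) stop("ref and alt must differ")
    ts <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
          (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
    ifelse(ts, "transition", "transversion")
}

#' Ts:Tv profile along the range of a call annotation
#'
#' Bins SNPs along the observed range of an INFO annotation and reports, for
#' each interval, the SNP count and the transition:transversion ratio.
#' Intervals with zero transversions report `NA` for the ratio; variants
#' lacking the annotation are excluded from the bins and counted separately.
#'
#' @param geno a [GenotypeData-class] object.
#' @param annotation one of `DP`, `QD`, `MQ`, `MQRankSum`,
#'   `ReadPosRankSum`, `FS`.
#' @param nBins number of equal-width bins over the observed range.
#' @return `data.frame` with `bin_low`, `bin_high`, `n_snps`, `tstv`; the
#'   count of unannotated variants is in `attr(, "n_unannotated")`.
#' @export
tstvProfile <- function(geno, annotation, nBins = 10L) {
    vi <- variantInfo(geno)
    if (!annotation %in% ANNOTATION_KEYS)
        stop("unknown annotation '", annotation, "'")
    v <- vi[[annotation]]
    has <- !is.na(v)
    isTs <- classifySubstitution(vi$ref, vi$alt) == "transition"
    if (!any(has)) stop("annotation '", annotation, "' absent for all variants")
    rng <- range(v[has])
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
    bin <- findInterval(v[has], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tsc <- tabulate(bin[isTs[has]], nbins = nBins)
    tvc <- tabulate(bin[!isTs[has]], nbins = nBins)
    out <- data.frame(bin_low = edges[-(nBins + 1L)], bin_high = edges[-1L],
                      n_snps = tsc + tvc,
                      tstv = ifelse(tvc > 0, tsc / tvc, NA_real_))
    attr(out, "n_unannotated") <- sum(!has)
    out
}

#' Hard-filter specification
#'
#' Keep-intervals per annotation plus a missing-data ceiling.  The two named
#' presets mirror a permissive ("full") and a stringent ("strict") call set;
#' their thresholds are starting points to be tuned with [tstvProfile()],
#' not asserted values.
#'
#' @param DP,QD,MQ,MQRankSum,ReadPosRankSum,FS length-2 numeric
#'   keep-intervals `c(lower, upper)` (closed; `-Inf`/`Inf` for open ends),
#'   or `NULL` to skip the annotation.
#' @param maxMissing maximum allowed fraction of no-calls per variant.
#' @param preset `"full"` or `"strict"` fills in default intervals which
#'   explicit arguments then override.
#' @return A list of class `"FilterSpec"`.
#' @export
filterSpec <- function(DP = NULL, QD = NULL, MQ = NULL, MQRankSum = NULL,
                       ReadPosRankSum = NULL, FS = NULL, maxMissing = NULL,
                       preset = c("full", "strict")) {
    preset <- match.arg(preset)
    base <- if (preset == "full")
        list(DP = NULL, QD = c(2, Inf), MQ = c(40, Inf),
             MQRankSum = c(-12.5, Inf), ReadPosRankSum = c(-8, Inf),
             FS = c(-Inf, 60), maxMissing = 0.5)
    else
        list(DP = NULL, QD = c(5, Inf), MQ = c(50, Inf),
             MQRankSum = c(-4, 4), ReadPosRankSum = c(-4, 4),
             FS = c(-Inf, 20), maxMissing = 0.2)
    args <- list(DP = DP, QD = QD, MQ = MQ, MQRankSum = MQRankSum,
                 ReadPosRankSum = ReadPosRankSum, FS = FS,
                 maxMissing = maxMissing)
    for (k in names(args)) if (!is.null(args[[k]])) base[[k]] <- args[[k]]
    for (k in ANNOTATION_KEYS) {
        iv <- base[[k]]
        if (!is.null(iv) && (length(iv) != 2L || iv[1] > iv[2]))
            stop("keep-interval for ", k, " must be c(lower, upper)")
    }
    structure(base, class = "FilterSpec")
}

#' Apply hard filters to a call set
#'
#' A variant is removed if any annotation falls outside its keep-interval
#' (annotations that are `NA` pass, as in a hard-filter pipeline) or if its
#' no-call fraction exceeds `maxMissing`.  Removal counts attribute each
#' removed variant to the first failing filter in the fixed order DP, QD,
#' MQ, MQRankSum, ReadPosRankSum, FS, missingness, so the counts plus the
#' survivors always partition the input.  The operation is idempotent.
#'
#' @param geno a [GenotypeData-class] object.
#' @param spec a [filterSpec()].
#' @return List with `geno` (filtered) and `removed` (named integer vector
#'   of per-filter removal counts).
#' @export
applyFilters <- function(geno, spec) {
    stopifnot(inherits(spec, "FilterSpec"))
    vi <- variantInfo(geno)
    gt <- genotypes(geno)
    nv <- nrow(gt)
    failedBy <- rep(NA_character_, nv)
    for (k in ANNOTATION_KEYS) {
        iv <- spec[[k]]
        if (is.null(iv)) next
        bad <- !is.na(vi[[k]]) & (vi[[k]] < iv[1] | vi[[k]] > iv[2])
        failedBy[is.na(failedBy) & bad] <- k
    }
    if (!is.null(spec$maxMissing) && nv) {
        missFrac <- rowMeans(is.na(gt))
        failedBy[is.na(failedBy) & missFrac > spec$maxMissing] <- "missingness"
    }
    keep <- is.na(failedBy)
    removed <- vapply(c(ANNOTATION_KEYS, "missingness"),
                      function(k) sum(failedBy == k, na.rm = TRUE), integer(1))
    list(geno = geno[keep, ], removed = removed)
}

#' Per-sample call statistics
#'
#' Computes, per accession, the call rate (called genotypes / total
#' variants), heterozygosity (heterozygous calls / called genotypes; `NA`
#' when nothing is called), optionally the mean site depth, and a low
#' coverage flag using a strict `<` threshold.
#'
#' @param geno a [GenotypeData-class] object.
#' @param depths optional numeric vector of mean sequencing depths aligned
#'   to the samples (defaults to the `coverage` column of the sample table).
#' @param minCoverage coverage threshold; samples with depth strictly below
#'   it are flagged.
#' @return `data.frame` with `id`, `call_rate`, `heterozygosity`, `depth`,
#'   `low_coverage`.
#' @export
sampleStats <- function(geno, depths = NULL, minCoverage = 4) {
    gt <- genotypes(geno)
    called <- colSums(!is.na(gt))
    het <- colSums(gt == 1L, na.rm = TRUE)
    if (is.null(depths))
        depths <- SummarizedExperiment::colData(geno)$coverage
    if (is.null(depths)) depths <- rep(NA_real_, ncol(gt))
    data.frame(id = colnames(gt),
               call_rate = if (nrow(gt)) called / nrow(gt) else
                   rep(0, ncol(gt)),
               heterozygosity = ifelse(called > 0, het / called, NA_real_),
               depth = depths,
               low_coverage = !is.na(depths) & depths < minCoverage,
               row.names = NULL, stringsAsFactors = FALSE)
}
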