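# Allele bookkeeping shared by the diversity statistics: haplotype counts
# from diploid codes are m = 2 * called samples, a heterozygote contributing
# one copy of each allele.
.alleleCounts <- function(gt) {
    gt <- if (is.matrix(gt)) gt else matrix(gt, nrow = 1L)
    list(alt = rowSums(gt, na.rm = TRUE),
         m = 2L * rowSums(!is.na(gt)))
}

#' Per-site nucleotide diversity
#'
#' Unbiased average pairwise difference at each site:
#' `pi = 2 x (1 - x) m / (m - 1)` where `x` is the alternate-allele
#' frequency among the `m` non-missing haplotypes.  Sites with fewer than
#' two called haplotypes return `NA`.
#'
#' @param gt genotype codes: a variants x samples matrix (or a single
#'   site's vector).
#' @return Numeric vector of per-site pi values.
#' @examples
#' perSitePi(c(0L, 0L, 1L, 1L))  # 4 haplotypes 0,0,1,1 at one... see tests
#' @export
perSitePi <- function(gt) {
    ac <- .alleleCounts(gt)
    x <- ifelse(ac$m > 0L, ac$alt / ac$m, NA_real_)
    ifelse(ac$m >= 2L, 2 * x * (1 - x) * ac$m / (ac$m - 1L), NA_real_)
}

#' Watterson's theta
#'
#' `theta_W = S / a1`, the expected number of segregating sites between two
#' sequences under the standard neutral model, with
#' `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S segregating-site count.
#' @param n haplotype (sequence) count, `n >= 2`.
#' @return `theta_W` (same units as `S`; divide by sequence length for a
#'   per-site value).
#' @export
wattersonTheta <- function(S, n) {
    if (n < 2L) stop("need at least two sequences")
    S / sum(1 / seq_len(n - 1L))
}

#' Constants of Tajima's (1989) D denominator
#'
#' @param n haplotype count, `n >= 2`.
#' @return Named list with `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @export
tajimaConstants <- function(n) {
    if (n < 2L) stop("need at least two sequences")
    i <- seq_len(n - 1L)
    a1 <- sum(1 / i)
    a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
         e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-difference estimator of theta
#' (the sum of per-site pi) and Watterson's `S / a1`:
#' `D = (pi_total - theta_W) / sqrt(e1 S + e2 S (S - 1))`.  Negative values
#' indicate an excess of rare variants (expansion, sweeps); positive values
#' an excess of intermediate frequencies (bottlenecks, structure).
#'
#' @param gt genotype code matrix (variants x samples) for the region.
#' @param n haplotype count used for the constants; defaults to
#'   `2 * ncol(gt)`.
#' @return `D`, or `NA` when no site segregates.
#' @export
tajimasD <- function(gt, n = 2L * ncol(gt)) {
    gt <- if (is.matrix(gt)) gt else matrix(gt, nrow = 1L)
    ac <- .alleleCounts(gt)
    seg <- ac$m >= 2L & ac$alt > 0L & ac$alt < ac$m
    S <- sum(seg)
    if (S == 0L) return(NA_real_)
    piTotal <- sum(perSitePi(gt[seg, , drop = FALSE]))
    k <- tajimaConstants(n)
    (piTotal - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Windowed scan of a diversity statistic
#'
#' Tiles each chromosome with windows anchored at position 1 (1-based
#' inclusive bounds; the terminal window is truncated and kept), and
#' computes the chosen statistic per window.  Per-length scaling uses the
#' window width, not the number of covered sites.
#'
#' @param geno a [GenotypeData-class] object.
#' @param statistic one of `"pi"` (per site), `"theta_w"` (per site),
#'   `"tajima_d"`, `"snp_density"` (segregating sites per kb).
#' @param windowBp,stepBp window width and step in bp
#'   (`windowBp >= stepBp >= 1`); equal values give a disjoint tiling.
#' @param chromLengths optional named vector of chromosome lengths; defaults
#'   to the last observed variant position per chromosome.
#' @return `data.frame` with `chrom`, `start`, `end`, `n_sites`, `value`.
#' @export
windowedScan <- function(geno, statistic = c("pi", "theta_w", "tajima_d",
                                             "snp_density"),
                         windowBp = 1e5, stepBp = windowBp,
                         chromLengths = NULL) {
    statistic <- match.arg(statistic)
    stopifnot(windowBp >= stepBp, stepBp >= 1)
    vi <- variantInfo(geno)
    gt <- genotypes(geno)
    nHap <- 2L * ncol(gt)
    chroms <- unique(vi$chrom)
    out <- list()
    for (ch in chroms) {
        len <- if (!is.null(chromLengths) && ch %in% names(chromLengths))
            chromLengths[[ch]] else max(vi$pos[vi$chrom == ch])
        starts <- seq(1, len, by = stepBp)
        starts <- starts[starts <= len]
        idxAll <- which(vi$chrom == ch)
        for (s in starts) {
            e <- min(s + windowBp - 1, len)
            idx <- idxAll[vi$pos[idxAll] >= s & vi$pos[idxAll] <= e]
            sub <- gt[idx, , drop = FALSE]
            ac <- .alleleCounts(sub)
            seg <- ac$m >= 2L & ac$alt > 0L & ac$alt < ac$m
            S <- sum(seg)
            width <- e - s + 1
            val <- switch(statistic,
                pi = sum(perSitePi(sub)[seg]) / width,
                theta_w = if (nHap >= 2L) wattersonTheta(S, nHap) / width
                          else NA_real_,
                tajima_d = if (S > 0L) tajimasD(sub, n = nHap) else NA_real_,
                snp_density = S / (width / 1000))
            out[[length(out) + 1L]] <-
                data.frame(chrom = ch, start = s, end = e, n_sites = S,
                           value = val, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Minor allele frequency spectrum
#'
#' Minor allele frequency is `min(x, 1 - x)` over non-missing haplotypes.
#' Monomorphic sites are removed first; the default bin edges isolate the
#' rare (`MAF < 0.01`) and intermediate (`0.01-0.05`) classes.
#'
#' @param geno a [GenotypeData-class] object (or genotype matrix).
#' @param edges increasing bin edges on (0, 0.5]; bins are left-open,
#'   right-closed.
#' @param population optional label stored on the result.
#' @return `data.frame` with `bin_low`, `bin_high`, `count`;
#'   `attr(, "total")` gives the polymorphic-site count.
#' @export
mafSpectrum <- function(geno, edges = c(0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4,
                                        0.5),
                        population = NA_character_) {
    gt <- if (methods::is(geno, "GenotypeData")) genotypes(geno) else geno
    ac <- .alleleCounts(gt)
    poly <- ac$m >= 2L & ac$alt > 0L & ac$alt < ac$m
    x <- ac$alt[poly] / ac$m[poly]
    maf <- pmin(x, 1 - x)
    bin <- cut(maf, edges, right = TRUE, include.lowest = FALSE)
    cnt <- as.integer(table(bin))
    out <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1L],
                      count = cnt)
    attr(out, "total") <- sum(poly)
    attr(out, "population") <- population
    out
}

#' Kruskal-Wallis comparison of two sets of windowed statistics
#'
#' Rank-based two-group comparison with tie correction; the p-value comes
#' from the chi-square approximation with one degree of freedom.  Fully
#' tied data return `H = 0`, `p = 1`.
#'
#' @param valuesA,valuesB numeric vectors (e.g. per-window pi of two
#'   species); `NA`s are dropped.
#' @return List with `H` and `p`.
#' @export
kruskalCompare <- function(valuesA, valuesB) {
    valuesA <- valuesA[!is.na(valuesA)]
    valuesB <- valuesB[!is.na(valuesB)]
    if (!length(valuesA) || !length(valuesB)) stop("both groups must be nonempty")
    if (length(unique(c(valuesA, valuesB))) == 1L)
        return(list(H = 0, p = 1))
    kt <- stats::kruskal.test(list(valuesA, valuesB))
    list(H = unname(kt$statistic), p = kt$p.value)
}

#' Relative nucleotide diversity between wild and cultivated windows
#'
#' Joins two windowed pi tables on window coordinates and reports the
#' per-window ratio `pi_w / pi_c` (windows with `pi_c = 0` are `NA`, not
#' infinite) and the genome-wide ratio of sums.
#'
#' @param wildWindows,cultivatedWindows results of
#'   [windowedScan()] with `statistic = "pi"` on the two populations.
#' @return List with `windows` (joined table plus `ratio`) and
#'   `genomeWide`.
#' @export
piRatio <- function(wildWindows, cultivatedWindows) {
    m <- merge(wildWindows, cultivatedWindows,
               by = c("chrom", "start", "end"),
               suffixes = c("_w", "_c"))
    totC <- sum(m$value_c, na.rm = TRUE)
    if (totC == 0) stop("cultivated diversity is zero genome-wide")
    m$ratio <- ifelse(!is.na(m$value_c) & m$value_c > 0,
                      m$value_w / m$value_c, NA_real_)
    list(windows = m,
         genomeWide = sum(m$value_w, na.rm = TRUE) / totC)
}
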