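DISCARD_LEVELS <- c("none", "unaligned", "gap5", "multimap",
                    "outgroup_mismatch")

#' Polarize SNPs against an outgroup
#'
#' Assigns ancestral/derived states from the outgroup allele.  A variant is
#' polarizable iff no alignment flag is set and the outgroup allele equals
#' the reference or the alternate; the outgroup allele is then taken as
#' ancestral and the other allele as derived.  Discard reasons (first
#' applicable of `unaligned`, `gap5`, `multimap`, `outgroup_mismatch`)
#' partition the input exactly.  Derived allele frequencies are computed per
#' group over non-missing haplotypes.
#'
#' @param geno a [GenotypeData-class] object.
#' @param map outgroup map table ([makeOutgroupMap()] format), covering the
#'   variants of `geno` by (chrom, pos).
#' @param groups factor/character vector of group labels per sample;
#'   defaults to the `species` column of the sample table, or one pooled
#'   group.
#' @return List with `variants` (per-variant table: alleles, ancestral,
#'   derived, `discard_reason`, `derived_freq_<group>` columns,
#'   `functional_class`) and `tally` (named counts over discard classes,
#'   summing to the variant count).
#' @export
polarize <- function(geno, map, groups = NULL) {
    vi <- variantInfo(geno)
    gt <- genotypes(geno)
    key <- paste(vi$chrom, vi$pos)
    mi <- match(key, paste(map$chrom, map$pos))
    if (anyNA(mi)) stop("outgroup map does not cover all variants")
    map <- map[mi, , drop = FALSE]
    reason <- rep("none", nrow(vi))
    mism <- !is.na(map$outgroup_allele) & map$outgroup_allele != vi$ref &
        map$outgroup_allele != vi$alt
    reason[mism] <- "outgroup_mismatch"
    reason[map$multimap] <- "multimap"
    reason[map$gap5] <- "gap5"
    reason[map$unaligned | is.na(map$outgroup_allele)] <- "unaligned"
    ancestral <- ifelse(reason == "none", map$outgroup_allele, NA_character_)
    derived <- ifelse(reason == "none",
                      ifelse(ancestral == vi$ref, vi$alt, vi$ref),
                      NA_character_)
    if (is.null(groups)) {
        sp <- SummarizedExperiment::colData(geno)$species
        groups <- if (is.null(sp)) rep("all", ncol(gt)) else as.character(sp)
    }
    out <- data.frame(chrom = vi$chrom, pos = vi$pos, ref = vi$ref,
                      alt = vi$alt, ancestral = ancestral, derived = derived,
                      discard_reason = factor(reason, DISCARD_LEVELS),
                      functional_class = vi$functional_class,
                      stringsAsFactors = FALSE)
    derIsAlt <- !is.na(derived) & derived == vi$alt
    for (g in unique(groups)) {
        sub <- gt[, groups == g, drop = FALSE]
        ac <- .alleleCounts(sub)
        altFreq <- ifelse(ac$m > 0L, ac$alt / ac$m, NA_real_)
        f <- ifelse(derIsAlt, altFreq, 1 - altFreq)
        f[reason != "none"] <- NA_real_
        out[[paste0("derived_freq_", g)]] <- f
    }
    tally <- table(out$discard_reason)
    list(variants = out, tally = stats::setNames(as.integer(tally),
                                                 names(tally)))
}

#' Unfolded (derived) allele frequency spectrum
#'
#' Bins polarizable variants by derived allele frequency in one group,
#' keeping only the requested functional classes (default synonymous and
#' noncoding, the putatively neutral fraction).  Fixed derived sites
#' (frequency 1) are retained.  In addition to the binned spectrum, the
#' paper-style report classes are attached: the (0.7, 1] interval and the
#' independent `> 0.95` and `> 0.99` thresholds, as counts and percentages
#' of the spectrum total.
#'
#' @param polarized result of [polarize()].
#' @param population group label (must match a `derived_freq_<group>`
#'   column).
#' @param classes functional classes to keep; `NULL` keeps all.
#' @param edges bin edges on `[0, 1]`; bins are left-open, right-closed.
#' @return `data.frame` with `bin_low`, `bin_high`, `count`;
#'   `attr(, "total")` and `attr(, "report")` carry the total and the
#'   report classes.
#' @export
dafSpectrum <- function(polarized, population,
                        classes = c("synonymous", "noncoding"),
                        edges = seq(0, 1, by = 0.1)) {
    v <- polarized$variants
    col <- paste0("derived_freq_", population)
    if (!col %in% colnames(v)) stop("no derived frequencies for group '",
                                    population, "'")
    keep <- v$discard_reason == "none" & !is.na(v[[col]]) & v[[col]] > 0
    if (!is.null(classes))
        keep <- keep & v$functional_class %in% classes
    f <- v[[col]][keep]
    bin <- cut(f, edges, right = TRUE, include.lowest = FALSE)
    out <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1L],
                      count = as.integer(table(bin)))
    total <- length(f)
    rep <- data.frame(
        class = c("(0.7,1]", ">0.95", ">0.99"),
        count = c(sum(f > 0.7), sum(f > 0.95), sum(f > 0.99)))
    rep$percent <- if (total > 0) 100 * rep$count / total else NA_real_
    attr(out, "total") <- total
    attr(out, "report") <- rep
    attr(out, "population") <- population
    out
}

#' Expected neutral site frequency spectrum
#'
#' Under the standard neutral model the expected count of sites at derived
#' copy number `i` (of `n` haplotypes) is `theta_W / i` with
#' `theta_W = S_total / a1`, so the expected counts sum to `S_total` by
#' construction.  Counts are binned by `i / n` on the same edges as the
#' observed spectrum.
#'
#' @param S_total total segregating sites.
#' @param n haplotype count.
#' @param edges bin edges on `[0, 1]`.
#' @return `data.frame` with `bin_low`, `bin_high`, `expected`;
#'   `attr(, "per_i")` holds the unbinned `theta / i` series.
#' @export
expectedNeutralSfs <- function(S_total, n, edges = seq(0, 1, by = 0.1)) {
    if (n < 2L) stop("need at least two haplotypes")
    i <- seq_len(n - 1L)
    thetaW <- wattersonTheta(S_total, n)
    ei <- thetaW / i
    bin <- cut(i / n, edges, right = TRUE, include.lowest = FALSE)
    out <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1L],
                      expected = as.numeric(tapply(ei, bin, sum,
                                                   default = 0)))
    attr(out, "per_i") <- ei
    out
}

#' ECDF comparison and two-sample KS test of binned spectra
#'
#' Builds empirical cumulative distributions over the shared bins and
#' reports the Kolmogorov-Smirnov statistic `max |ECDF_obs - ECDF_exp|`
#' with the asymptotic two-sample p-value using the effective size
#' `n1 n2 / (n1 + n2)`.
#'
#' @param observed spectrum with a `count` column.
#' @param expected spectrum with an `expected` (or `count`) column over the
#'   same bins.
#' @return List with `curve` (per-bin ECDFs and their difference), `ks`
#'   and `p`.
#' @export
ecdfKsCompare <- function(observed, expected) {
    o <- observed$count
    e <- if (!is.null(expected$expected)) expected$expected else
        expected$count
    if (length(o) != length(e)) stop("spectra must share the same bins")
    if (sum(o) == 0 || sum(e) == 0) stop("empty spectrum")
    Fo <- cumsum(o) / sum(o)
    Fe <- cumsum(e) / sum(e)
    ks <- max(abs(Fo - Fe))
    n1 <- sum(o); n2 <- sum(e)
    ne <- n1 * n2 / (n1 + n2)
    lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * ks
    if (lam < 1e-9) {
        p <- 1
    } else {
        j <- seq_len(100)
        p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))
        p <- min(max(p, 0), 1)
    }
    list(curve = data.frame(bin_high = observed$bin_high, ecdf_obs = Fo,
                            ecdf_exp = Fe, diff = Fo - Fe),
         ks = ks, p = p)
}

#' Excess of observed sites above the neutral expectation in a range
#'
#' Sums the positive part of (observed - expected) over the bins lying in
#' the given derived-frequency range and reports it as a percentage of the
#' total observed sites — the "percent of total SNPs above expectation"
#' summary of the far end of the unfolded spectrum.
#'
#' @param observed,expected spectra over the same bins.
#' @param range derived-frequency interval, default `c(0.7, 1)`.
#' @return Percentage (0-100).
#' @export
excessAboveExpectation <- function(observed, expected, range = c(0.7, 1)) {
    o <- observed$count
    e <- if (!is.null(expected$expected)) expected$expected else
        expected$count
    if (length(o) != length(e)) stop("spectra must share the same bins")
    inR <- observed$bin_low >= range[1] & observed$bin_high <= range[2] +
        1e-12
    tot <- sum(o)
    if (tot == 0) return(0)
    100 * sum(pmax(o[inR] - e[inR], 0)) / tot
}
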