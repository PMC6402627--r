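#' Linkage disequilibrium between two sites
#'
#' With phased haplotypes (0/1 vectors), computes the classical
#' `r^2 = D^2 / (p1 p2 q1 q2)` from haplotype frequencies, where `D` is the
#' deviation of the observed joint haplotype frequency from independence.
#' With unphased diploid codes, the genotype-correlation surrogate
#' `r^2 = cor(g_i, g_j)^2` is used.  The mode is recorded on the result.
#'
#' @param x,y allele/genotype vectors at the two sites (equal length; `NA`
#'   pairs dropped).
#' @param phased `TRUE` for 0/1 haplotype vectors.
#' @return List with `r2`, `D` (phased mode only), the four allele
#'   frequencies, and `mode`.
#' @export
rSquared <- function(x, y, phased = FALSE) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L) stop("need at least two shared called samples")
    if (phased) {
        p1 <- mean(x); q1 <- mean(y)
        if (p1 %in% c(0, 1) || q1 %in% c(0, 1))
            return(list(r2 = NA_real_, D = NA_real_, p1 = p1, p2 = 1 - p1,
                        q1 = q1, q2 = 1 - q1, mode = "haplotype"))
        D <- mean(x == 1 & y == 1) - p1 * q1
        list(r2 = D^2 / (p1 * (1 - p1) * q1 * (1 - q1)), D = D,
             p1 = p1, p2 = 1 - p1, q1 = q1, q2 = 1 - q1, mode = "haplotype")
    } else {
        if (stats::var(x) == 0 || stats::var(y) == 0)
            return(list(r2 = NA_real_, D = NA_real_, p1 = mean(x) / 2,
                        p2 = 1 - mean(x) / 2, q1 = mean(y) / 2,
                        q2 = 1 - mean(y) / 2, mode = "genotype"))
        list(r2 = stats::cor(x, y)^2, D = NA_real_, p1 = mean(x) / 2,
             p2 = 1 - mean(x) / 2, q1 = mean(y) / 2, q2 = 1 - mean(y) / 2,
             mode = "genotype")
    }
}

# pairwise r^2 matrix for a sites x samples (or sites x haplotypes) matrix;
# for 0/1 haplotypes the squared correlation equals D^2/(p1 p2 q1 q2)
.r2Matrix <- function(sub) {
    suppressWarnings(stats::cor(t(sub), use = "pairwise.complete.obs"))^2
}

#' Omega statistic at a fixed split
#'
#' Evaluates the LD contrast
#' `omega = [ (C(l,2)+C(W-l,2))^-1 (sum_L r2 + sum_R r2) ] /
#'          [ (l(W-l))^-1 sum_{LxR} r2 ]`
#' for sites 1..l against sites (l+1)..W of a pairwise `r^2` matrix.  A
#' sweep centred between the two groups leaves strong LD within each flank
#' but little across, inflating omega.  A zero cross-term makes the ratio
#' undefined; it is reported capped at `cap` (flagged via attribute
#' `capped`).
#'
#' @param r2 symmetric W x W matrix of pairwise `r^2` (diagonal ignored).
#' @param l split index, `1 <= l < W`; `W >= 3`.
#' @param cap ceiling for the undefined zero-cross-term case.
#' @return omega (numeric scalar).
#' @export
omegaAtSplit <- function(r2, l, cap = 1e6) {
    W <- nrow(r2)
    if (W < 3L) stop("need at least three sites")
    if (l < 1L || l >= W) stop("split must satisfy 1 <= l < W")
    iL <- seq_len(l)
    iR <- (l + 1L):W
    sumL <- if (l >= 2L) sum(r2[iL, iL][upper.tri(r2[iL, iL])], na.rm = TRUE)
            else 0
    sumR <- if (W - l >= 2L)
        sum(r2[iR, iR][upper.tri(r2[iR, iR])], na.rm = TRUE) else 0
    cross <- sum(r2[iL, iR], na.rm = TRUE)
    nPairs <- choose(l, 2) + choose(W - l, 2)
    if (nPairs == 0) stop("no within-group pairs at this split")
    num <- (sumL + sumR) / nPairs
    den <- cross / (l * (W - l))
    if (den == 0) {
        out <- cap
        attr(out, "capped") <- TRUE
        return(out)
    }
    out <- num / den
    attr(out, "capped") <- FALSE
    out
}

#' Grid scan of the omega statistic
#'
#' At every grid position, collects the nearest segregating sites inside the
#' assessment window, computes pairwise `r^2` (genotype-correlation mode by
#' default; exact haplotype `r^2` when a phased 0/1 haplotype matrix is
#' supplied), and maximizes omega over admissible splits (at least two
#' sites on each side).  Values are log10-transformed for reporting.
#'
#' @param geno a [GenotypeData-class] object.
#' @param gridBp grid spacing in bp; a spacing larger than the chromosome
#'   yields a single mid-chromosome evaluation.
#' @param maxWindowBp half-width of the assessment window around each grid
#'   position.
#' @param maxSites cap on the number of nearest sites used per position.
#' @param haplotypes optional variants x haplotypes 0/1 matrix aligned to
#'   the rows of `geno` (phased mode).
#' @param chromLengths optional named chromosome lengths.
#' @param cap omega ceiling for zero cross-terms.
#' @return `data.frame` with `chrom`, `pos`, `W`, `l`, `omega`,
#'   `log10_omega`, `capped`; `attr(, "mode")` records the LD mode.
#' @export
omegaScan <- function(geno, gridBp = 10000, maxWindowBp = 1e5,
                      maxSites = 200L, haplotypes = NULL,
                      chromLengths = NULL, cap = 1e6) {
    vi <- variantInfo(geno)
    gt <- if (is.null(haplotypes)) genotypes(geno) else haplotypes
    ac <- .alleleCounts(genotypes(geno))
    seg <- ac$m >= 2L & ac$alt > 0L & ac$alt < ac$m
    out <- list()
    for (ch in unique(vi$chrom)) {
        idx <- which(vi$chrom == ch & seg)
        pos <- vi$pos[idx]
        len <- if (!is.null(chromLengths) && ch %in% names(chromLengths))
            chromLengths[[ch]] else max(vi$pos[vi$chrom == ch])
        grid <- if (gridBp > len) round(len / 2) else
            seq(gridBp, len, by = gridBp)
        for (g in grid) {
            near <- which(abs(pos - g) <= maxWindowBp)
            if (length(near) > maxSites)
                near <- near[order(abs(pos[near] - g))[seq_len(maxSites)]]
            near <- near[order(pos[near])]
            W <- length(near)
            if (W < 4L) next
            sub <- gt[idx[near], , drop = FALSE]
            r2 <- .r2Matrix(sub)
            r2[is.na(r2)] <- 0
            diag(r2) <- 0
            # cumulative within-group sums over all splits:
            # swl[l] = pair sum among sites 1..l,
            # withinR[l] = pair sum among sites l..W
            swl <- numeric(W)
            for (l in 2:W) swl[l] <- swl[l - 1L] + sum(r2[l, seq_len(l - 1L)])
            total <- swl[W]
            withinR <- numeric(W + 1L)
            for (l in (W - 1L):1L)
                withinR[l] <- withinR[l + 1L] + sum(r2[l, (l + 1L):W])
            bestOmega <- -Inf; bestL <- NA_integer_; bestCapped <- FALSE
            for (l in 2:(W - 2L)) {
                sumL <- swl[l]
                sumR <- withinR[l + 1L]
                cross <- total - sumL - sumR
                num <- (sumL + sumR) / (choose(l, 2) + choose(W - l, 2))
                if (cross == 0) {
                    om <- cap; capped <- TRUE
                } else {
                    om <- num / (cross / (l * (W - l)))
                    capped <- FALSE
                }
                if (om > bestOmega) {
                    bestOmega <- om; bestL <- l; bestCapped <- capped
                }
            }
            out[[length(out) + 1L]] <- data.frame(
                chrom = ch, pos = g, W = W, l = bestL,
                omega = min(bestOmega, cap), log10_omega =
                    log10(max(min(bestOmega, cap), .Machine$double.xmin)),
                capped = bestCapped, stringsAsFactors = FALSE)
        }
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(chrom = character(), pos = numeric(), W = integer(),
                   l = integer(), omega = numeric(), log10_omega = numeric(),
                   capped = logical())
    attr(res, "mode") <- if (is.null(haplotypes)) "genotype" else "haplotype"
    res
}

#' Flag top-quantile outliers
#'
#' Flags grid points whose statistic reaches the empirical `1 - q` tail:
#' the threshold is the `ceiling(q n)`-th largest value and ties at the
#' threshold are all flagged, so 1000 points yield 5 flags (plus ties) at
#' the default top 0.5%.
#'
#' @param results `data.frame` with a `value` column named by `column`.
#' @param quantile tail fraction, default `0.005`.
#' @param column column to rank, default `"omega"`.
#' @return `results` with a logical `outlier` column added.
#' @export
callOutliers <- function(results, quantile = 0.005, column = "omega") {
    if (!nrow(results)) stop("no results to flag")
    v <- results[[column]]
    k <- max(1L, ceiling(quantile * length(v)))
    thr <- sort(v, decreasing = TRUE)[k]
    results$outlier <- v >= thr
    results
}

#' Features near sweep outliers carrying impactful variants
#'
#' Joins outlier grid positions to annotated features: a feature is
#' reported iff its interval lies strictly closer than `maxDistance` to an
#' outlier position (distance 0 when overlapping) and contains at least one
#' variant of a requested impact class.
#'
#' @param outliers `data.frame` with `chrom`, `pos` (typically the flagged
#'   rows of [callOutliers()]).
#' @param features gene table with `chrom`, `start`, `end`, `id`.
#' @param geno a [GenotypeData-class] supplying variant functional classes.
#' @param impactClasses classes counting as impactful, default
#'   `"nonsynonymous"`.
#' @param maxDistance strict upper bound on the edge distance in bp.
#' @return Join table: feature columns plus `outlier_pos`, `distance_bp`,
#'   `n_impact_variants`.
#' @export
featureProximity <- function(outliers, features, geno,
                             impactClasses = "nonsynonymous",
                             maxDistance = 25000) {
    vi <- variantInfo(geno)
    out <- list()
    for (k in seq_len(nrow(features))) {
        f <- features[k, ]
        nImp <- sum(vi$chrom == f$chrom & vi$pos >= f$start &
                    vi$pos <= f$end &
                    vi$functional_class %in% impactClasses)
        if (nImp == 0L) next
        op <- outliers$pos[outliers$chrom == f$chrom]
        if (!length(op)) next
        d <- ifelse(op >= f$start & op <= f$end, 0,
                    pmin(abs(op - f$start), abs(op - f$end)))
        hit <- which(d < maxDistance)
        for (h in hit)
            out[[length(out) + 1L]] <- data.frame(
                id = f$id, chrom = f$chrom, start = f$start, end = f$end,
                outlier_pos = op[h], distance_bp = d[h],
                n_impact_variants = nImp, stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else
        data.frame(id = character(), chrom = character(), start = integer(),
                   end = integer(), outlier_pos = numeric(),
                   distance_bp = numeric(), n_impact_variants = integer())
}

#' Align omega grid points with windowed neutrality statistics
#'
#' Matches every omega grid point to all (possibly overlapping) windows
#' covering its position; points not covered by any window get a single row
#' with missing window values.  Used to cross-check sweep outliers against
#' local depressions in pi and Tajima's D.
#'
#' @param omegaResults result of [omegaScan()] (optionally flagged).
#' @param piWindows,dWindows windowed tables from [windowedScan()].
#' @return Long-format `data.frame`: omega columns plus `win_start`,
#'   `win_end`, `pi`, `tajima_d`.
#' @export
neutralityCrossCheck <- function(omegaResults, piWindows, dWindows) {
    win <- merge(piWindows, dWindows, by = c("chrom", "start", "end"),
                 suffixes = c("_pi", "_d"))
    out <- list()
    for (k in seq_len(nrow(omegaResults))) {
        r <- omegaResults[k, ]
        cov <- win[win$chrom == r$chrom & win$start <= r$pos &
                   win$end >= r$pos, , drop = FALSE]
        if (!nrow(cov)) {
            out[[length(out) + 1L]] <-
                cbind(r, win_start = NA_real_, win_end = NA_real_,
                      pi = NA_real_, tajima_d = NA_real_, row.names = NULL)
        } else {
            for (j in seq_len(nrow(cov)))
                out[[length(out) + 1L]] <-
                    cbind(r, win_start = cov$start[j], win_end = cov$end[j],
                          pi = cov$value_pi[j], tajima_d = cov$value_d[j],
                          row.names = NULL)
        }
    }
    do.call(rbind, out)
}
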