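#' LD pruning in sliding SNP windows
#'
#' Greedy pruning as in the PLINK `--indep-pairwise` procedure: inside each
#' sliding window (in SNP units, per chromosome) every pair of retained
#' SNPs with `r^2` above the threshold loses its later member; windows
#' advance by the step.  The retained set is stable under re-application.
#'
#' @param geno a [GenotypeData-class] object.
#' @param r2Threshold prune pairs with `r^2` strictly above this, default
#'   0.25.
#' @param windowSnps,stepSnps window and step sizes in SNPs (default
#'   500 / 50).
#' @return Integer vector of retained variant indices (rows of `geno`).
#' @export
ldPrune <- function(geno, r2Threshold = 0.25, windowSnps = 500L,
                    stepSnps = 50L) {
    stopifnot(windowSnps >= stepSnps)
    vi <- variantInfo(geno)
    gt <- genotypes(geno)
    keep <- rep(TRUE, nrow(gt))
    # one windowed greedy pass over the currently retained SNPs;
    # iterated to a fixpoint so that re-application never prunes further
    pass <- function(keep) {
        for (ch in unique(vi$chrom)) {
            idx <- which(vi$chrom == ch & keep)
            if (length(idx) < 2L) next
            starts <- seq(1L, length(idx), by = stepSnps)
            for (ws in starts) {
                we <- min(ws + windowSnps - 1L, length(idx))
                win <- idx[ws:we]
                win <- win[keep[win]]
                if (length(win) < 2L) next
                r2 <- .r2Matrix(gt[win, , drop = FALSE])
                for (j in 2:length(win)) {
                    if (!keep[win[j]]) next
                    prev <- win[seq_len(j - 1L)]
                    prev <- prev[keep[prev]]
                    if (!length(prev)) next
                    r2j <- r2[match(prev, win), j]
                    if (any(!is.na(r2j) & r2j > r2Threshold))
                        keep[win[j]] <- FALSE
                }
                if (we == length(idx)) break
            }
        }
        keep
    }
    repeat {
        newKeep <- pass(keep)
        if (identical(newKeep, keep)) break
        keep <- newKeep
    }
    which(keep)
}

#' PCA of a genotype matrix
#'
#' Genotypes are centred per variant with missing values imputed to the
#' variant mean (a deterministic convention), then decomposed with
#' `prcomp`.  Sample scores are orthogonal by construction.
#'
#' @param geno a [GenotypeData-class] object.
#' @param k number of components to return (default 20, truncated to the
#'   available dimensions).
#' @return List with `scores` (samples x k), `sdev`, and `varExplained`
#'   (fraction of total variance per returned component).
#' @export
pcaGenotypes <- function(geno, k = 20L) {
    gt <- genotypes(geno)
    if (ncol(gt) < 2L || nrow(gt) < 2L) stop("need >= 2 samples and variants")
    X <- t(gt)
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- mu[j]
    k <- min(k, ncol(gt) - 1L, nrow(gt))
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    kk <- min(k, ncol(pc$x))
    list(scores = pc$x[, seq_len(kk), drop = FALSE],
         sdev = pc$sdev,
         varExplained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(kk)])
}

#' Correlation of principal components with geography
#'
#' Pearson correlation of each component's scores with latitude and
#' longitude, assessed by the two-sided t-test
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.  Samples
#' without coordinates are excluded.
#'
#' @param scores samples x PCs score matrix.
#' @param coords `data.frame` with `lat` and `lon` aligned to the rows of
#'   `scores`.
#' @return `data.frame` with one row per PC: `r_lat`, `t_lat`, `p_lat`,
#'   `r_lon`, `t_lon`, `p_lon`, `n`.
#' @export
pcGeoCorrelation <- function(scores, coords) {
    ok <- !is.na(coords$lat) & !is.na(coords$lon)
    if (sum(ok) < 3L) stop("need >= 3 geo-referenced samples")
    n <- sum(ok)
    one <- function(x, y) {
        r <- suppressWarnings(stats::cor(x, y))
        if (is.na(r) || abs(r) >= 1) {
            t <- if (is.na(r)) NA_real_ else sign(r) * Inf
            p <- if (is.na(r)) NA_real_ else 0
        } else {
            t <- r * sqrt((n - 2) / (1 - r^2))
            p <- 2 * stats::pt(-abs(t), n - 2)
        }
        c(r = r, t = t, p = p)
    }
    res <- t(vapply(seq_len(ncol(scores)), function(j) {
        a <- one(scores[ok, j], coords$lat[ok])
        b <- one(scores[ok, j], coords$lon[ok])
        c(a, b)
    }, numeric(6)))
    out <- data.frame(pc = seq_len(ncol(scores)), res, n = n)
    colnames(out) <- c("pc", "r_lat", "t_lat", "p_lat", "r_lon", "t_lon",
                       "p_lon", "n")
    out
}

#' Assign samples to subpopulations from ancestry fractions
#'
#' A sample is assigned to its largest ancestry component iff that
#' component's fraction strictly exceeds the threshold (default the
#' majority rule > 0.5); otherwise it is unassigned (`NA`).
#'
#' @param q samples x K ancestry-fraction matrix (rows sum to 1).
#' @param threshold majority threshold, strict `>`.
#' @return Character vector of component labels (column names of `q`) or
#'   `NA`.
#' @export
assignSubpops <- function(q, threshold = 0.5) {
    q <- as.matrix(q)
    if (any(q < -1e-9) || any(abs(rowSums(q) - 1) > 1e-6))
        stop("ancestry fractions must be nonnegative and rows must sum to 1")
    lab <- colnames(q)
    if (is.null(lab)) lab <- paste0("Q", seq_len(ncol(q)))
    best <- max.col(q, ties.method = "first")
    ifelse(q[cbind(seq_len(nrow(q)), best)] > threshold, lab[best],
           NA_character_)
}

FST_CLASSES <- function(f) {
    cut(f, c(-Inf, 0.05, 0.15, 0.25, Inf),
        labels = c("little", "moderate", "great", "very great"))
}

#' Fixation index between two groups
#'
#' Primary mode implements the Wright variance form
#' `F_ST = sigma^2_S / sigma^2_T = sigma^2_S / (p (1 - p))`, with
#' `sigma^2_S` the sample-size-weighted between-group variance of allele
#' frequencies and `p` the pooled frequency; the weighted genome-wide value
#' is the ratio of sums over sites.  `method = "weir_cockerham"` exposes
#' the full Weir & Cockerham (1984) theta estimator (ratio of sums of the
#' a and a+b+c variance components) for comparison.
#'
#' @param geno a [GenotypeData-class] object.
#' @param groupA,groupB sample ids (or column indices) of the two groups.
#' @param method `"wright"` (the variance form) or `"weir_cockerham"`.
#' @return List with `perSite` (per-usable-site values), `weighted`, and
#'   `classification` ("little" < 0.05, "moderate" 0.05-0.15, "great"
#'   0.15-0.25, "very great" > 0.25).
#' @export
fst <- function(geno, groupA, groupB,
                method = c("wright", "weir_cockerham")) {
    method <- match.arg(method)
    gt <- genotypes(geno)
    sel <- function(g) if (is.character(g)) match(g, colnames(gt)) else g
    ia <- sel(groupA); ib <- sel(groupB)
    if (!length(ia) || !length(ib) || anyNA(ia) || anyNA(ib))
        stop("empty or unknown group")
    ga <- gt[, ia, drop = FALSE]
    gb <- gt[, ib, drop = FALSE]
    aca <- .alleleCounts(ga); acb <- .alleleCounts(gb)
    ok <- aca$m >= 2L & acb$m >= 2L
    pa <- aca$alt[ok] / aca$m[ok]
    pb <- acb$alt[ok] / acb$m[ok]
    na <- aca$m[ok]; nb <- acb$m[ok]
    p <- (aca$alt[ok] + acb$alt[ok]) / (na + nb)
    if (method == "wright") {
        s2 <- (na * (pa - p)^2 + nb * (pb - p)^2) / (na + nb)
        sT <- p * (1 - p)
        use <- sT > 0
        per <- s2[use] / sT[use]
        weighted <- sum(s2[use]) / sum(sT[use])
    } else {
        # Weir & Cockerham (1984), two populations, sizes in individuals
        niA <- rowSums(!is.na(ga))[ok]
        niB <- rowSums(!is.na(gb))[ok]
        hA <- rowSums(ga == 1L, na.rm = TRUE)[ok] / niA
        hB <- rowSums(gb == 1L, na.rm = TRUE)[ok] / niB
        r <- 2
        nbar <- (niA + niB) / r
        nC <- (r * nbar - (niA^2 + niB^2) / (r * nbar)) / (r - 1)
        pbar <- (niA * pa + niB * pb) / (r * nbar)
        s2 <- (niA * (pa - pbar)^2 + niB * (pb - pbar)^2) / ((r - 1) * nbar)
        hbar <- (niA * hA + niB * hB) / (r * nbar)
        a <- nbar / nC * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
        b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
        cc <- hbar / 2
        use <- (a + b + cc) != 0 & pbar > 0 & pbar < 1
        per <- a[use] / (a + b + cc)[use]
        weighted <- sum(a[use]) / sum((a + b + cc)[use])
    }
    list(perSite = per, weighted = weighted,
         classification = as.character(FST_CLASSES(weighted)),
         method = method, nSites = sum(ok))
}

#' Geographic cline splits and balanced subsampling
#'
#' Splits geo-referenced samples at the 11°N latitude cline (arid north vs
#' tropical south) and the 6°W longitude cline (inland east vs coastal
#' west); samples exactly on a cline go to the north/east groups (declared
#' convention).  Within each level of `by`, a balanced subsample of
#' `nPerGroup` is drawn without replacement with the given seed — or, when
#' `preferHighCoverage` and a `coverage` column is present, the
#' `nPerGroup` highest-coverage samples are taken deterministically.
#' Groups smaller than `nPerGroup` are used whole with a warning.
#'
#' @param samples `data.frame` with `id`, `lat`, `lon` (and optionally
#'   `coverage`, and the `by` column).
#' @param latCline,lonCline cline positions in degrees (default 11°N,
#'   -6° = 6°W).
#' @param by column name used for balancing, default `"subpop"`; `NULL`
#'   skips subsampling.
#' @param nPerGroup balanced group size, default 15.
#' @param seed RNG seed for the uniform draw.
#' @param preferHighCoverage select by descending coverage instead of
#'   uniformly.
#' @return `samples` with added `ns_group`, `ew_group` and logical
#'   `selected` columns.
#' @export
clineAndBalance <- function(samples, latCline = 11, lonCline = -6,
                            by = "subpop", nPerGroup = 15L, seed = 1L,
                            preferHighCoverage = FALSE) {
    samples$ns_group <- ifelse(samples$lat >= latCline, "north", "south")
    samples$ew_group <- ifelse(samples$lon >= lonCline, "east", "west")
    samples$selected <- TRUE
    if (!is.null(by) && by %in% colnames(samples)) {
        set.seed(as.integer(seed))
        samples$selected <- FALSE
        for (g in unique(samples[[by]])) {
            idx <- which(samples[[by]] == g)
            if (length(idx) <= nPerGroup) {
                if (length(idx) < nPerGroup)
                    warning("group '", g, "' smaller than nPerGroup; using all")
                pick <- idx
            } else if (preferHighCoverage &&
                       "coverage" %in% colnames(samples)) {
                pick <- idx[order(-samples$coverage[idx],
                                  samples$id[idx])][seq_len(nPerGroup)]
            } else {
                pick <- idx[sample.int(length(idx), nPerGroup)]
            }
            samples$selected[pick] <- TRUE
        }
    }
    samples
}
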