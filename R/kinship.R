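#' KING-robust kinship coefficient for one pair
#'
#' Within-pair estimator robust to population structure:
#' `phi = (N_het,het - 2 N_opposing_hom) / (N_het(i) + N_het(j))`, with all
#' counts taken over sites called in both samples.  A sample compared with
#' itself gives exactly 0.5; unrelated samples from diverged populations go
#' negative.
#'
#' @param gi,gj genotype code vectors of the two samples.
#' @return `phi`, or `NA` when neither sample is heterozygous at a shared
#'   called site.
#' @export
kingKinship <- function(gi, gj) {
    ok <- !is.na(gi) & !is.na(gj)
    gi <- gi[ok]; gj <- gj[ok]
    if (!length(gi)) stop("no shared called sites")
    nHetHet <- sum(gi == 1L & gj == 1L)
    nOpp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
    den <- sum(gi == 1L) + sum(gj == 1L)
    if (den == 0L) return(NA_real_)
    (nHetHet - 2 * nOpp) / den
}

#' All-pairs KING-robust kinship matrix
#'
#' @param geno a [GenotypeData-class] object.
#' @return Symmetric samples x samples matrix of `phi` (diagonal 0.5 by
#'   construction).
#' @export
kinshipMatrix <- function(geno) {
    gt <- genotypes(geno)
    n <- ncol(gt)
    phi <- matrix(NA_real_, n, n, dimnames = list(colnames(gt),
                                                  colnames(gt)))
    for (i in seq_len(n)) {
        phi[i, i] <- kingKinship(gt[, i], gt[, i])
        if (i < n) for (j in (i + 1L):n) {
            phi[i, j] <- phi[j, i] <- kingKinship(gt[, i], gt[, j])
        }
    }
    phi
}

#' Haversine great-circle distance
#'
#' Shortest distance between two points on a spherical Earth of radius
#' 6,378 km (the convention used for the isolation-by-distance analysis).
#' Thin wrapper over `geosphere::distHaversine`.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @param radiusKm sphere radius in km, default 6378.
#' @return Distance(s) in km.
#' @examples
#' haversineKm(0, 0, 0, 1)    # ~111.3 km along the equator
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2, radiusKm = 6378) {
    if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
        stop("coordinates out of range")
    geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                             r = radiusKm)
}

#' Kinship-distance pairs for isolation-by-distance analysis
#'
#' Builds every unordered sample pair with its KING-robust kinship and the
#' Haversine distance between collection sites.
#'
#' @param geno a [GenotypeData-class] object whose sample table carries
#'   `lat`/`lon`.
#' @param ids optional subset of sample ids.
#' @param group optional label stored on each pair.
#' @return `data.frame` with `i`, `j`, `phi`, `km`, `group`.
#' @export
ibdPairs <- function(geno, ids = NULL, group = NA_character_) {
    sm <- sampleInfo(geno)
    if (is.null(ids)) ids <- sm$id
    sm <- sm[match(ids, sm$id), , drop = FALSE]
    gt <- genotypes(geno)[, match(ids, colnames(genotypes(geno))),
                          drop = FALSE]
    n <- length(ids)
    out <- vector("list", n * (n - 1L) / 2L)
    k <- 0L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        k <- k + 1L
        out[[k]] <- data.frame(
            i = ids[i], j = ids[j],
            phi = kingKinship(gt[, i], gt[, j]),
            km = haversineKm(sm$lat[i], sm$lon[i], sm$lat[j], sm$lon[j]),
            group = group, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Isolation-by-distance regression
#'
#' Excludes pairs whose geographic distance falls outside the 1.5 x IQR
#' fences (computed on distances only; a one-sided upper fence is available
#' for the "separated by more than X km" convention), then fits ordinary
#' least squares of kinship on distance and reports the Pearson
#' correlation.
#'
#' @param pairs `data.frame` from [ibdPairs()] (columns `phi`, `km`).
#' @param iqrMultiplier fence multiplier, default 1.5.
#' @param oneSided if `TRUE`, apply only the upper fence.
#' @return List with `slope` (per km), `intercept`, `r`, `excluded`, `n`.
#' @export
ibdRegression <- function(pairs, iqrMultiplier = 1.5, oneSided = FALSE) {
    ok <- !is.na(pairs$phi) & !is.na(pairs$km)
    pairs <- pairs[ok, , drop = FALSE]
    q <- stats::quantile(pairs$km, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    lo <- if (oneSided) -Inf else q[1] - iqrMultiplier * iqr
    hi <- q[2] + iqrMultiplier * iqr
    keep <- pairs$km >= lo & pairs$km <= hi
    excluded <- sum(!keep)
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) < 3L) stop("need >= 3 pairs after outlier exclusion")
    if (stats::var(pairs$km) == 0)
        return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                    excluded = excluded, n = nrow(pairs)))
    fit <- stats::lm(phi ~ km, data = pairs)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = stats::cor(pairs$km, pairs$phi),
         excluded = excluded, n = nrow(pairs))
}
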