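#' Genomic distance between two samples from genotype codes
#'
#' Per shared called site the dissimilarity is
#' `1 - max(delta(a,c)+delta(b,d), delta(a,d)+delta(b,c)) / 2` over the two
#' unordered diploid genotypes, which for biallelic codes reduces to
#' `|g_x - g_y| / 2` (0 for identical genotypes, 0.5 for hom vs het, 1 for
#' opposing homozygotes).  The distance is the mean over the `L` sites
#' called in both samples.
#'
#' @param gx,gy genotype code vectors.
#' @return List with `d` and `L`.
#' @export
genomeDistance <- function(gx, gy) {
    ok <- !is.na(gx) & !is.na(gy)
    L <- sum(ok)
    if (L == 0L) stop("no sites called in both samples")
    list(d = sum(abs(gx[ok] - gy[ok])) / (2 * L), L = L)
}

#' All-pairs genomic distance matrix
#'
#' @param geno a [GenotypeData-class] object with >= 3 samples.
#' @return List with `d` (symmetric distance matrix, zero diagonal) and
#'   `L` (per-pair compared-site counts).
#' @export
genomeDistanceMatrix <- function(geno) {
    gt <- genotypes(geno)
    n <- ncol(gt)
    if (n < 3L) stop("need >= 3 samples")
    ids <- colnames(gt)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    L <- matrix(0L, n, n, dimnames = list(ids, ids))
    diag(L) <- colSums(!is.na(gt))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        gd <- genomeDistance(gt[, i], gt[, j])
        d[i, j] <- d[j, i] <- gd$d
        L[i, j] <- L[j, i] <- gd$L
    }
    list(d = d, L = L)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (or the BioNJ variance-weighted variant) on
#' a symmetric distance matrix; additive distances are recovered exactly.
#' Negative branch-length estimates are clamped to zero and counted.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param method `"nj"` or `"bionj"`.
#' @return An unrooted `ape::phylo`; `attr(, "n_clamped")` counts clamped
#'   branches.
#' @export
njTree <- function(d, method = c("nj", "bionj")) {
    method <- match.arg(method)
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
    tr <- if (method == "nj") ape::nj(as.dist(d)) else ape::bionj(as.dist(d))
    neg <- tr$edge.length < 0
    tr$edge.length[neg] <- 0
    attr(tr, "n_clamped") <- sum(neg)
    tr
}

#' @rdname njTree
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @return `writeNewickTree` returns `path` invisibly; `readNewickTree`
#'   returns the parsed `phylo` (round-trip preserves topology, labels and
#'   lengths).
#' @export
writeNewickTree <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' @rdname njTree
#' @export
readNewickTree <- function(path) {
    tr <- ape::read.tree(path)
    if (is.null(tr)) stop("malformed Newick in ", path)
    tr
}

#' Extract gene haplotypes with flanking regions
#'
#' Collects the variant sites inside a gene interval extended by `flankBp`
#' on either side and builds two haplotype strings per sample with the
#' naive phasing rule: homozygous sites contribute their allele to both
#' haplotypes; at heterozygous sites haplotype 1 receives the reference and
#' haplotype 2 the alternate (fixed canonical order).  Missing genotypes
#' are imputed to the site's modal genotype first (`impute = FALSE` leaves
#' them as `?`).  Haplotypes are grouped by exact string match
#' and ranked by descending count (counts sum to two per sample).
#'
#' @param geno a [GenotypeData-class] object.
#' @param feature one-row `data.frame` with `chrom`, `start`, `end`, `id`.
#' @param flankBp flank width, default 5000.
#' @param impute impute missing genotypes to the site's modal code
#'   (default `TRUE`), as a phasing model would.
#' @return List with `sequences` (named character vector, two per sample,
#'   names `<id>_1`/`<id>_2`), `groups` (`data.frame`: `gene`,
#'   `haplotype`, `count`, `rank`, `members`, `subpops`), and `nSites`.
#'   Empty (with a warning) when the interval contains no variants.
#' @export
extractGeneHaplotypes <- function(geno, feature, flankBp = 5000,
                                  impute = TRUE) {
    vi <- variantInfo(geno)
    gt <- genotypes(geno)
    lo <- feature$start - flankBp
    hi <- feature$end + flankBp
    idx <- which(vi$chrom == feature$chrom & vi$pos >= lo & vi$pos <= hi)
    if (!length(idx)) {
        warning("no variants in interval of ", feature$id)
        return(list(sequences = character(), groups =
                    data.frame(gene = character(), haplotype = character(),
                               count = integer(), rank = integer(),
                               members = character(), subpops = character()),
                    nSites = 0L))
    }
    sub <- gt[idx, , drop = FALSE]
    if (impute && anyNA(sub)) {
        # population-aware: a missing call takes the modal genotype of the
        # sample's own subpopulation (global mode as fallback)
        sp <- SummarizedExperiment::colData(geno)$subpop
        if (is.null(sp)) sp <- rep("all", ncol(sub))
        for (k in which(rowSums(is.na(sub)) > 0L)) {
            glob <- which.max(tabulate(sub[k, ] + 1L, nbins = 3L)) - 1L
            for (j in which(is.na(sub[k, ]))) {
                same <- sub[k, sp == sp[j]]
                tab <- tabulate(same + 1L, nbins = 3L)
                sub[k, j] <- if (sum(tab)) which.max(tab) - 1L else glob
            }
        }
    }
    ref <- vi$ref[idx]; alt <- vi$alt[idx]
    ids <- colnames(gt)
    h1 <- h2 <- matrix("?", length(idx), length(ids))
    hom0 <- !is.na(sub) & sub == 0L
    hom2 <- !is.na(sub) & sub == 2L
    het <- !is.na(sub) & sub == 1L
    for (j in seq_along(ids)) {
        h1[hom0[, j], j] <- ref[hom0[, j]]
        h2[hom0[, j], j] <- ref[hom0[, j]]
        h1[hom2[, j], j] <- alt[hom2[, j]]
        h2[hom2[, j], j] <- alt[hom2[, j]]
        h1[het[, j], j] <- ref[het[, j]]
        h2[het[, j], j] <- alt[het[, j]]
    }
    seqs <- c(apply(h1, 2L, paste, collapse = ""),
              apply(h2, 2L, paste, collapse = ""))
    names(seqs) <- c(paste0(ids, "_1"), paste0(ids, "_2"))
    seqs <- seqs[order(names(seqs))]
    sampleOf <- sub("_[12]$", "", names(seqs))
    subpop <- SummarizedExperiment::colData(geno)$subpop
    if (is.null(subpop)) subpop <- rep(NA_character_, length(ids))
    names(subpop) <- ids
    grp <- split(seq_along(seqs), seqs)
    groups <- data.frame(
        gene = feature$id,
        haplotype = names(grp),
        count = lengths(grp),
        members = vapply(grp, function(g)
            paste(names(seqs)[g], collapse = ","), character(1)),
        subpops = vapply(grp, function(g) {
            sp <- sort(unique(subpop[sampleOf[g]]))
            paste(sp[!is.na(sp)], collapse = ",")
        }, character(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    groups <- groups[order(-groups$count, groups$haplotype), , drop = FALSE]
    groups$rank <- seq_len(nrow(groups))
    list(sequences = seqs, groups = groups, nSites = length(idx))
}

#' Pairwise p-distance with pairwise deletion
#'
#' Proportion of differing positions between two sequences, ignoring for
#' each pair the positions where either sequence is ambiguous/missing
#' (`?`, `N` or `-`).
#'
#' @param seqs named character vector of equal-length sequences.
#' @return Symmetric distance matrix; an error if any pair has zero
#'   comparable sites.
#' @export
pDistance <- function(seqs) {
    n <- length(seqs)
    m <- do.call(rbind, strsplit(seqs, ""))
    ambiguous <- m %in% c("?", "N", "-")
    dim(ambiguous) <- dim(m)
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ok <- !ambiguous[i, ] & !ambiguous[j, ]
        if (!any(ok)) stop("zero comparable sites for a pair")
        d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
    d
}

#' Gene tree from haplotype sequences
#'
#' Neighbour joining on the pairwise-deletion p-distance matrix; duplicate
#' haplotype strings are legitimate (distance zero).
#'
#' @param seqs named character vector of >= 3 sequences.
#' @return An unrooted `ape::phylo`.
#' @export
pDistanceTree <- function(seqs) {
    if (length(seqs) < 3L) stop("need >= 3 sequences")
    njTree(pDistance(seqs))
}

# Major clade of the domesticated leaves: the smallest bipartition side
# (over all tree edges) containing at least half of the domesticated
# leaves; first candidate wins ties.
.majorClade <- function(tree, isDom) {
    labs <- tree$tip.label
    domTot <- sum(isDom)
    parts <- ape::prop.part(tree)
    best <- seq_along(labs); bestSize <- length(labs) + 1L
    consider <- function(set) {
        if (sum(isDom[set]) >= 0.5 * domTot && length(set) < bestSize) {
            bestSize <<- length(set); best <<- set
        }
    }
    for (p in parts) {
        consider(p)
        consider(setdiff(seq_along(labs), p))
    }
    labs[best]
}

#' Detect segregating single-subpopulation haplotypes
#'
#' Formalizes the visual criterion for gene haplotypes that "escape" the
#' main domesticated clade: among the top-`topN` haplotype groups of a gene,
#' a group is flagged iff (i) all its domesticated members belong to one
#' subpopulation, (ii) none of its domesticated leaves lie inside the gene
#' tree's major domesticated clade (the bipartition side best separating
#' domesticated from wild leaves, max Youden index), and (iii) its nearest
#' wild neighbour in the gene tree belongs to a different wild
#' subpopulation than the wild sister group of the domesticates in the
#' genome tree (the wild subpopulation with smallest mean cophenetic
#' distance to the domesticated leaves).
#'
#' @param geneTree `phylo` over haplotype sequences (`<id>_1`/`<id>_2`
#'   leaves).
#' @param genomeTree `phylo` over sample ids.
#' @param subpop,species named character vectors per sample id.
#' @param groups haplotype group table from [extractGeneHaplotypes()].
#' @param topN number of most common haplotypes examined, default 5.
#' @return `groups` (top `topN`) with columns `flagged`,
#'   `nearest_wild_subpop` and `genome_sister_subpop` added.
#' @export
detectSegregatingHaplotypes <- function(geneTree, genomeTree, subpop,
                                        species, groups, topN = 5L) {
    sampleOfLeaf <- sub("_[12]$", "", geneTree$tip.label)
    if (anyNA(subpop[sampleOfLeaf]) || anyNA(species[sampleOfLeaf]))
        stop("unlabeled leaves in gene tree")
    isDomLeaf <- species[sampleOfLeaf] == "dom"
    major <- .majorClade(geneTree, isDomLeaf)
    coGene <- stats::cophenetic(geneTree)
    coGenome <- stats::cophenetic(genomeTree)
    domIds <- names(species)[species == "dom"]
    wildIds <- names(species)[species == "wild"]
    wp <- unique(subpop[wildIds])
    sisterMeans <- vapply(wp, function(p) {
        w <- intersect(wildIds[subpop[wildIds] == p], rownames(coGenome))
        mean(coGenome[w, intersect(domIds, colnames(coGenome)),
                      drop = FALSE])
    }, numeric(1))
    genomeSister <- wp[which.min(sisterMeans)]
    top <- groups[groups$rank <= topN, , drop = FALSE]
    wildLeaves <- geneTree$tip.label[!isDomLeaf]
    top$flagged <- FALSE
    top$nearest_wild_subpop <- NA_character_
    top$genome_sister_subpop <- genomeSister
    for (k in seq_len(nrow(top))) {
        mem <- strsplit(top$members[k], ",", fixed = TRUE)[[1L]]
        memSamples <- sub("_[12]$", "", mem)
        domMem <- mem[species[memSamples] == "dom"]
        if (!length(domMem)) next
        sp <- unique(subpop[sub("_[12]$", "", domMem)])
        if (length(sp) != 1L) next                       # rule (i)
        if (any(domMem %in% major)) next                 # rule (ii)
        outsideWild <- setdiff(wildLeaves, mem)
        if (!length(outsideWild)) next
        dmat <- coGene[mem, outsideWild, drop = FALSE]
        nearest <- outsideWild[which.min(apply(dmat, 2L, min))]
        nw <- subpop[sub("_[12]$", "", nearest)]
        top$nearest_wild_subpop[k] <- nw
        top$flagged[k] <- !identical(unname(nw), unname(genomeSister))  # rule (iii)
    }
    top
}
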