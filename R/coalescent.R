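# Event-driven structured coalescent over piecewise-constant epochs.
# Time is measured in units of 2 * N0_eff generations, where
# N0_eff = ne / (1 + F) and F = s / (2 - s) is the selfing inbreeding
# coefficient; selfing enters as an effective-size rescaling here and as
# within-individual haplotype identity when diploids are assembled.
#
# An epoch is list(t0, t1, size, lam, moves):
#   size  relative deme sizes (units of N0_eff; NA = deme inactive)
#   lam   per-lineage backward migration rate matrix lam[d, e] (may be NULL)
#   moves integer vector applied on entering the epoch: lineages in deme d
#         jump to deme moves[d] (NA = stay)

.simBlockSegments <- function(demeOfHap, epochs) {
    nh <- length(demeOfHap)
    ndeme <- length(epochs[[1L]]$size)
    deme <- as.integer(demeOfHap)
    birth <- numeric(nh)
    leaves <- as.list(seq_len(nh))
    active <- rep(TRUE, nh)
    segLeaves <- vector("list", 2L * nh)
    segLen <- numeric(2L * nh)
    nseg <- 0L
    t <- 0
    if (nh <= 1L) return(list(leaves = list(), len = numeric()))
    for (ep in epochs) {
        if (!is.null(ep$moves)) {
            for (i in which(active)) {
                mv <- ep$moves[deme[i]]
                if (!is.na(mv)) deme[i] <- mv
            }
        }
        t <- max(t, ep$t0)
        repeat {
            idx <- which(active)
            if (length(idx) <= 1L) break
            kd <- tabulate(deme[idx], nbins = ndeme)
            coalRate <- numeric(ndeme)
            ok <- kd >= 2L & !is.na(ep$size) & ep$size > 0
            coalRate[ok] <- kd[ok] * (kd[ok] - 1L) / 2 / ep$size[ok]
            migMat <- NULL
            migRate <- 0
            if (!is.null(ep$lam)) {
                migMat <- kd * ep$lam
                migRate <- sum(migMat)
            }
            tot <- sum(coalRate) + migRate
            if (tot <= 0) { t <- ep$t1; break }
            dt <- stats::rexp(1L, tot)
            if (t + dt > ep$t1) { t <- ep$t1; break }
            t <- t + dt
            if (stats::runif(1L) * tot <= sum(coalRate)) {
                d <- sample.int(ndeme, 1L, prob = coalRate)
                v <- idx[deme[idx] == d]
                pair <- v[sample.int(length(v), 2L)]
                for (i in pair) {
                    nseg <- nseg + 1L
                    if (nseg > length(segLen)) {     # grow storage
                        segLeaves <- c(segLeaves, vector("list", nseg))
                        segLen <- c(segLen, numeric(nseg))
                    }
                    segLeaves[[nseg]] <- leaves[[i]]
                    segLen[nseg] <- t - birth[i]
                }
                a <- pair[1L]; b <- pair[2L]
                leaves[[a]] <- c(leaves[[a]], leaves[[b]])
                birth[a] <- t
                active[b] <- FALSE
            } else {
                pick <- sample.int(length(migMat), 1L, prob = as.numeric(migMat))
                d <- (pick - 1L) %% ndeme + 1L
                e <- (pick - 1L) %/% ndeme + 1L
                v <- idx[deme[idx] == d]
                deme[v[sample.int(length(v), 1L)]] <- e
            }
        }
        if (sum(active) <= 1L) break
    }
    list(leaves = segLeaves[seq_len(nseg)], len = segLen[seq_len(nseg)])
}

# Translate a SimConfig into the epoch list plus derived scales.
.buildDemography <- function(cfg) {
    Fcoef <- cfg@selfingRate / (2 - cfg@selfingRate)
    n0eff <- cfg@ne / (1 + Fcoef)
    T2 <- 2 * n0eff
    nw <- cfg@nWildDemes
    nd <- if (cfg@nDom > 0L) cfg@nDomDemes else 0L
    ndeme <- nw + nd
    tDom <- cfg@bottleneckTime / T2
    tWild <- max(cfg@wildSplitTime,
                 (cfg@bottleneckTime + cfg@bottleneckDuration) * 1.001) / T2
    stepLam <- function(idx, lam) {
        m <- matrix(0, ndeme, ndeme)
        if (length(idx) > 1L && lam > 0)
            for (k in seq_along(idx)) {
                if (k > 1L) m[idx[k], idx[k - 1L]] <- lam
                if (k < length(idx)) m[idx[k], idx[k + 1L]] <- lam
            }
        m
    }
    lamAll <- stepLam(seq_len(nw), 2 * n0eff * cfg@migrationWild)
    if (nd > 0L)
        lamAll <- lamAll + stepLam(nw + seq_len(nd), 2 * n0eff * cfg@migrationDom)
    sizeW <- rep(NA_real_, ndeme)
    sizeW[seq_len(nw)] <- 1 / nw
    founder <- 1L                     # domesticate founded from wild deme 1
    eps <- list()
    if (nd > 0L && tDom > 0) {
        ks <- 6L                      # exponential recovery, discretized
        bk <- seq(0, tDom, length.out = ks + 1L)
        szNow <- cfg@recoveredNe / cfg@ne           # relative present size
        szBot <- max(cfg@bottleneckSeverity, 1e-6)  # relative founding size
        r <- log(szNow / szBot) / tDom
        for (k in seq_len(ks)) {
            sz <- sizeW
            sz[nw + seq_len(nd)] <- (szNow / nd) *
                exp(-r * (bk[k] + bk[k + 1L]) / 2)
            eps[[length(eps) + 1L]] <-
                list(t0 = bk[k], t1 = bk[k + 1L], size = sz, lam = lamAll,
                     moves = NULL)
        }
        # founding pinch: every domesticate lineage passes through one
        # small founding population before joining the wild founder deme
        dB <- cfg@bottleneckDuration / T2
        pinch <- sizeW
        pinch[nw + 1L] <- max(cfg@bottleneckSeverity, 1e-6)
        mvP <- rep(NA_integer_, ndeme)
        mvP[nw + seq_len(nd)] <- nw + 1L
        lamW <- stepLam(seq_len(nw), 2 * n0eff * cfg@migrationWild)
        eps[[length(eps) + 1L]] <-
            list(t0 = tDom, t1 = tDom + dB, size = pinch, lam = lamW,
                 moves = mvP)
        mv <- rep(NA_integer_, ndeme)
        mv[nw + 1L] <- founder
        eps[[length(eps) + 1L]] <-
            list(t0 = tDom + dB, t1 = tWild, size = sizeW, lam = lamW,
                 moves = mv)
    } else {
        eps[[1L]] <- list(t0 = 0, t1 = tWild, size = sizeW, lam = lamAll,
                          moves = NULL)
    }
    mvA <- rep(1L, ndeme); mvA[1L] <- NA_integer_
    szA <- rep(NA_real_, ndeme); szA[1L] <- 1
    eps[[length(eps) + 1L]] <-
        list(t0 = tWild, t1 = Inf, size = szA, lam = NULL, moves = mvA)
    list(epochs = eps, n0eff = n0eff, T2 = T2,
         thetaSite = 4 * n0eff * cfg@mu, founder = founder,
         nWildDemes = nw, nDomDemes = nd)
}
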