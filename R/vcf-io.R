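#' Write a GenotypeData object as VCF 4.2
#'
#' Emits biallelic SNP records with GT genotypes and the call-quality
#' annotations (`DP`, `QD`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `FS`) plus
#' the functional class (`FC`) in INFO.  Positions are written 1-based per
#' the VCF standard.
#'
#' @param geno a [GenotypeData-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(geno, path) {
    gt <- genotypes(geno)
    vi <- variantInfo(geno)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##source=oryzapop",
        paste0("##INFO=<ID=", ANNOTATION_KEYS,
               ",Number=1,Type=Float,Description=\"", ANNOTATION_KEYS, "\">"),
        "##INFO=<ID=FC,Number=1,Type=String,Description=\"Functional class\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(gt)),
              collapse = "\t")), con)
    if (nrow(gt)) {
        code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
        gstr <- matrix("./.", nrow(gt), ncol(gt))
        ok <- !is.na(gt)
        gstr[ok] <- code[as.character(gt[ok])]
        fmtNum <- function(x) ifelse(is.na(x), NA, format(x, trim = TRUE,
                                                          scientific = FALSE))
        infoParts <- lapply(ANNOTATION_KEYS, function(k) {
            v <- vi[[k]]
            ifelse(is.na(v), NA_character_, paste0(k, "=", fmtNum(v)))
        })
        infoParts$FC <- ifelse(is.na(vi$functional_class), NA_character_,
                               paste0("FC=", vi$functional_class))
        info <- apply(do.call(cbind, infoParts), 1L, function(r)
            if (all(is.na(r))) "." else paste(r[!is.na(r)], collapse = ";"))
        lines <- paste(vi$chrom, vi$pos, ".", vi$ref, vi$alt, ".", "PASS",
                       info, "GT",
                       apply(gstr, 1L, paste, collapse = "\t"), sep = "\t")
        writeLines(lines, con)
    }
    invisible(path)
}

#' Read a VCF into a GenotypeData object
#'
#' Parses a VCF 4.x with vcfR.  Multi-allelic records and non-SNP records
#' (indels, symbolic alleles) are excluded with a counted warning.  INFO
#' annotations among `DP`, `QD`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `FS`
#' are parsed where present (absent values are `NA`), as is the functional
#' class key `FC`.
#'
#' @param path VCF file path.
#' @param samples optional per-sample metadata `data.frame` keyed by an `id`
#'   column, joined to the VCF sample columns.
#' @return A [GenotypeData-class] object; the number of excluded records is
#'   in `metadata(x)$excluded`.
#' @export
readGenotypeVcf <- function(path, samples = NULL) {
    v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    snp <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
        fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
    nExcluded <- sum(!snp)
    if (nExcluded > 0L)
        warning(nExcluded, " non-biallelic or non-SNP record(s) excluded")
    if (!any(snp)) {
        gd <- makeGenotypeData(matrix(integer(), 0L,
                                      ncol = ncol(v@gt) - 1L),
                               character(), integer(), character(),
                               character(),
                               samples = data.frame(row.names =
                                   colnames(v@gt)[-1L]))
        S4Vectors::metadata(gd)$excluded <- nExcluded
        return(gd)
    }
    v <- v[snp, ]
    fix <- fix[snp, , drop = FALSE]
    gtRaw <- vcfR::extract.gt(v)
    alt1 <- matrix(0L, nrow(gtRaw), ncol(gtRaw), dimnames = dimnames(gtRaw))
    a <- substr(gtRaw, 1L, 1L)
    b <- substr(gtRaw, 3L, 3L)
    code <- (a == "1") + (b == "1")
    code[a == "." | b == "." | is.na(gtRaw)] <- NA_integer_
    alt1[] <- code
    ann <- as.data.frame(lapply(ANNOTATION_KEYS, function(k)
        suppressWarnings(as.numeric(vcfR::extract.info(v, k)))))
    colnames(ann) <- ANNOTATION_KEYS
    fc <- vcfR::extract.info(v, "FC")
    meta <- if (!is.null(samples)) {
        m <- samples[match(colnames(gtRaw), samples$id), , drop = FALSE]
        rownames(m) <- colnames(gtRaw)
        m
    } else data.frame(row.names = colnames(gtRaw))
    gd <- makeGenotypeData(alt1, fix$CHROM, as.integer(fix$POS), fix$REF,
                           fix$ALT, samples = meta, annotations = ann,
                           functional_class = fc)
    S4Vectors::metadata(gd)$excluded <- nExcluded
    gd
}

#' Write a full synthetic bundle to disk
#'
#' Serializes a simulated data set as the plain-text files downstream
#' modules consume: `variants.vcf`, `samples.tsv`, `outgroup_map.tsv`,
#' `features.gff3`, `qmatrix.tsv` and `truth.json`.  Re-reading the VCF with
#' [readGenotypeVcf()] recovers the genotype codes exactly, and a fixed
#' simulation seed yields byte-identical files.
#'
#' @param sim result of [simulateHistory()].
#' @param outdir output directory (created if missing).
#' @param map outgroup map table from [makeOutgroupMap()]; by default an
#'   all-aligned map (no flags) derived from the truth log.
#' @return Named character vector of the written paths, invisibly.
#' @export
writeBundle <- function(sim, outdir, map = NULL) {
    if (!dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)
    if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
    if (is.null(map))
        map <- makeOutgroupMap(sim$truth, 0, 0, 0, seed = 1L)
    paths <- c(vcf = file.path(outdir, "variants.vcf"),
               samples = file.path(outdir, "samples.tsv"),
               map = file.path(outdir, "outgroup_map.tsv"),
               gff = file.path(outdir, "features.gff3"),
               q = file.path(outdir, "qmatrix.tsv"),
               truth = file.path(outdir, "truth.json"))
    writeGenotypeVcf(sim$geno, paths["vcf"])
    utils::write.table(sim$samples, paths["samples"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(map, paths["map"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ft <- sim$features
    gff <- c("##gff-version 3",
             if (!is.null(ft) && nrow(ft))
                 paste(ft$chrom, "oryzapop", "gene", ft$start, ft$end, ".",
                       "+", ".", paste0("ID=", ft$id), sep = "\t"))
    writeLines(gff, paths["gff"])
    q <- data.frame(id = sim$samples$id, sim$truth$qmatrix,
                    check.names = FALSE)
    utils::write.table(q, paths["q"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tr <- sim$truth
    jsonlite::write_json(list(
        sweeps = tr$sweeps, theta = as.list(tr$theta),
        subpop = as.list(tr$subpop), species = as.list(tr$species),
        variants = data.frame(chrom = tr$chrom, pos = tr$pos,
                              ancestral = tr$ancestral_allele,
                              derived = tr$derived_allele,
                              outgroup = tr$outgroup_allele,
                              functional_class = tr$functional_class,
                              stringsAsFactors = FALSE),
        introgression = tr$introgression),
        paths["truth"], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}

#' Read a features GFF3 into a gene table
#'
#' @param path GFF3 file with `gene` records carrying `ID=` attributes.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `id`.
#' @export
readFeaturesGff <- function(path) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    if (!length(ln))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), id = character()))
    f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
    data.frame(chrom = f[, 1L], start = as.integer(f[, 4L]),
               end = as.integer(f[, 5L]),
               id = sub("^ID=", "", sub(";.*$", "", f[, 9L])),
               stringsAsFactors = FALSE)
}
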