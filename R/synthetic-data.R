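#' Expected fully-overlapping reads per region
#'
#' The coverage-planning formula for single-read analyses: a read of length
#' `readLength` covers a whole region of size `regionSize` only if it starts
#' within the `readLength - regionSize` positions upstream of the region, so
#' `expected reads per region = coverage * (1 - regionSize / readLength)`.
#' Coverage here is per bisulfite strand, since a region can only use reads
#' of its own bisulfite strand.
#'
#' @param coverage mean per-strand sequencing depth.
#' @param regionSize region span in bp (<= `readLength`).
#' @param readLength read length in bp.
#' @return Expected number of fully-overlapping reads.
#' @examples
#' expectedReads(10, 30, 100)  # 7
#' @export
expectedReads <- function(coverage, regionSize, readLength) {
    stopifnot(regionSize <= readLength, coverage > 0)
    coverage * (1 - regionSize / readLength)
}

.randomBases <- function(n, gc) {
    sample(c("A", "T", "C", "G"), n, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.COMP <- c(A = "T", T = "A", C = "G", G = "C", N = "N")

## lightweight per-strand context-site scan on a character vector of bases;
## returns plus-strand C positions (the GRanges-based findContextSites path
## is authoritative; this is only used inside the generator's guarantee loop)
.sitePositionsChar <- function(bases, context) {
    w <- length(bases)
    if (w < 3L) return(integer(0))
    idx <- which(bases == "C")
    idx <- idx[idx <= w - 2L]
    if (!length(idx)) return(integer(0))
    b2 <- bases[idx + 1L]; b3 <- bases[idx + 2L]
    ok <- b2 != "N" & b3 != "N"
    keep <- switch(context,
        CHH = b2 != "G" & b3 != "G",
        CWA = b2 %in% c("A", "T") & b3 == "A",
        nonCWA = b2 != "G" & b3 != "G" & !(b2 %in% c("A", "T") & b3 == "A"),
        CH = b2 != "G",
        CG = b2 == "G",
        CHG = b2 != "G" & b3 == "G")
    idx[ok & keep]
}

#' Generate a synthetic genome with annotated elements
#'
#' Builds a random chromosome at a target GC content with non-overlapping
#' "TE" elements tiling a set fraction of its length, guaranteeing that every
#' element yields at least `minRegionsPerStrand` valid context regions on
#' each strand (element sequences are resampled until they do). The default
#' GC of 0.36 mimics an *A. thaliana*-like base composition.
#'
#' @param length chromosome length in bp (>= 1000).
#' @param gc target GC fraction.
#' @param seed integer seed.
#' @param teFraction fraction of the chromosome covered by elements.
#' @param elementLength element length in bp.
#' @param nSites,maxSpan,context region parameters used for the per-element
#'   region guarantee (defaults 5 CHH sites within 30 bp).
#' @param minRegionsPerStrand minimum regions per element per strand.
#' @return List with `genome` (`DNAStringSet`, one chromosome `chr1`) and
#'   `elements` (unstranded `GRanges` with `element_id`, `feature_class`).
#' @export
generateGenome <- function(length = 1e5L, gc = 0.36, seed = 1L,
                           teFraction = 0.4, elementLength = 500L,
                           nSites = 5L, maxSpan = 30L, context = "CHH",
                           minRegionsPerStrand = 1L) {
    stopifnot(length >= 1000L, gc > 0, gc < 1)
    set.seed(seed)
    bases <- .randomBases(length, gc)
    period <- round(elementLength / teFraction)
    starts <- seq(1L, length - elementLength, by = period)
    elements <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(starts, width = elementLength),
        strand = "*",
        element_id = sprintf("te%03d", seq_along(starts)),
        feature_class = "TE",
        seqlengths = c(chr1 = length))
    ## resample element sequences until each yields enough regions per strand
    for (i in seq_along(elements)) {
        span <- GenomicRanges::start(elements[i]):
            GenomicRanges::end(elements[i])
        for (try in seq_len(50L)) {
            elBases <- bases[span]
            nPlus <- length(.segmentPositions(
                .sitePositionsChar(elBases, context), nSites, maxSpan))
            nMinus <- length(.segmentPositions(
                .sitePositionsChar(rev(unname(.COMP[elBases])), context),
                nSites, maxSpan))
            if (nPlus >= minRegionsPerStrand &&
                nMinus >= minRegionsPerStrand) break
            bases[span] <- .randomBases(elementLength, gc)
        }
    }
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- "chr1"
    list(genome = genome, elements = elements)
}

.regimeStates <- function(regime, nReads, nSites, p, pBg, cwa, cwaBoost) {
    if (regime == "cmt2_like") {
        pvec <- pmin(p + cwaBoost * cwa, 1)
        matrix(rbinom(nReads * nSites, 1L, rep(pvec, each = nReads)),
               nrow = nReads)
    } else {
        fFull <- (p - pBg) / (1 - pBg)
        fFull <- min(max(fFull, 0), 1)
        full <- runif(nReads) < fFull
        st <- matrix(rbinom(nReads * nSites, 1L, pBg), nrow = nReads)
        st[full, ] <- 1L
        st
    }
}

#' Simulate per-region read state matrices and their features
#'
#' Draws region feature vectors directly from the two methylation regimes,
#' without the genome/alignment machinery — the training set for the pattern
#' classifier. Each region gets a target methylation level drawn uniformly
#' from `pRange` (so the two regimes are matched in methylation level and
#' the classifier must learn the *pattern*, not the level) and a read count
#' of `minReads + Poisson(meanReads - minReads)`. CMT2-like regions
#' methylate each site of each read independently at the region level;
#' DRM2-like regions are a two-component read mixture — fully methylated
#' with probability `f_full` (set per region so the mean matches the target
#' level), background Bernoulli(`pBg`) otherwise.
#'
#' @param n number of regions.
#' @param regime `"cmt2_like"` or `"drm2_like"`.
#' @param nSites sites per region (default 5).
#' @param meanReads mean reads per region (default 7, the expected count at
#'   per-strand coverage 10, 30-bp regions, 100-bp reads).
#' @param minReads minimum reads per region (default 4).
#' @param pRange range of region methylation targets (default 0.15-0.6).
#' @param pBg DRM2-like background per-site probability (default 0.05).
#' @param seed integer seed.
#' @return A region feature `data.frame` (as [regionFeaturesTable()]) with
#'   extra columns `regime` and `true_p`.
#' @export
simulateRegimeFeatures <- function(n, regime = c("cmt2_like", "drm2_like"),
                                   nSites = 5L, meanReads = 7,
                                   minReads = 4L, pRange = c(0.15, 0.6),
                                   pBg = 0.05, seed = 1L) {
    regime <- match.arg(regime)
    set.seed(seed)
    p <- runif(n, pRange[1L], pRange[2L])
    nr <- minReads + rpois(n, max(meanReads - minReads, 0))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        st <- .regimeStates(regime, nr[i], nSites, p[i], pBg,
                            cwa = rep(FALSE, nSites), cwaBoost = 0)
        f <- regionFeatures(st, minReads = 1L)
        rows[[i]] <- data.frame(
            region_id = sprintf("%s_%05d", regime, i),
            element_id = NA_character_, n_reads = f$n_reads,
            mean_read_meth = f$mean_read_meth,
            sd_read_meth = f$sd_read_meth,
            mean_stochasticity = f$mean_stochasticity,
            sd_site_meth = f$sd_site_meth, gc = NA_real_,
            regime = regime, true_p = p[i])
    }
    do.call(rbind, rows)
}

#' Simulate bisulfite reads over a synthetic genome
#'
#' Places single-end reads uniformly along each chromosome (half on each
#' bisulfite strand; `coverage` is per strand, so the expected number of
#' reads fully overlapping a region follows [expectedReads()]). Each read
#' fully covering a region draws that region's site states from the
#' element's assigned regime: CMT2-like sites are independent
#' Bernoulli(`p` + `cwaBoost` at CWA sites); DRM2-like reads are fully
#' methylated with probability `f_full` (derived per region from the target
#' level) and background-methylated at `pBg` otherwise. Per-region target
#' levels are drawn from `pRange`. All cytosines outside (or not fully
#' covering) a region are emitted unmethylated, isolating the signal to the
#' defined regions. Unmethylated cytosines are bisulfite-converted in the
#' read sequence (C to T on the plus bisulfite strand; G to A in the
#' reference-forward representation of minus-strand reads).
#'
#' @param genome `DNAStringSet`.
#' @param regions `GRanges` from [buildRegions()] (with `cwa` site flags).
#' @param regimeByElement named character vector mapping `element_id` to
#'   `"cmt2_like"` or `"drm2_like"`.
#' @param coverage per-bisulfite-strand depth (> 0).
#' @param readLength read length in bp (> the largest region span).
#' @param pRange,pBg,cwaBoost regime parameters (defaults 0.15-0.6 target
#'   methylation, 0.05 background, +0.15 at CWA sites).
#' @param seed integer seed.
#' @return List with `reads` (data.frame: `read_id`, `chrom`, `pos`,
#'   `bs_strand`, `flag`, `seq`) and `truth` (one row per read-region pair
#'   fully covered: `read_id`, `region_id`, `states` 0/1 string, `regime`,
#'   `true_p`; plus per-region attributes in `region_truth`).
#' @export
simulateReads <- function(genome, regions, regimeByElement, coverage = 10,
                          readLength = 100L, pRange = c(0.15, 0.6),
                          pBg = 0.05, cwaBoost = 0.15, seed = 1L) {
    stopifnot(coverage > 0)
    if (length(regions) &&
        max(GenomicRanges::width(regions)) >= readLength)
        stop("readLength must exceed the largest region span")
    set.seed(seed)
    regRegime <- unname(regimeByElement[regions$element_id])
    if (anyNA(regRegime)) stop("regime assignment missing for some elements")
    regP <- runif(length(regions), pRange[1L], pRange[2L])
    ## expected region methylation including the CWA boost (the truth the
    ## pipeline should recover); the DRM2-like mixture is mean-matched to
    ## regP by construction
    effP <- regP
    isCmtReg <- regRegime == "cmt2_like"
    if (any(isCmtReg) && !is.null(regions$cwa)) {
        effP[isCmtReg] <- vapply(which(isCmtReg), function(i)
            mean(pmin(regP[i] + cwaBoost * regions$cwa[[i]], 1)),
            numeric(1))
    }
    allReads <- list(); allTruth <- list()
    for (chrom in names(genome)) {
        L <- Biostrings::nchar(genome[[chrom]])
        nTotal <- round(2 * coverage * L / readLength)
        starts <- sample.int(L - readLength + 1L, nTotal, replace = TRUE)
        bs <- ifelse(runif(nTotal) < 0.5, "+", "-")
        ids <- sprintf("%s_read%06d", chrom, seq_len(nTotal))
        chromStr <- as.character(genome[[chrom]])
        seqs <- substring(chromStr, starts, starts + readLength - 1L)
        ## bisulfite-convert everything, then restore methylated bases
        conv <- ifelse(bs == "+", chartr("C", "T", seqs),
                       chartr("G", "A", seqs))
        onChrom <- as.character(GenomeInfoDb::seqnames(regions)) == chrom
        ridx <- which(onChrom)
        truth <- NULL
        if (length(ridx)) {
            readGR <- GenomicRanges::GRanges(
                chrom, IRanges::IRanges(starts, width = readLength),
                strand = bs)
            hits <- suppressWarnings(GenomicRanges::findOverlaps(
                regions[ridx], readGR, type = "within",
                ignore.strand = FALSE))
            ri <- ridx[S4Vectors::queryHits(hits)]
            di <- S4Vectors::subjectHits(hits)
            if (length(ri)) {
                nS <- regions$n_sites[1L]
                nh <- length(ri)
                ## vectorised regime draws over all (read, region) pairs
                cwaMat <- if (!is.null(regions$cwa))
                    matrix(unlist(regions$cwa[ri]), nrow = nh, byrow = TRUE)
                else matrix(FALSE, nh, nS)
                isCmt <- regRegime[ri] == "cmt2_like"
                pMat <- matrix(pBg, nh, nS)
                if (any(isCmt))
                    pMat[isCmt, ] <- pmin(
                        regP[ri[isCmt]] +
                            cwaBoost * cwaMat[isCmt, , drop = FALSE], 1)
                states <- matrix(rbinom(nh * nS, 1L, as.vector(pMat)),
                                 nh, nS)
                fFull <- pmin(pmax((regP[ri] - pBg) / (1 - pBg), 0), 1)
                full <- !isCmt & runif(nh) < fFull
                states[full, ] <- 1L
                ## restore unconverted (methylated) bases: flat list of
                ## (read, genome position) pairs across all hits
                sitePos <- matrix(unlist(regions$sites[ri]), nrow = nh,
                                  byrow = TRUE)
                meth <- states == 1L
                if (any(meth)) {
                    dRep <- rep(di, times = rowSums(meth))
                    posFlat <- t(sitePos)[t(meth)]
                    off <- posFlat - starts[dRep] + 1L
                    restore <- ifelse(bs[dRep] == "+", "C", "G")
                    for (k in seq_along(dRep))
                        substr(conv[dRep[k]], off[k], off[k]) <- restore[k]
                }
                truth <- data.frame(
                    read_id = ids[di], region_id = regions$region_id[ri],
                    states = apply(states, 1L, paste, collapse = ""),
                    regime = regRegime[ri], true_p = effP[ri])
            }
        }
        allReads[[chrom]] <- data.frame(
            read_id = ids, chrom = chrom, pos = starts, bs_strand = bs,
            flag = ifelse(bs == "+", 0L, 16L), seq = conv)
        if (!is.null(truth)) allTruth[[chrom]] <- truth
    }
    truth <- if (length(allTruth)) do.call(rbind, allTruth) else
        data.frame(read_id = character(0), region_id = character(0),
                   states = character(0), regime = character(0),
                   true_p = numeric(0))
    rownames(truth) <- NULL
    out <- list(reads = do.call(rbind, allReads), truth = truth)
    rownames(out$reads) <- NULL
    out$region_truth <- data.frame(region_id = regions$region_id,
                                   regime = regRegime, true_p = effP,
                                   base_p = regP)
    out
}

#' Write simulated reads as SAM
#'
#' Emits a valid single-end SAM file (`@SQ` headers from the genome,
#' mandatory fields, pure-match CIGAR, constant placeholder qualities)
#' against the unconverted reference.
#'
#' @param reads data.frame from [simulateReads()]`$reads`.
#' @param genome `DNAStringSet` the reads were simulated from.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(reads, genome, path) {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                paste0("@SQ\tSN:", names(genome), "\tLN:",
                       Biostrings::nchar(genome)))
    rl <- nchar(reads$seq)
    body <- paste(reads$read_id, reads$flag, reads$chrom, reads$pos, 42L,
                  paste0(rl, "M"), "*", 0L, 0L, reads$seq,
                  strrep("I", rl), sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}
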