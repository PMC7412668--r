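## In-code fixtures shared across the suite.

writeToyFasta <- function(seqs, path = tempfile(fileext = ".fa")) {
    writeLines(unlist(lapply(names(seqs), function(n)
        c(paste0(">", n), seqs[[n]]))), path)
    path
}

writeToyGff <- function(rows, path = tempfile(fileext = ".gff3")) {
    ## rows: data.frame chrom, start, end (1-based incl), strand, type, id
    writeLines(c("##gff-version 3",
                 sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                         rows$chrom, rows$type, rows$start, rows$end,
                         rows$strand, rows$id)), path)
    path
}

## SAM with a single @SQ line; fields beyond the mandatory 11 appended as-is
writeToySam <- function(records, chromLens = c(chr1 = 1000L),
                        path = tempfile(fileext = ".sam")) {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                paste0("@SQ\tSN:", names(chromLens), "\tLN:", chromLens))
    writeLines(c(header, records), path)
    path
}

samRecord <- function(qname, flag, chrom, pos, seq, cigar = NULL,
                      extra = NULL) {
    if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
    rec <- paste(qname, flag, chrom, pos, 42L, cigar, "*", 0L, 0L, seq,
                 strrep("I", nchar(seq)), sep = "\t")
    if (!is.null(extra)) rec <- paste(rec, extra, sep = "\t")
    rec
}

## toy 5-site CHH region: chr1 = "A" + "CATT" x5 + "AAAA"; CHH sites (all
## nonCWA, CAT) at 1-based positions 2, 6, 10, 14, 18 on the plus strand.
toyRegionGenome <- function() {
    seq <- paste0("A", strrep("CATT", 5), "AAAA")
    g <- Biostrings::DNAStringSet(seq)
    names(g) <- "chr1"
    g
}

toyRegion <- function(genome = toyRegionGenome()) {
    el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 25),
                                 strand = "*", element_id = "toy")
    sites <- findContextSites(genome, el, "CHH")
    buildRegions(sites[GenomicRanges::strand(sites) == "+"],
                 nSites = 5, maxSpan = 30, genome = genome)
}

## a read covering the toy region with the given site states (1 = C kept)
toyReadSeq <- function(states) {
    ref <- paste0("A", strrep("CATT", 5), "AAAA")
    conv <- chartr("C", "T", ref)
    sitePos <- c(2, 6, 10, 14, 18)
    for (k in which(states == 1)) substr(conv, sitePos[k], sitePos[k]) <- "C"
    conv
}

## all 2^5 binary patterns as a matrix
allPatterns5 <- function() {
    as.matrix(expand.grid(rep(list(0:1), 5)))[, 5:1, drop = FALSE]
}

## independent brute-force oracle: maximum number of disjoint windows of
## nSites consecutive sites within maxSpan (backward dynamic programme)
bruteMaxRegions <- function(pos, nSites, maxSpan) {
    m <- length(pos)
    if (m < nSites) return(0L)
    valid <- vapply(seq_len(m - nSites + 1L), function(i)
        pos[i + nSites - 1L] - pos[i] + 1L <= maxSpan, logical(1))
    f <- integer(m + 1L)  # f[k]: best using sites k..m (f[m+1] = 0)
    for (k in m:1) {
        f[k] <- if (k + 1L <= m + 1L) f[k + 1L] else 0L
        if (k <= m - nSites + 1L && valid[k])
            f[k] <- max(f[k], 1L + f[k + nSites])
    }
    f[1L]
}

## Mann-Whitney pair-counting oracle for ROC AUC
aucByPairs <- function(scores, labels) {
    sp <- scores[labels == 1]; sn <- scores[labels == 0]
    cmp <- outer(sp, sn, function(a, b)
        (a > b) + 0.5 * (a == b))
    mean(cmp)
}
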