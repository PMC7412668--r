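## greedy left-to-right segmentation of one sorted position vector.
## Emits non-overlapping windows of exactly nSites consecutive sites whose
## C-to-C span (last - first + 1) fits within maxSpan; when the window grows
## past maxSpan the leftmost site is dropped; after emitting, the scan
## restarts at the next unused site.
.segmentPositions <- function(pos, nSites, maxSpan) {
    out <- list(); lo <- 1L
    for (hi in seq_along(pos)) {
        while (pos[hi] - pos[lo] + 1L > maxSpan) lo <- lo + 1L
        if (hi - lo + 1L == nSites) {
            out[[length(out) + 1L]] <- pos[lo:hi]
            lo <- hi + 1L
        }
    }
    out
}

#' Segment context sites into fixed-site-count regions
#'
#' Segments each element's per-strand site list into non-overlapping regions
#' of exactly `nSites` consecutive context sites whose span (first to last
#' cytosine, inclusive) does not exceed `maxSpan` base pairs. The scan is
#' greedy left-to-right, restarting after each emitted region, matching the
#' sequential iteration used to define regions in the single-read pipeline.
#' The defaults (5 sites within 30 bp) are the standard CHH analysis
#' parameters; CWA analyses use `maxSpan = 50` to compensate for the lower
#' subcontext density, and read-level binning analyses use 5/10/15 sites
#' within 100 bp.
#'
#' @param sites `GRanges` of context sites from [findContextSites()].
#' @param nSites integer >= 2, number of sites per region (default 5).
#' @param maxSpan integer >= `nSites`, maximum region span in bp (default 30).
#' @param genome optional `DNAStringSet`; when supplied, each region's GC
#'   content over its span is recorded.
#' @return A `GRanges` of region spans with metadata columns `region_id`,
#'   `element_id`, `n_sites`, `sites` (an `IntegerList` of 1-based site
#'   positions) and `gc` (`NA` when no genome given).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = strrep("CATGA", 20)))
#' el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
#'                              strand = "*", element_id = "e1")
#' s <- findContextSites(g, el, "CHH")
#' buildRegions(s, nSites = 5, maxSpan = 30, genome = g)
#' @export
buildRegions <- function(sites, nSites = 5L, maxSpan = 30L, genome = NULL) {
    stopifnot(nSites >= 2L, maxSpan >= nSites)
    if (length(sites) == 0L)
        return(GenomicRanges::GRanges(
            region_id = character(0), element_id = character(0),
            n_sites = integer(0), sites = IRanges::IntegerList(),
            gc = numeric(0)))
    key <- paste(sites$element_id, as.character(GenomeInfoDb::seqnames(sites)),
                 as.character(GenomicRanges::strand(sites)), sep = "\r")
    groups <- split(seq_along(sites), key)
    rows <- list()
    for (idx in groups) {
        pos <- sort(GenomicRanges::start(sites)[idx])
        segs <- .segmentPositions(pos, nSites, maxSpan)
        if (!length(segs)) next
        rows[[length(rows) + 1L]] <- list(
            chrom = as.character(GenomeInfoDb::seqnames(sites))[idx[1L]],
            strand = as.character(GenomicRanges::strand(sites))[idx[1L]],
            element = sites$element_id[idx[1L]], segs = segs)
    }
    if (!length(rows))
        return(GenomicRanges::GRanges(
            region_id = character(0), element_id = character(0),
            n_sites = integer(0), sites = IRanges::IntegerList(),
            gc = numeric(0)))
    chrom <- unlist(lapply(rows, function(r)
        rep(r$chrom, length(r$segs))))
    strand <- unlist(lapply(rows, function(r) rep(r$strand, length(r$segs))))
    element <- unlist(lapply(rows, function(r)
        rep(r$element, length(r$segs))))
    segs <- unlist(lapply(rows, `[[`, "segs"), recursive = FALSE)
    first <- vapply(segs, min, integer(1))
    last <- vapply(segs, max, integer(1))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(first, last),
                                 strand = strand)
    gr$region_id <- paste0(element, ":", strand, ":", first)
    gr$element_id <- element
    gr$n_sites <- nSites
    gr$sites <- IRanges::IntegerList(segs)
    ## carry CWA identity of each site when the input provides subcontexts
    if (!is.null(sites$subcontext)) {
        cwaPos <- GenomicRanges::start(sites)[!is.na(sites$subcontext) &
                                              sites$subcontext == "CWA"]
        gr$cwa <- IRanges::LogicalList(lapply(segs, function(s)
            s %in% cwaPos))
    }
    gr$gc <- NA_real_
    if (!is.null(genome)) {
        spanSeq <- vapply(seq_along(gr), function(i)
            as.character(Biostrings::subseq(genome[[chrom[i]]],
                                            first[i], last[i])),
            character(1))
        gr$gc <- gcContent(spanSeq)
    }
    o <- order(chrom, first)
    gr[o]
}

#' Write a region table
#'
#' BED-like TSV: chrom, 0-based span start, half-open span end, region_id,
#' n_sites, strand, comma-joined 0-based site offsets (relative to span
#' start), gc.
#'
#' @param regions `GRanges` from [buildRegions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRegionTable <- function(regions, path) {
    off <- vapply(seq_along(regions), function(i)
        paste(regions$sites[[i]] - GenomicRanges::start(regions)[i],
              collapse = ","), character(1))
    df <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(regions)),
        start0 = GenomicRanges::start(regions) - 1L,
        end = GenomicRanges::end(regions),
        region_id = regions$region_id, n_sites = regions$n_sites,
        strand = as.character(GenomicRanges::strand(regions)),
        site_offsets = off, gc = regions$gc)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
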