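#' Read aligned bisulfite reads from SAM
#'
#' Parses a SAM file of end-to-end, ungapped bisulfite alignments (the
#' expected input is an alignment run with no mismatches or gaps permitted,
#' so CIGARs are pure matches). Unmapped (flag 4), secondary (flag 256) and
#' gapped/clipped records are skipped and counted. The bisulfite strand of
#' each read is inferred from the SAM flag assuming a directional library
#' (forward-mapped = original-top strand `+`, reverse-mapped = original-bottom
#' strand `-`); a Bismark-style `XG` tag (`CT`/`GA`), when present, overrides
#' the flag.
#'
#' @param path path to a SAM file with `@SQ` headers.
#' @param genome optional `DNAStringSet`; when supplied, alignments to
#'   chromosomes absent from the genome raise an error.
#' @return A `data.frame` with columns `read_id`, `chrom`, `pos` (1-based
#'   leftmost), `bs_strand` (`+`/`-`), `seq` (reference-forward orientation,
#'   as stored in SAM), and attribute `skipped` (named counts of unmapped /
#'   secondary / gapped records).
#' @export
readBisulfiteAlignments <- function(path, genome = NULL) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam))
    res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
        tag = "XG"))[[1L]]
    flag <- res$flag
    unmapped <- bitwAnd(flag, 4L) != 0L
    secondary <- bitwAnd(flag, 256L) != 0L
    gapped <- !grepl("^[0-9]+M$", res$cigar) & !unmapped
    keep <- !(unmapped | secondary | gapped)
    skipped <- c(unmapped = sum(unmapped), secondary = sum(secondary & !unmapped),
                 gapped = sum(gapped & !secondary))
    bs <- ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+")
    xg <- res$tag$XG
    if (!is.null(xg)) {
        xg <- xg[keep]
        bs[!is.na(xg) & xg == "CT"] <- "+"
        bs[!is.na(xg) & xg == "GA"] <- "-"
    }
    out <- data.frame(
        read_id = res$qname[keep],
        chrom = as.character(res$rname[keep]),
        pos = res$pos[keep],
        bs_strand = bs,
        seq = as.character(res$seq[keep]),
        stringsAsFactors = FALSE)
    if (!is.null(genome)) {
        miss <- setdiff(unique(out$chrom), names(genome))
        if (length(miss))
            stop("alignment chromosome(s) absent from genome: ",
                 paste(miss, collapse = ", "))
    }
    attr(out, "skipped") <- skipped
    out
}

#' Remove exact duplicate alignments
#'
#' Collapses reads identical in (chrom, position, orientation, sequence) to a
#' single representative, after sorting by position — the duplicate-removal
#' step applied after alignment sorting.
#'
#' @param reads data.frame from [readBisulfiteAlignments()].
#' @return The deduplicated data.frame, position-sorted, with attribute
#'   `duplicates_removed`.
#' @export
dedupeAlignments <- function(reads) {
    if (nrow(reads) == 0L) {
        attr(reads, "duplicates_removed") <- 0L
        return(reads)
    }
    reads <- reads[order(reads$chrom, reads$pos), , drop = FALSE]
    key <- paste(reads$chrom, reads$pos, reads$bs_strand, reads$seq,
                 sep = "\r")
    dup <- duplicated(key)
    out <- reads[!dup, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "duplicates_removed") <- sum(dup)
    out
}

#' Call the methylation state of one site on one read
#'
#' Bisulfite conversion leaves methylated cytosines as C and converts
#' unmethylated cytosines to T (read on the cytosine's own strand). For a
#' plus-strand site the reference-forward read base is therefore C
#' (methylated) or T (unmethylated); for a minus-strand site, where the SAM
#' sequence is stored reference-forward, the complement applies: G
#' (methylated) or A (unmethylated). Any other base is uninformative.
#'
#' @param readPos 1-based leftmost aligned position of the read.
#' @param readSeq read bases, reference-forward orientation.
#' @param sitePos 1-based genomic position of the site's cytosine.
#' @param siteStrand `"+"` or `"-"`.
#' @return `1L`, `0L`, or `NA` (uninformative). Errors if the site lies
#'   outside the read's aligned span.
#' @export
callSite <- function(readPos, readSeq, sitePos, siteStrand) {
    off <- sitePos - readPos + 1L
    if (off < 1L || off > nchar(readSeq))
        stop("site outside the read's aligned span")
    base <- substr(readSeq, off, off)
    if (siteStrand == "+") {
        if (base == "C") 1L else if (base == "T") 0L else NA_integer_
    } else {
        if (base == "G") 1L else if (base == "A") 0L else NA_integer_
    }
}

#' Extract per-read binary methylation vectors for regions
#'
#' For every region, every alignment whose span covers *all* the region's
#' sites and whose bisulfite strand equals the region strand is converted to
#' a binary vector (1 = methylated) over the region's sites. A read with an
#' uninformative base at any region site is dropped for that region:
#' downstream features require complete vectors, and with a no-mismatch
#' alignment such bases are rare.
#'
#' @param regions `GRanges` from [buildRegions()] (a single `n_sites`).
#' @param reads data.frame from [readBisulfiteAlignments()].
#' @return A [ReadVectorSet-class]; attribute `dropped_uninformative` counts
#'   read-region pairs discarded for an uninformative base.
#' @export
extractReadVectors <- function(regions, reads) {
    nSites <- unique(regions$n_sites)
    if (length(nSites) > 1L)
        stop("regions must share a single n_sites")
    empty <- function() {
        rv <- new("ReadVectorSet",
                  states = matrix(integer(0), 0L, max(nSites, 2L)),
                  regionId = character(0), readId = character(0))
        attr(rv, "dropped_uninformative") <- 0L
        rv
    }
    if (length(regions) == 0L || nrow(reads) == 0L) return(empty())
    readGR <- GenomicRanges::GRanges(
        reads$chrom,
        IRanges::IRanges(reads$pos, width = nchar(reads$seq)),
        strand = reads$bs_strand)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
        regions, readGR, type = "within", ignore.strand = FALSE))
    if (length(hits) == 0L) return(empty())
    ri <- S4Vectors::queryHits(hits)
    di <- S4Vectors::subjectHits(hits)
    sitePos <- matrix(unlist(regions$sites[ri]), ncol = nSites, byrow = TRUE)
    off <- sitePos - reads$pos[di] + 1L
    chars <- matrix("", nrow = length(ri), ncol = nSites)
    for (j in seq_len(nSites))
        chars[, j] <- substring(reads$seq[di], off[, j], off[, j])
    plus <- as.character(GenomicRanges::strand(regions))[ri] == "+"
    states <- matrix(NA_integer_, nrow = length(ri), ncol = nSites)
    states[plus & chars == "C"] <- 1L
    states[plus & chars == "T"] <- 0L
    states[!plus & chars == "G"] <- 1L
    states[!plus & chars == "A"] <- 0L
    ok <- rowSums(is.na(states)) == 0L
    rv <- new("ReadVectorSet", states = states[ok, , drop = FALSE],
              regionId = regions$region_id[ri][ok],
              readId = reads$read_id[di][ok])
    attr(rv, "dropped_uninformative") <- sum(!ok)
    rv
}

#' Write a read-vector table
#'
#' TSV with columns region_id, read_id, states (0/1 string), score.
#'
#' @param rv a [ReadVectorSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReadVectorTable <- function(rv, path) {
    df <- data.frame(region_id = rv@regionId, read_id = rv@readId,
                     states = apply(rv@states, 1L, paste, collapse = ""),
                     score = readScores(rv))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname readFeatures
#' @export
setMethod("readScores", "ReadVectorSet", function(x) rowSums(x@states))

#' @rdname readFeatures
#' @export
setMethod("readScores", "matrix", function(x) rowSums(x))

#' @rdname readFeatures
#' @export
setMethod("readMethylation", "ReadVectorSet",
          function(x) rowMeans(x@states))

#' @rdname readFeatures
#' @export
setMethod("readMethylation", "matrix", function(x) rowMeans(x))
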