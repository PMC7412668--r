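#' Load a reference genome from FASTA
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file and returns the
#' sequences uppercased, named by the first whitespace-delimited token of each
#' header.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per record.
#' @export
loadGenome <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0L)
        stop("no sequences in FASTA file: ", path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyNA(names(seqs)) || any(names(seqs) == ""))
        stop("malformed FASTA header in ", path)
    Biostrings::DNAStringSet(toupper(seqs))
}

#' Load element annotations from GFF3
#'
#' Imports a GFF3 annotation (1-based inclusive coordinates) as a `GRanges`.
#' Records with end < start are rejected with a warning. The `ID` attribute
#' (falling back to `Name`, then a generated identifier) becomes
#' `element_id`; the GFF `type` column becomes `feature_class`.
#'
#' @param path path to a GFF3 file.
#' @param featureFilter optional character; keep only rows whose GFF type
#'   matches one of these values (e.g. `"TE"`).
#' @return A [GenomicRanges::GRanges] with metadata columns `element_id` and
#'   `feature_class`. Strand `*` means unstranded (both strands are scanned
#'   for context sites).
#' @export
loadElements <- function(path, featureFilter = NULL) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (!is.null(featureFilter))
        gr <- gr[as.character(gr$type) %in% featureFilter]
    bad <- GenomicRanges::width(gr) < 1L
    if (any(bad)) {
        warning(sum(bad), " annotation record(s) with end < start rejected")
        gr <- gr[!bad]
    }
    id <- as.character(gr$ID)
    if (is.null(gr$ID)) id <- rep(NA_character_, length(gr))
    if (!is.null(gr$Name)) id[is.na(id)] <- as.character(gr$Name)[is.na(id)]
    noid <- is.na(id)
    id[noid] <- paste0("elem", seq_along(gr))[noid]
    out <- GenomicRanges::granges(gr)
    out$element_id <- id
    out$feature_class <- as.character(gr$type)
    out
}

.CONTEXTS <- c("CHH", "CWA", "nonCWA", "CH", "CG", "CHG")

## classify trinucleotides read 5'->3' on the site's own strand;
## any N disqualifies the site
.classifyTri <- function(tri) {
    b2 <- substr(tri, 2L, 2L)
    b3 <- substr(tri, 3L, 3L)
    ctx <- rep(NA_character_, length(tri))
    ok <- !grepl("N", tri, fixed = TRUE)
    ctx[ok & b2 == "G"] <- "CG"
    ctx[ok & b2 != "G" & b3 == "G"] <- "CHG"
    ctx[ok & b2 != "G" & b3 != "G"] <- "CHH"
    ctx
}

.scanStrand <- function(bases) {
    ## bases: character vector of single letters, 5'->3' on the scanned strand
    w <- length(bases)
    if (w < 3L) return(integer(0))
    which(bases[seq_len(w - 2L)] == "C")
}

#' Find methylation-context cytosine sites within elements
#'
#' Scans the reference sequence of each element, per strand, for cytosines in
#' the requested methylation context. Contexts follow the plant convention:
#' `CG`; `CHG` and `CHH` with H = A/C/T; `CH` = any non-CG cytosine (the
#' union of CHG and CHH, used for mammalian non-CG methylation); the CHH
#' subcontexts `CWA` (trinucleotide CAA or CTA, W = A/T) and `nonCWA`.
#' Minus-strand sites are cytosines on the reverse complement; their reported
#' position is the forward-strand coordinate of that base. Sites whose
#' trinucleotide would run past the element end (the last two positions) or
#' contains an N are skipped, as their context is undefined.
#'
#' Stranded elements are scanned on their own strand only; unstranded (`*`)
#' elements are scanned on both strands. CHH regions are intrinsically
#' strand-specific, so TE annotations are normally supplied unstranded.
#'
#' @param genome a `DNAStringSet` from [loadGenome()].
#' @param elements a `GRanges` from [loadElements()].
#' @param context one of `"CHH"`, `"CWA"`, `"nonCWA"`, `"CH"`, `"CG"`,
#'   `"CHG"`.
#' @return A `GRanges` of width-1 sites (1-based), sorted by position within
#'   each element/strand, with metadata columns `element_id`, `context`
#'   (canonical class: CG/CHG/CHH), `subcontext` (CWA/nonCWA for CHH sites,
#'   `NA` otherwise) and `trinucleotide` (as read 5'->3' on the site's
#'   strand).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "CAACAT"))
#' el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 6), strand = "+",
#'                              element_id = "e1")
#' findContextSites(g, el, "CHH")  # CAA (CWA) at 1, CAT (nonCWA) at 4
#' @export
findContextSites <- function(genome, elements, context = "CHH") {
    context <- match.arg(context, .CONTEXTS)
    missing <- setdiff(unique(as.character(
        GenomeInfoDb::seqnames(elements))), names(genome))
    if (length(missing))
        stop("annotation chromosome(s) absent from genome: ",
             paste(missing, collapse = ", "))
    pieces <- vector("list", length(elements) * 2L)
    k <- 0L
    for (i in seq_along(elements)) {
        el <- elements[i]
        chrom <- as.character(GenomeInfoDb::seqnames(el))
        st <- GenomicRanges::start(el); en <- GenomicRanges::end(el)
        if (st < 1L || en > Biostrings::nchar(genome[[chrom]]))
            stop("element ", el$element_id, " outside sequence bounds")
        elSeq <- as.character(Biostrings::subseq(genome[[chrom]], st, en))
        strands <- switch(as.character(GenomicRanges::strand(el)),
                          "+" = "+", "-" = "-", c("+", "-"))
        for (strd in strands) {
            if (strd == "+") {
                bases <- strsplit(elSeq, "", fixed = TRUE)[[1]]
                cpos <- .scanStrand(bases)
                tri <- paste0(bases[cpos], bases[cpos + 1L], bases[cpos + 2L])
                gpos <- st + cpos - 1L
            } else {
                rc <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(elSeq)))
                bases <- strsplit(rc, "", fixed = TRUE)[[1]]
                cpos <- .scanStrand(bases)
                tri <- paste0(bases[cpos], bases[cpos + 1L], bases[cpos + 2L])
                gpos <- en - cpos + 1L
            }
            ctx <- .classifyTri(tri)
            keep <- !is.na(ctx)
            keep <- keep & switch(context,
                CHH = ctx == "CHH",
                CWA = ctx == "CHH" & tri %in% c("CAA", "CTA"),
                nonCWA = ctx == "CHH" & !tri %in% c("CAA", "CTA"),
                CH = ctx != "CG",
                CG = ctx == "CG",
                CHG = ctx == "CHG")
            if (!any(keep)) next
            gp <- gpos[keep]; o <- order(gp)
            k <- k + 1L
            pieces[[k]] <- GenomicRanges::GRanges(
                chrom, IRanges::IRanges(gp[o], width = 1L), strand = strd,
                element_id = el$element_id, context = ctx[keep][o],
                subcontext = ifelse(ctx[keep][o] == "CHH",
                    ifelse(tri[keep][o] %in% c("CAA", "CTA"),
                           "CWA", "nonCWA"), NA_character_),
                trinucleotide = tri[keep][o],
                seqlengths = setNames(Biostrings::nchar(genome[[chrom]]),
                                      chrom))
        }
    }
    if (k == 0L)
        return(GenomicRanges::GRanges(element_id = character(0),
                                      context = character(0),
                                      subcontext = character(0),
                                      trinucleotide = character(0)))
    suppressWarnings(do.call(c, pieces[seq_len(k)]))
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (sequence length excluding N). An all-N sequence has
#' undefined GC content and returns `NA` with a warning.
#'
#' @param seq a character string, `DNAString`, or `DNAStringSet`
#'   (vectorised over records).
#' @return numeric in \[0, 1\] (or `NA` for all-N input).
#' @examples
#' gcContent("ACGTN")  # 2/4 = 0.5; the N is dropped from both counts
#' @export
gcContent <- function(seq) {
    if (is(seq, "DNAString")) seq <- Biostrings::DNAStringSet(seq)
    if (!is(seq, "DNAStringSet"))
        seq <- Biostrings::DNAStringSet(toupper(as.character(seq)))
    if (any(Biostrings::nchar(seq) == 0L)) stop("empty sequence")
    f <- Biostrings::alphabetFrequency(seq, baseOnly = TRUE)
    denom <- rowSums(f[, c("A", "C", "G", "T"), drop = FALSE])
    out <- ifelse(denom > 0, (f[, "C"] + f[, "G"]) / denom, NA_real_)
    if (anyNA(out)) warning("all-N sequence: GC content undefined")
    unname(out)
}

#' Write a context-site table
#'
#' TSV with columns chrom, pos0 (0-based), strand, context, subcontext,
#' trinucleotide.
#'
#' @param sites `GRanges` from [findContextSites()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(sites, path) {
    df <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(sites)),
        pos0 = GenomicRanges::start(sites) - 1L,
        strand = as.character(GenomicRanges::strand(sites)),
        context = sites$context, subcontext = sites$subcontext,
        trinucleotide = sites$trinucleotide)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
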