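#' Analysis configuration
#'
#' Assembles (and validates) the parameter set shared across the pipeline
#' stages: the methylation context, region geometry, and the filter
#' thresholds applied before element aggregation and classification.
#'
#' @param context context class (default `"CHH"`).
#' @param nSites context sites per region (default 5).
#' @param maxSpan maximum region span in bp (default 30).
#' @param minMeth minimum region mean methylation (default 0.10).
#' @param minReads minimum reads per region (default 4).
#' @param minRegions minimum surviving regions per element (default 2).
#' @param hyperDelta hypermethylation threshold between samples
#'   (default 0.10).
#' @param seed integer seed for any stochastic stage.
#' @param dedupe remove exact duplicate alignments (default TRUE).
#' @return A named list of class `srmeth_config`.
#' @export
analysisConfig <- function(context = "CHH", nSites = 5L, maxSpan = 30L,
                           minMeth = 0.10, minReads = 4L, minRegions = 2L,
                           hyperDelta = 0.10, seed = 1L, dedupe = TRUE) {
    stopifnot(nSites >= 2L, maxSpan >= nSites,
              minMeth >= 0, minMeth <= 1, minReads >= 1L, minRegions >= 1L,
              hyperDelta >= 0, hyperDelta <= 1)
    context <- match.arg(context, .CONTEXTS)
    structure(list(context = context, nSites = as.integer(nSites),
                   maxSpan = as.integer(maxSpan), minMeth = minMeth,
                   minReads = as.integer(minReads),
                   minRegions = as.integer(minRegions),
                   hyperDelta = hyperDelta, seed = as.integer(seed),
                   dedupe = isTRUE(dedupe)),
              class = "srmeth_config")
}

#' Read / write an analysis configuration file
#'
#' Plain `key = value` text format; round-trips losslessly.
#'
#' @param config an `srmeth_config` from [analysisConfig()].
#' @param path file path.
#' @return `writeAnalysisConfig` returns `path` invisibly;
#'   `readAnalysisConfig` returns the config.
#' @export
writeAnalysisConfig <- function(config, path) {
    writeLines(paste(names(config), "=",
                     vapply(config, function(v)
                         format(v, digits = 17), character(1))), path)
    invisible(path)
}

#' @rdname writeAnalysisConfig
#' @export
readAnalysisConfig <- function(path) {
    lines <- readLines(path)
    kv <- strsplit(lines, "\\s*=\\s*")
    vals <- setNames(vapply(kv, `[`, character(1), 2L),
                     vapply(kv, `[`, character(1), 1L))
    analysisConfig(context = vals[["context"]],
                   nSites = as.integer(vals[["nSites"]]),
                   maxSpan = as.integer(vals[["maxSpan"]]),
                   minMeth = as.numeric(vals[["minMeth"]]),
                   minReads = as.integer(vals[["minReads"]]),
                   minRegions = as.integer(vals[["minRegions"]]),
                   hyperDelta = as.numeric(vals[["hyperDelta"]]),
                   seed = as.integer(vals[["seed"]]),
                   dedupe = as.logical(vals[["dedupe"]]))
}

#' Run the three-stage single-read pipeline
#'
#' Stage 1 identifies short per-strand context regions within the annotated
#' elements; stage 2 extracts complete per-read binary methylation vectors
#' for each region; stage 3 averages read data into region features and
#' element summaries under the configured filters. Attrition counts at every
#' filter are reported via `message()` and returned in `log`.
#'
#' @param fasta,gff,sam input file paths (reference genome, element
#'   annotation, aligned bisulfite reads).
#' @param config an `srmeth_config` from [analysisConfig()].
#' @param outDir optional directory; when given, TSV tables (sites, regions,
#'   read vectors, region features, element summaries) are written there.
#' @param featureFilter optional GFF type filter passed to [loadElements()].
#' @return List with `sites`, `regions`, `readVectors`, `regionTable`,
#'   `elementTable`, `log`.
#' @export
runPipeline <- function(fasta, gff, sam, config = analysisConfig(),
                        outDir = NULL, featureFilter = NULL) {
    genome <- loadGenome(fasta)
    elements <- loadElements(gff, featureFilter = featureFilter)
    miss <- setdiff(unique(as.character(GenomeInfoDb::seqnames(elements))),
                    names(genome))
    if (length(miss))
        stop("chromosome mismatch between FASTA and GFF: ",
             paste(miss, collapse = ", "))
    sites <- findContextSites(genome, elements, config$context)
    regions <- buildRegions(sites, config$nSites, config$maxSpan,
                            genome = genome)
    reads <- readBisulfiteAlignments(sam, genome = genome)
    nRaw <- nrow(reads)
    skipped <- attr(reads, "skipped")
    nDup <- 0L
    if (config$dedupe) {
        reads <- dedupeAlignments(reads)
        nDup <- attr(reads, "duplicates_removed")
    }
    rv <- extractReadVectors(regions, reads)
    regionTable <- regionFeaturesTable(rv, regions,
                                       minReads = config$minReads)
    elementTable <- aggregateElements(regionTable, minMeth = config$minMeth,
                                      minReads = config$minReads,
                                      minRegions = config$minRegions)
    log <- list(n_sites = length(sites), n_regions = length(regions),
                n_reads_kept = nRaw, reads_skipped = skipped,
                duplicates_removed = nDup,
                n_read_vectors = length(rv),
                dropped_uninformative = attr(rv, "dropped_uninformative"),
                regions_low_reads = attr(regionTable, "filtered_low_reads"),
                n_regions_with_features = nrow(regionTable),
                n_elements = nrow(elementTable))
    message("sites: ", log$n_sites, "; regions: ", log$n_regions,
            "; reads kept: ", log$n_reads_kept,
            " (skipped ", sum(skipped), ", duplicates ", nDup, ")",
            "; read vectors: ", log$n_read_vectors,
            " (uninformative ", log$dropped_uninformative, ")",
            "; regions with features: ", log$n_regions_with_features,
            " (low-read ", log$regions_low_reads, ")",
            "; elements: ", log$n_elements)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeSiteTable(sites, file.path(outDir, "sites.tsv"))
        writeRegionTable(regions, file.path(outDir, "regions.tsv"))
        writeReadVectorTable(rv, file.path(outDir, "read_vectors.tsv"))
        write.table(regionTable, file.path(outDir, "region_features.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(elementTable, file.path(outDir, "element_summary.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(sites = sites, regions = regions, readVectors = rv,
         regionTable = regionTable, elementTable = elementTable, log = log)
}

#' Compare two processed samples
#'
#' Matches regions and elements by id across two samples processed with
#' identical region definitions, and reports per-region and per-element
#' feature deltas (B minus A), the hypermethylated region set
#' (B exceeding A by more than `hyperDelta`), and — when a fitted model is
#' given — the per-element pattern-score shift (distance from the f(x) = x
#' diagonal indicates a change in the methylating enzyme).
#'
#' @param resultA,resultB outputs of [runPipeline()] (or lists with
#'   `regionTable`/`elementTable`).
#' @param config an `srmeth_config`.
#' @param model optional fitted [PatternModel-class].
#' @return List with `regionDelta`, `elementDelta`, `hypermethylated`, and
#'   (with a model) `scoreShift`; unmatched ids are counted in `log`.
#' @export
compareSamples <- function(resultA, resultB, config = analysisConfig(),
                           model = NULL) {
    featCols <- c("mean_read_meth", "sd_read_meth", "mean_stochasticity",
                  "sd_site_meth")
    matchTables <- function(a, b, key) {
        common <- intersect(a[[key]], b[[key]])
        ia <- match(common, a[[key]]); ib <- match(common, b[[key]])
        d <- data.frame(common)
        names(d) <- key
        for (f in featCols)
            d[[paste0("delta_", f)]] <- b[[f]][ib] - a[[f]][ia]
        list(delta = d, unmatched = length(a[[key]]) + length(b[[key]]) -
                 2L * length(common))
    }
    reg <- matchTables(resultA$regionTable, resultB$regionTable, "region_id")
    ele <- matchTables(resultA$elementTable, resultB$elementTable,
                       "element_id")
    out <- list(regionDelta = reg$delta, elementDelta = ele$delta,
                hypermethylated = selectHypermethylated(
                    resultA$regionTable, resultB$regionTable,
                    delta = config$hyperDelta),
                log = list(regions_unmatched = reg$unmatched,
                           elements_unmatched = ele$unmatched))
    if (!is.null(model)) {
        common <- ele$delta$element_id
        ia <- match(common, resultA$elementTable$element_id)
        ib <- match(common, resultB$elementTable$element_id)
        sa <- patternScore(model, resultA$elementTable[ia, , drop = FALSE])
        sb <- patternScore(model, resultB$elementTable[ib, , drop = FALSE])
        out$scoreShift <- data.frame(element_id = common, score_a = sa,
                                     score_b = sb, shift = sb - sa)
    }
    message("compare: ", nrow(reg$delta), " matched regions (",
            reg$unmatched, " unmatched); ", nrow(ele$delta),
            " matched elements (", ele$unmatched, " unmatched); ",
            length(out$hypermethylated), " hypermethylated regions")
    out
}
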