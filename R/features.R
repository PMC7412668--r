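## population (uncorrected) standard deviation
.popSD <- function(x) sqrt(mean((x - mean(x))^2))

#' @rdname readFeatures
#' @export
setMethod("readStochasticity", "matrix", function(x) {
    if (ncol(x) < 2L) stop("stochasticity requires at least 2 sites")
    n <- ncol(x)
    rowSums(abs(x[, -1L, drop = FALSE] - x[, -n, drop = FALSE])) / (n - 1L)
})

#' @rdname readFeatures
#' @export
setMethod("readStochasticity", "ReadVectorSet",
          function(x) readStochasticity(x@states))

#' @rdname readFeatures
#' @export
setMethod("readStochasticity", "numeric",
          function(x) readStochasticity(matrix(x, nrow = 1L)))

#' @rdname readFeatures
#' @export
setMethod("readStochasticity", "integer",
          function(x) readStochasticity(matrix(x, nrow = 1L)))

#' Methylation-variation features of a single region
#'
#' Computes the region-level features from a complete read-by-site binary
#' matrix: mean read methylation, the standard deviation of read methylation
#' (cell-to-cell heterogeneity), mean read stochasticity, and the standard
#' deviation of the per-site mean methylation fractions (among-site
#' variation). Standard deviations are population (uncorrected) SDs. For a
#' complete matrix the mean read methylation equals the mean of the per-site
#' fractions.
#'
#' @param states binary matrix (reads x sites) or [ReadVectorSet-class]
#'   restricted to one region.
#' @param minReads minimum read count for the region to be retained
#'   (default 4); regions below it return `NULL` (filtered out).
#' @return A list with `n_reads`, `mean_read_meth`, `sd_read_meth`,
#'   `mean_stochasticity`, `sd_site_meth`, `per_site_meth`, or `NULL` if the
#'   region fails the read-count filter (or the matrix is empty).
#' @examples
#' regionFeatures(rbind(rep(1, 5), rep(0, 5)), minReads = 2)
#' @export
regionFeatures <- function(states, minReads = 4L) {
    if (is(states, "ReadVectorSet")) states <- states@states
    if (nrow(states) < max(1L, minReads)) return(NULL)
    perSite <- colMeans(states)
    list(n_reads = nrow(states),
         mean_read_meth = mean(rowMeans(states)),
         sd_read_meth = .popSD(rowMeans(states)),
         mean_stochasticity = mean(readStochasticity(states)),
         sd_site_meth = .popSD(perSite),
         per_site_meth = perSite)
}

#' Region feature table for a ReadVectorSet
#'
#' Applies [regionFeatures()] to every region present in `rv`; regions with
#' fewer than `minReads` complete read vectors are dropped (and counted in
#' the `filtered_low_reads` attribute). When `regions` is supplied, the
#' region GC content and parent element are carried over.
#'
#' @param rv a [ReadVectorSet-class].
#' @param regions optional `GRanges` from [buildRegions()].
#' @param minReads minimum overlapping reads per region (default 4).
#' @return A `data.frame` with one row per surviving region: `region_id`,
#'   `element_id`, `n_reads`, `mean_read_meth`, `sd_read_meth`,
#'   `mean_stochasticity`, `sd_site_meth`, `gc`.
#' @export
regionFeaturesTable <- function(rv, regions = NULL, minReads = 4L) {
    groups <- split(seq_len(nrow(rv@states)), rv@regionId)
    feats <- lapply(groups, function(idx)
        regionFeatures(rv@states[idx, , drop = FALSE], minReads = minReads))
    keep <- !vapply(feats, is.null, logical(1))
    ids <- names(groups)[keep]
    feats <- feats[keep]
    df <- data.frame(
        region_id = ids,
        element_id = NA_character_,
        n_reads = vapply(feats, `[[`, numeric(1), "n_reads"),
        mean_read_meth = vapply(feats, `[[`, numeric(1), "mean_read_meth"),
        sd_read_meth = vapply(feats, `[[`, numeric(1), "sd_read_meth"),
        mean_stochasticity = vapply(feats, `[[`, numeric(1),
                                    "mean_stochasticity"),
        sd_site_meth = vapply(feats, `[[`, numeric(1), "sd_site_meth"),
        gc = NA_real_, row.names = NULL)
    if (!is.null(regions)) {
        m <- match(df$region_id, regions$region_id)
        df$element_id <- regions$element_id[m]
        df$gc <- regions$gc[m]
    }
    attr(df, "filtered_low_reads") <- sum(!keep)
    df
}

#' Histogram of per-read methylation scores
#'
#' Counts reads by their methylation score (number of methylated sites,
#' 0..`n_sites`), optionally restricted to regions whose mean read
#' methylation reaches `minRegionMeth` — the read-state summaries plotted per
#' region-methylation bin (at 5%, 20% and 40% minimum methylation).
#'
#' @param rv a [ReadVectorSet-class].
#' @param minRegionMeth optional minimum region mean methylation; regions
#'   below it are excluded before counting.
#' @return Named integer vector of counts over scores `0..n_sites`.
#' @export
readStateHistogram <- function(rv, minRegionMeth = NULL) {
    states <- rv@states
    if (!is.null(minRegionMeth) && nrow(states)) {
        rmeans <- tapply(rowMeans(states), rv@regionId, mean)
        ok <- names(rmeans)[rmeans >= minRegionMeth]
        states <- states[rv@regionId %in% ok, , drop = FALSE]
    }
    n <- ncol(states)
    tabulate(rowSums(states) + 1L, nbins = n + 1L) |>
        setNames(as.character(0:n))
}

#' Joint histogram of read methylation and stochasticity
#'
#' Bins reads by (methylation fraction, stochasticity), the two per-read
#' axes whose joint distribution separates DRM2-like from CMT2-like reads.
#' Cells with no reads are absent from the output (no data, not zero).
#'
#' @param rv a [ReadVectorSet-class] (typically built from regions with 5,
#'   10 or 15 sites within 100 bp).
#' @param methBreaks,stochBreaks bin edges covering \[0, 1\]; defaults are
#'   the feasible value grids for the set's site count.
#' @return A `data.frame` with columns `meth_bin`, `stoch_bin`, `count`
#'   (occupied cells only).
#' @export
methStochGrid <- function(rv, methBreaks = NULL, stochBreaks = NULL) {
    n <- ncol(rv@states)
    meth <- readMethylation(rv)
    stoch <- readStochasticity(rv)
    if (is.null(methBreaks)) {
        mb <- round(meth * n)
        meth <- mb / n
    } else meth <- methBreaks[
        pmax(pmin(findInterval(meth, methBreaks), length(methBreaks)), 1L)]
    if (is.null(stochBreaks)) {
        sb <- round(stoch * (n - 1L))
        stoch <- sb / (n - 1L)
    } else stoch <- stochBreaks[
        pmax(pmin(findInterval(stoch, stochBreaks), length(stochBreaks)), 1L)]
    agg <- table(meth_bin = meth, stoch_bin = stoch)
    df <- as.data.frame(agg, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0L, , drop = FALSE]
    data.frame(meth_bin = as.numeric(df$meth_bin),
               stoch_bin = as.numeric(df$stoch_bin),
               count = df$Freq, row.names = NULL)
}

#' Aggregate region features to whole elements
#'
#' Filters regions to those with at least `minReads` reads and mean read
#' methylation of at least `minMeth` (excluding unmethylated background),
#' then averages the features of the surviving regions within each element,
#' unweighted. Elements with fewer than `minRegions` surviving regions are
#' dropped.
#'
#' @param regionTable data.frame from [regionFeaturesTable()].
#' @param minMeth minimum region mean methylation (default 0.10).
#' @param minReads minimum reads per region (default 4).
#' @param minRegions minimum surviving regions per element (default 2).
#' @return A `data.frame` with one row per surviving element: `element_id`,
#'   `n_regions_used` and the four averaged features.
#' @export
aggregateElements <- function(regionTable, minMeth = 0.10, minReads = 4L,
                              minRegions = 2L) {
    ok <- regionTable$n_reads >= minReads &
        regionTable$mean_read_meth >= minMeth
    rt <- regionTable[ok, , drop = FALSE]
    groups <- split(seq_len(nrow(rt)), rt$element_id)
    groups <- groups[lengths(groups) >= minRegions]
    featCols <- c("mean_read_meth", "sd_read_meth", "mean_stochasticity",
                  "sd_site_meth")
    out <- data.frame(
        element_id = names(groups),
        n_regions_used = lengths(groups), row.names = NULL)
    for (f in featCols)
        out[[f]] <- vapply(groups, function(idx) mean(rt[[f]][idx]),
                           numeric(1))
    out
}

#' Select hypermethylated regions between two samples
#'
#' Region ids whose mean read methylation increases by strictly more than
#' `delta` from sample A to sample B (regions must be defined identically in
#' both samples; ids present in only one sample are skipped).
#'
#' @param tableA,tableB region feature tables from [regionFeaturesTable()].
#' @param delta minimum methylation increase (default 0.10, i.e. the >10%
#'   hypermethylation filter).
#' @return Character vector of region ids.
#' @export
selectHypermethylated <- function(tableA, tableB, delta = 0.10) {
    common <- intersect(tableA$region_id, tableB$region_id)
    a <- tableA$mean_read_meth[match(common, tableA$region_id)]
    b <- tableB$mean_read_meth[match(common, tableB$region_id)]
    common[b - a > delta]
}

#' Simple linear regression of one feature on another
#'
#' Ordinary least-squares simple regression, as used for the among-site
#' versus read-methylation SD comparison at the whole-element level.
#'
#' @param x,y numeric vectors of equal length (>= 3 points).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
featureRegression <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    if (.popSD(y) == 0)
        return(list(slope = 0, intercept = mean(y), r_squared = 0,
                    p_value = NA_real_))
    fit <- lm(y ~ x)
    ## an exact fit is a legitimate input; summary.lm warns about it
    s <- suppressWarnings(summary(fit))
    slope <- unname(coef(fit)[2L])
    if (is.na(slope)) slope <- 0
    r2 <- s$r.squared
    if (!is.finite(r2)) r2 <- 0
    pv <- if (nrow(s$coefficients) < 2L) NA_real_ else
        s$coefficients[2L, 4L]
    list(slope = slope,
         intercept = unname(coef(fit)[1L]),
         r_squared = r2,
         p_value = pv)
}
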