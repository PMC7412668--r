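#' Simulate a region under the stochastic (per-site Bernoulli) null
#'
#' The null model against which the observed feature distributions are
#' compared: every site of every read is methylated independently with
#' probability `p`, the region's mean methylation. (The original description
#' calls this a "Poisson model of single-C sites"; the stated chance
#' mechanism — an equal per-site, per-read methylation probability — is an
#' independent Bernoulli draw per cell of the read-by-site matrix, which is
#' what is implemented.)
#'
#' @param p per-site methylation probability in \[0, 1\].
#' @param nSites sites per region (>= 2).
#' @param nReads reads to simulate (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return A [ReadVectorSet-class] with `nReads` vectors.
#' @export
simulateNullRegion <- function(p, nSites = 5L, nReads = 10L, seed = NULL) {
    stopifnot(p >= 0, p <= 1, nReads >= 1L, nSites >= 2L)
    if (!is.null(seed)) set.seed(seed)
    states <- matrix(rbinom(nReads * nSites, 1L, p), nrow = nReads)
    ReadVectorSet(states, regionId = rep("null", nReads))
}

#' Closed-form expectations under the Bernoulli null
#'
#' For independent per-site, per-read methylation at probability `p`:
#' expected mean read methylation is `p`; expected read stochasticity is
#' `2 p (1 - p)` (each adjacent pair differs with that probability); and the
#' asymptotic (many-read) SD of read methylation is
#' `sqrt(p (1 - p) / n_sites)`, the binomial SD of a read mean.
#'
#' @param p per-site methylation probability.
#' @param nSites sites per region.
#' @return List with `mean_read_meth`, `mean_stochasticity`, `sd_read_meth`.
#' @examples
#' nullExpectations(0.5, 5)  # 0.5, 0.5, 0.2236
#' @export
nullExpectations <- function(p, nSites = 5L) {
    stopifnot(p >= 0, p <= 1)
    list(mean_read_meth = p,
         mean_stochasticity = 2 * p * (1 - p),
         sd_read_meth = sqrt(p * (1 - p) / nSites))
}

#' Matched null feature distribution for observed regions
#'
#' Simulates, for each observed region, `replicates` null regions matched in
#' methylation level (`p` = the observed mean read methylation), site count,
#' and read count — so finite-sample inflation of the SD features is shared
#' between observed and null — and computes features through the same code
#' path as the observed data.
#'
#' @param regionTable data.frame from [regionFeaturesTable()].
#' @param nSites sites per region (must match the table's regions).
#' @param seed integer seed.
#' @param replicates simulated regions per observed region (default 1).
#' @return A `data.frame` of the same feature columns with `null = TRUE`.
#' @export
nullFeatureDistribution <- function(regionTable, nSites = 5L, seed = 1L,
                                    replicates = 1L) {
    set.seed(seed)
    rows <- vector("list", nrow(regionTable) * replicates)
    k <- 0L
    for (i in seq_len(nrow(regionTable))) {
        for (r in seq_len(replicates)) {
            rv <- simulateNullRegion(regionTable$mean_read_meth[i], nSites,
                                     regionTable$n_reads[i])
            f <- regionFeatures(rv, minReads = 1L)
            k <- k + 1L
            rows[[k]] <- data.frame(
                region_id = paste0(regionTable$region_id[i], ".null", r),
                source_region = regionTable$region_id[i],
                n_reads = f$n_reads, mean_read_meth = f$mean_read_meth,
                sd_read_meth = f$sd_read_meth,
                mean_stochasticity = f$mean_stochasticity,
                sd_site_meth = f$sd_site_meth, null = TRUE)
        }
    }
    do.call(rbind, rows)
}
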