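#' @import methods
#' @importFrom stats lm coef density rbinom runif rpois sd setNames
#' @importFrom utils write.table read.table head
NULL

#' Per-read binary methylation vectors for a set of regions
#'
#' Container for the single-read methylation calls underlying all downstream
#' feature computation. Each row of `states` is one read restricted to the
#' sites of one region: 1 = methylated (unconverted C), 0 = unmethylated
#' (bisulfite-converted). All regions in one set share the same number of
#' sites, so the calls form a dense read-by-site matrix.
#'
#' @slot states integer matrix, reads x sites, entries in \{0, 1\}.
#' @slot regionId character, region identifier per row.
#' @slot readId character, read identifier per row.
#'
#' @seealso [extractReadVectors()], [regionFeaturesTable()]
#' @export
setClass("ReadVectorSet",
    representation(states = "matrix", regionId = "character",
                   readId = "character"))

setValidity("ReadVectorSet", function(object) {
    msg <- NULL
    st <- object@states
    if (ncol(st) < 2L)
        msg <- c(msg, "states must have at least 2 site columns")
    if (length(st) && !all(st %in% c(0L, 1L)))
        msg <- c(msg, "states must be binary (0/1)")
    if (nrow(st) != length(object@regionId) ||
        nrow(st) != length(object@readId))
        msg <- c(msg, "regionId/readId lengths must match nrow(states)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a ReadVectorSet
#'
#' @param states binary matrix (reads x sites).
#' @param regionId,readId character vectors, one entry per row of `states`.
#' @return A [ReadVectorSet-class] object.
#' @examples
#' rv <- ReadVectorSet(rbind(c(1, 0, 1, 0, 1), c(1, 1, 1, 1, 1)),
#'                     regionId = c("r1", "r1"), readId = c("a", "b"))
#' readScores(rv)
#' @export
ReadVectorSet <- function(states,
                          regionId = rep(NA_character_, nrow(states)),
                          readId = paste0("read", seq_len(nrow(states)))) {
    states <- matrix(as.integer(states), nrow = nrow(states),
                     ncol = ncol(states))
    new("ReadVectorSet", states = states,
        regionId = as.character(regionId), readId = as.character(readId))
}

#' Fitted linear pattern-score model
#'
#' An ordinary least-squares fit of a 0/1 class label (0 = DRM2-like,
#' 1 = CMT2-like) on region methylation-variation features, together with the
#' affine scaling that maps the raw linear predictor onto the \[0, 1\]
#' pattern score. `scaleLow`/`scaleHigh` are the min/max raw fitted values on
#' the training data; scores of unseen data are clipped into \[0, 1\].
#'
#' @slot featureNames character, features used (subset of
#'   `mean_read_meth`, `sd_read_meth`, `mean_stochasticity`, `sd_site_meth`).
#' @slot coefficients numeric, named OLS coefficients (per feature).
#' @slot intercept numeric(1), OLS intercept.
#' @slot scaleLow,scaleHigh numeric(1), raw-score bounds used for scaling.
#' @slot perFeatureR2 numeric, marginal (single-feature) r-squared per feature.
#'
#' @seealso [fitPatternModel()], [patternScore()]
#' @export
setClass("PatternModel",
    representation(featureNames = "character", coefficients = "numeric",
                   intercept = "numeric", scaleLow = "numeric",
                   scaleHigh = "numeric", perFeatureR2 = "numeric"))

setValidity("PatternModel", function(object) {
    msg <- NULL
    if (!identical(names(object@coefficients), object@featureNames))
        msg <- c(msg, "coefficient names must equal featureNames")
    if (length(object@scaleLow) != 1L || length(object@scaleHigh) != 1L ||
        !(object@scaleLow < object@scaleHigh))
        msg <- c(msg, "scaleLow must be < scaleHigh")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ReadVectorSet-class number of read vectors
#' @param x,object a `ReadVectorSet`
#' @export
setMethod("length", "ReadVectorSet", function(x) nrow(x@states))

setMethod("show", "ReadVectorSet", function(object) {
    cat("ReadVectorSet:", nrow(object@states), "read vectors over",
        ncol(object@states), "sites in",
        length(unique(object@regionId)), "region(s)\n")
    if (nrow(object@states)) {
        sc <- readScores(object)
        cat("  score range:", min(sc), "-", max(sc), "\n")
    }
})

setMethod("show", "PatternModel", function(object) {
    cat("PatternModel (OLS linear probability classifier)\n")
    cat("  features:  ", paste(object@featureNames, collapse = ", "), "\n")
    co <- c(`(intercept)` = object@intercept, object@coefficients)
    cat("  raw model: ", paste(sprintf("%s=%.4g", names(co), co),
                               collapse = ", "), "\n")
    cat(sprintf("  score scaling: (raw - %.4g) / %.4g, clipped to [0,1]\n",
                object@scaleLow, object@scaleHigh - object@scaleLow))
    cat("  marginal r2:", paste(sprintf("%s=%.3f", object@featureNames,
                                        object@perFeatureR2),
                                collapse = ", "), "\n")
})
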