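#' @rdname readFeatures
#' @export
setGeneric("readScores", function(x) standardGeneric("readScores"))

#' @rdname readFeatures
#' @export
setGeneric("readMethylation", function(x) standardGeneric("readMethylation"))

#' Per-read features: score, methylation fraction and stochasticity
#'
#' `readScores` counts methylated sites per read; `readMethylation` is the
#' score divided by the number of sites; `readStochasticity` is the fraction
#' of adjacent site pairs within a read whose methylation states differ
#' (0 = a contiguous block, 1 = perfect alternation).
#'
#' @param x a [ReadVectorSet-class], a binary matrix (reads x sites), or for
#'   `readStochasticity` a single binary vector of length >= 2.
#' @return numeric vector, one value per read.
#' @examples
#' readStochasticity(c(1, 1, 0, 0, 0))  # one change out of four -> 0.25
#' @rdname readFeatures
#' @export
setGeneric("readStochasticity",
           function(x) standardGeneric("readStochasticity"))

#' @rdname patternScore
#' @export
setGeneric("patternScore",
           function(model, features) standardGeneric("patternScore"))
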