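.FEATURES <- c("mean_read_meth", "sd_read_meth", "mean_stochasticity",
               "sd_site_meth")

#' Fit the pattern-score classifier
#'
#' Fits an ordinary least-squares linear probability model of the class label
#' (0 = DRM2-like, 1 = CMT2-like) on region methylation-variation features,
#' after filtering both classes to regions with mean read methylation of at
#' least `minMeth`. The raw linear predictor is then affinely rescaled using
#' its min/max over the training data so that training scores span \[0, 1\]
#' — the pattern score. Constant (singular) features are dropped with a
#' warning. The marginal (single-feature) r-squared of each feature is
#' recorded; in the two-regime setting the read-methylation SD is typically
#' the strongest single predictor.
#'
#' @param features0,features1 region feature tables (data.frames from
#'   [regionFeaturesTable()] or [simulateRegimeFeatures()]) for class 0
#'   (DRM2-like) and class 1 (CMT2-like).
#' @param featureNames features to use (default all four).
#' @param minMeth minimum region mean methylation (default 0.10).
#' @return A [PatternModel-class].
#' @export
fitPatternModel <- function(features0, features1, featureNames = .FEATURES,
                            minMeth = 0.10) {
    featureNames <- match.arg(featureNames, .FEATURES, several.ok = TRUE)
    f0 <- features0[features0$mean_read_meth >= minMeth, , drop = FALSE]
    f1 <- features1[features1$mean_read_meth >= minMeth, , drop = FALSE]
    if (nrow(f0) == 0L || nrow(f1) == 0L)
        stop("both classes must be non-empty after the methylation filter")
    X <- rbind(f0[, featureNames, drop = FALSE],
               f1[, featureNames, drop = FALSE])
    y <- c(rep(0, nrow(f0)), rep(1, nrow(f1)))
    const <- vapply(X, function(v) .popSD(v) == 0, logical(1))
    if (any(const)) {
        warning("dropping constant feature(s): ",
                paste(featureNames[const], collapse = ", "))
        featureNames <- featureNames[!const]
        X <- X[, featureNames, drop = FALSE]
        if (ncol(X) == 0L) stop("no non-constant features left")
    }
    fit <- lm(y ~ ., data = cbind(X, y = y))
    beta <- coef(fit)
    raw <- fit$fitted.values
    r2 <- vapply(featureNames, function(f) {
        r <- suppressWarnings(stats::cor(X[[f]], y))
        if (is.na(r)) 0 else r^2
    }, numeric(1))
    new("PatternModel", featureNames = featureNames,
        coefficients = setNames(unname(beta[featureNames]), featureNames),
        intercept = unname(beta[1L]),
        scaleLow = min(raw), scaleHigh = max(raw), perFeatureR2 = r2)
}

#' Pattern score of regions or elements
#'
#' Applies a fitted [PatternModel-class]: the raw linear predictor
#' `intercept + sum(coef * feature)` is mapped through the model's training
#' min/max scaling and clipped into \[0, 1\]. Low scores indicate DRM2-like
#' methylation patterns, high scores CMT2-like patterns; data outside the
#' training range (e.g. other species) is clipped to the endpoints.
#'
#' @param model a fitted [PatternModel-class].
#' @param features a data.frame containing the model's feature columns.
#' @return Numeric vector of scores in \[0, 1\].
#' @rdname patternScore
#' @export
setMethod("patternScore", signature("PatternModel", "data.frame"),
    function(model, features) {
        missing <- setdiff(model@featureNames, colnames(features))
        if (length(missing))
            stop("missing feature(s): ", paste(missing, collapse = ", "))
        X <- as.matrix(features[, model@featureNames, drop = FALSE])
        raw <- model@intercept + drop(X %*% model@coefficients)
        pmin(pmax((raw - model@scaleLow) /
                      (model@scaleHigh - model@scaleLow), 0), 1)
    })

#' Score whole elements
#'
#' Applies the pattern score to element-level feature summaries (the
#' unweighted means of each element's surviving regions).
#'
#' @param model a fitted [PatternModel-class].
#' @param elements data.frame from [aggregateElements()].
#' @return `elements` with an added `pattern_score` column.
#' @export
scoreElements <- function(model, elements) {
    elements$pattern_score <- patternScore(model, elements)
    elements
}

#' Receiver operating characteristic curve
#'
#' Threshold sweep over the unique scores (predict class 1 when
#' score >= threshold), yielding a monotone (FPR, TPR) curve from (0, 0) to
#' (1, 1); AUC by the trapezoid rule. Tied scores move along the curve
#' jointly, so constant scores give the chance diagonal (AUC 0.5).
#'
#' @param scores numeric scores (higher = more class-1-like).
#' @param labels 0/1 labels (both classes present).
#' @return List with `fpr`, `tpr` (numeric vectors) and `auc`.
#' @export
rocCurve <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L)
        stop("labels must contain both 0 and 1")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; y <- labels[o]
    np <- sum(y == 1L); nn <- sum(y == 0L)
    ## cumulative counts at each distinct threshold
    last <- which(!duplicated(s, fromLast = TRUE))
    tpr <- c(0, cumsum(y == 1L)[last] / np)
    fpr <- c(0, cumsum(y == 0L)[last] / nn)
    auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
    list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Kernel-density peak analysis of pattern scores
#'
#' Gaussian kernel density estimate of a score distribution on a fixed grid
#' over \[0, 1\], with Scott's rule-of-thumb bandwidth `sd(x) * n^(-1/5)`,
#' followed by peak calling: local maxima of the density (grid endpoints
#' included) whose topographic prominence — height above the deepest saddle
#' separating the maximum from higher ground — is at least `prominence`
#' times the global maximum. Using prominence rather than raw height keeps
#' small bandwidth wiggles on the flank of a single mode from being counted
#' as separate peaks. One peak indicates a single methylation-pattern signal
#' (one dominant enzyme); two peaks indicate the presence of both DRM2-like
#' and CMT2-like signals.
#'
#' @param values numeric scores (>= 10 values required).
#' @param gridN grid resolution over \[0, 1\] (default 512).
#' @param prominence minimum peak height as a fraction of the maximum
#'   density (default 0.05).
#' @param bw optional bandwidth override.
#' @return List with `x`, `density` (the grid and KDE), `n_peaks`, and
#'   `peaks` (score locations of the called peaks).
#' @export
kdePeaks <- function(values, gridN = 512L, prominence = 0.05, bw = NULL) {
    if (length(values) < 10L)
        stop("at least 10 values are required for peak analysis")
    if (is.null(bw)) bw <- sd(values) * length(values)^(-1 / 5)
    bw <- max(bw, 1e-4)
    d <- density(values, bw = bw, kernel = "gaussian", from = 0, to = 1,
                 n = gridN)
    y <- d$y
    n <- length(y)
    isMax <- logical(n)
    isMax[1L] <- y[1L] > y[2L]
    isMax[n] <- y[n] > y[n - 1L]
    mid <- 2:(n - 1L)
    isMax[mid] <- y[mid] > y[mid - 1L] & y[mid] >= y[mid + 1L]
    ## topographic prominence: walk outward until higher ground (or the
    ## grid edge); the key saddle is the higher of the two side minima
    prom <- vapply(which(isMax), function(i) {
        sideMin <- function(idx) {
            m <- Inf
            for (j in idx) {
                if (y[j] > y[i]) return(m)
                m <- min(m, y[j])
            }
            m
        }
        leftMin <- if (i > 1L) sideMin((i - 1L):1L) else Inf
        rightMin <- if (i < n) sideMin((i + 1L):n) else Inf
        saddles <- c(leftMin, rightMin)[is.finite(c(leftMin, rightMin))]
        y[i] - if (length(saddles)) max(saddles) else 0
    }, numeric(1))
    keep <- which(isMax)[prom >= prominence * max(y)]
    list(x = d$x, density = y, n_peaks = length(keep), peaks = d$x[keep])
}

#' Write / read a pattern model as plain text
#'
#' Key/value serialisation of a [PatternModel-class] (feature names,
#' coefficients, intercept, scale bounds, marginal r-squared).
#'
#' @param model a [PatternModel-class].
#' @param path file path.
#' @return `writePatternModel` returns `path` invisibly; `readPatternModel`
#'   returns the model.
#' @export
writePatternModel <- function(model, path) {
    lines <- c(
        paste0("features\t", paste(model@featureNames, collapse = ",")),
        paste0("coefficients\t",
               paste(format(model@coefficients, digits = 17),
                     collapse = ",")),
        paste0("intercept\t", format(model@intercept, digits = 17)),
        paste0("scale_low\t", format(model@scaleLow, digits = 17)),
        paste0("scale_high\t", format(model@scaleHigh, digits = 17)),
        paste0("per_feature_r2\t",
               paste(format(model@perFeatureR2, digits = 17),
                     collapse = ",")))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writePatternModel
#' @export
readPatternModel <- function(path) {
    kv <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                     col.names = c("key", "value"))
    val <- setNames(kv$value, kv$key)
    feats <- strsplit(val[["features"]], ",")[[1]]
    co <- as.numeric(strsplit(val[["coefficients"]], ",")[[1]])
    r2 <- as.numeric(strsplit(val[["per_feature_r2"]], ",")[[1]])
    new("PatternModel", featureNames = feats,
        coefficients = setNames(co, feats),
        intercept = as.numeric(val[["intercept"]]),
        scaleLow = as.numeric(val[["scale_low"]]),
        scaleHigh = as.numeric(val[["scale_high"]]),
        perFeatureR2 = setNames(r2, feats))
}
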