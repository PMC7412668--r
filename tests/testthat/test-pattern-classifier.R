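mkFeatures <- function(n, sdRead, seed = 1) {
    set.seed(seed)
    data.frame(mean_read_meth = runif(n, 0.2, 0.6),
               sd_read_meth = sdRead + runif(n, 0, 0.02),
               mean_stochasticity = runif(n, 0.2, 0.5),
               sd_site_meth = runif(n, 0, 0.2))
}

test_that("perfectly separated single-feature classes give training AUC 1", {
    f0 <- mkFeatures(30, 0.45, seed = 1)
    f1 <- mkFeatures(30, 0.10, seed = 2)
    m <- fitPatternModel(f0, f1, featureNames = "sd_read_meth")
    sc <- patternScore(m, rbind(f0, f1))
    r <- rocCurve(sc, rep(c(0, 1), each = 30))
    expect_equal(r$auc, 1.0)
    expect_gte(min(sc), 0); expect_lte(max(sc), 1)
})

test_that("labels independent of features give near-zero marginal r2", {
    set.seed(33)
    f <- mkFeatures(400, 0.2, seed = 3)
    idx <- sample(400, 200)
    m <- fitPatternModel(f[idx, ], f[-idx, ], minMeth = 0)
    expect_true(all(m@perFeatureR2 < 0.02))
})

test_that("read-SD-dominant regimes make sd_read_meth the top predictor", {
    ## class 0: per-site Bernoulli(p); class 1: mixture of fully methylated
    ## reads and background reads drawn at the same p, so the per-read
    ## mixture inflates read SD while stochasticity stays comparable
    set.seed(71)
    drawRegion <- function(bimodal) {
        p <- runif(1, 0.25, 0.45)
        st <- matrix(rbinom(50 * 5, 1, p), 50)
        if (bimodal) st[runif(50) < 0.3, ] <- 1L
        f <- regionFeatures(st, minReads = 1)
        data.frame(mean_read_meth = f$mean_read_meth,
                   sd_read_meth = f$sd_read_meth,
                   mean_stochasticity = f$mean_stochasticity,
                   sd_site_meth = f$sd_site_meth)
    }
    f0 <- do.call(rbind, replicate(250, drawRegion(FALSE), simplify = FALSE))
    f1 <- do.call(rbind, replicate(250, drawRegion(TRUE), simplify = FALSE))
    m <- fitPatternModel(f0, f1, minMeth = 0)
    expect_equal(names(which.max(m@perFeatureR2)), "sd_read_meth")
})

test_that("constant features are dropped with a warning", {
    f0 <- mkFeatures(20, 0.4, seed = 4); f1 <- mkFeatures(20, 0.1, seed = 5)
    f0$sd_site_meth <- 0.1; f1$sd_site_meth <- 0.1
    expect_warning(m <- fitPatternModel(f0, f1), "constant")
    expect_false("sd_site_meth" %in% m@featureNames)
})

test_that("scores hit the scaling endpoints and clip outside them", {
    f0 <- mkFeatures(25, 0.4, seed = 6); f1 <- mkFeatures(25, 0.1, seed = 7)
    m <- fitPatternModel(f0, f1)
    tr <- rbind(f0, f1)
    sc <- patternScore(m, tr)
    expect_equal(min(sc), 0); expect_equal(max(sc), 1)
    # push a feature far outside the training range: still inside [0, 1]
    extreme <- tr[1:2, ]
    extreme$sd_read_meth <- c(-5, 5)
    scx <- patternScore(m, extreme)
    expect_true(all(scx >= 0 & scx <= 1))
    expect_error(patternScore(m, tr[, -2]), "missing feature")
})

test_that("raw scores are monotone in each feature's coefficient sign", {
    f0 <- mkFeatures(50, 0.4, seed = 8); f1 <- mkFeatures(50, 0.1, seed = 9)
    m <- fitPatternModel(f0, f1)
    base <- f0[1, ]
    for (f in m@featureNames) {
        up <- base; up[[f]] <- up[[f]] + 0.1
        rawDelta <- 0.1 * m@coefficients[[f]]
        raw <- function(x) m@intercept +
            sum(m@coefficients * unlist(x[m@featureNames]))
        expect_equal(raw(up) - raw(base), rawDelta, tolerance = 1e-9)
    }
})

test_that("ROC handles hand-built, degenerate, and tied cases", {
    r <- rocCurve(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
    expect_equal(r$auc, 0.75)
    expect_equal(rocCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
    expect_equal(rocCurve(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
    expect_error(rocCurve(1:3, c(1, 1, 1)), "both")
    # curve monotone non-decreasing in both axes
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("trapezoid AUC equals the Mann-Whitney pair-counting oracle", {
    set.seed(17)
    for (i in 1:50) {
        n <- sample(4:50, 1)
        labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
        scores <- round(runif(n), 1)   # coarse grid forces ties
        expect_equal(rocCurve(scores, labels)$auc,
                     aucByPairs(scores, labels))
    }
})

test_that("AUC agrees with an independent ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(19)
    scores <- round(runif(200), 2)
    labels <- rbinom(200, 1, plogis(4 * scores - 2))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
    expect_equal(rocCurve(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("KDE peak calling separates mixtures from single modes", {
    set.seed(23)
    single <- pmin(pmax(rnorm(300, 0.5, 0.02), 0), 1)
    expect_equal(kdePeaks(single)$n_peaks, 1L)
    mix <- pmin(pmax(c(rnorm(200, 0.1, 0.04), rnorm(200, 0.9, 0.04)), 0), 1)
    pk <- kdePeaks(mix)
    expect_equal(pk$n_peaks, 2L)
    expect_equal(sort(pk$peaks), c(0.1, 0.9), tolerance = 0.1)
    # permutation invariance and the minimum-value contract
    expect_equal(kdePeaks(sample(mix))$n_peaks, 2L)
    expect_error(kdePeaks(runif(9)), "10")
})

test_that("a pattern model round-trips through its text serialisation", {
    f0 <- mkFeatures(25, 0.4, seed = 10)
    f1 <- mkFeatures(25, 0.1, seed = 11)
    m <- fitPatternModel(f0, f1)
    p <- tempfile(fileext = ".txt")
    writePatternModel(m, p)
    m2 <- readPatternModel(p)
    expect_equal(m2@coefficients, m@coefficients)
    expect_equal(m2@scaleLow, m@scaleLow)
    expect_equal(patternScore(m2, f0), patternScore(m, f0))
})

test_that("scored synthetic elements separate the two regimes", {
    tr0 <- simulateRegimeFeatures(400, "drm2_like", seed = 31)
    tr1 <- simulateRegimeFeatures(400, "cmt2_like", seed = 32)
    m <- fitPatternModel(tr0, tr1)
    # element summaries: average pairs of regions of the same regime
    mkElements <- function(ft, tag) {
        idx <- matrix(seq_len(nrow(ft)), ncol = 2, byrow = TRUE)
        data.frame(element_id = paste0(tag, seq_len(nrow(idx))),
                   n_regions_used = 2L,
                   mean_read_meth = (ft$mean_read_meth[idx[, 1]] +
                                         ft$mean_read_meth[idx[, 2]]) / 2,
                   sd_read_meth = (ft$sd_read_meth[idx[, 1]] +
                                       ft$sd_read_meth[idx[, 2]]) / 2,
                   mean_stochasticity =
                       (ft$mean_stochasticity[idx[, 1]] +
                            ft$mean_stochasticity[idx[, 2]]) / 2,
                   sd_site_meth = (ft$sd_site_meth[idx[, 1]] +
                                       ft$sd_site_meth[idx[, 2]]) / 2)
    }
    e0 <- scoreElements(m, mkElements(
        simulateRegimeFeatures(200, "drm2_like", seed = 33), "d"))
    e1 <- scoreElements(m, mkElements(
        simulateRegimeFeatures(200, "cmt2_like", seed = 34), "c"))
    r <- rocCurve(c(e0$pattern_score, e1$pattern_score),
                  rep(c(0, 1), c(nrow(e0), nrow(e1))))
    expect_gte(r$auc, 0.95)
    expect_equal(kdePeaks(c(e0$pattern_score, e1$pattern_score))$n_peaks, 2L)
    expect_equal(kdePeaks(e1$pattern_score)$n_peaks, 1L)
})
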