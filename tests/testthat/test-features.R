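test_that("stochasticity counts adjacent state changes", {
    expect_equal(readStochasticity(c(1, 0, 1, 0, 1)), 1.0)
    expect_equal(readStochasticity(c(1, 1, 1, 1, 1)), 0.0)
    expect_equal(readStochasticity(c(1, 1, 0, 0, 0)), 0.25)
    expect_error(readStochasticity(matrix(1, 1, 1)), "2 sites")
})

test_that("region features match hand computation with population SDs", {
    f <- regionFeatures(rbind(rep(1, 5), rep(0, 5)), minReads = 2)
    expect_equal(f$mean_read_meth, 0.5)
    expect_equal(f$sd_read_meth, 0.5)       # population SD of {1, 0}
    expect_equal(f$mean_stochasticity, 0.0)
    expect_equal(f$sd_site_meth, 0.0)       # every site at 0.5

    f2 <- regionFeatures(matrix(rep(c(1, 0, 1, 0, 1), each = 4), nrow = 4))
    expect_equal(f2$mean_read_meth, 0.6)
    expect_equal(f2$sd_read_meth, 0.0)
    expect_equal(f2$mean_stochasticity, 1.0)

    expect_null(regionFeatures(matrix(1, 3, 5), minReads = 4))
})

test_that("feature values stay in range for all 32 exhaustive inputs", {
    pat <- allPatterns5()
    for (i in seq_len(32)) {
        f <- regionFeatures(pat[i, , drop = FALSE], minReads = 1)
        expect_gte(f$mean_read_meth, 0); expect_lte(f$mean_read_meth, 1)
        expect_gte(f$mean_stochasticity, 0)
        expect_lte(f$mean_stochasticity, 1)
        expect_gte(f$sd_site_meth, 0); expect_lte(f$sd_site_meth, 0.5)
    }
    fAll <- regionFeatures(pat, minReads = 1)
    expect_equal(fAll$mean_read_meth, 0.5)
    expect_equal(fAll$sd_site_meth, 0)
})

test_that("read SD is invariant to read order; site SD to site order", {
    set.seed(11)
    st <- matrix(rbinom(40, 1, 0.4), nrow = 8)
    f <- regionFeatures(st, minReads = 1)
    fr <- regionFeatures(st[sample(8), ], minReads = 1)
    fc <- regionFeatures(st[, sample(5)], minReads = 1)
    expect_equal(fr$sd_read_meth, f$sd_read_meth)
    expect_equal(fc$sd_site_meth, f$sd_site_meth)
})

test_that("read-state histogram respects region-methylation bins", {
    rv <- ReadVectorSet(allPatterns5(), regionId = rep("r1", 32))
    expect_equal(unname(readStateHistogram(rv)), choose(5, 0:5))
    rv0 <- ReadVectorSet(matrix(0L, 6, 5), regionId = rep("r1", 6))
    expect_equal(unname(readStateHistogram(rv0)), c(6, 0, 0, 0, 0, 0))
    # region mean 0.5 passes a 0.4 filter; all-zero region does not
    both <- ReadVectorSet(rbind(allPatterns5(), matrix(0L, 6, 5)),
                          regionId = rep(c("hi", "lo"), c(32, 6)))
    expect_equal(sum(readStateHistogram(both, minRegionMeth = 0.4)), 32)
})

test_that("methylation-stochasticity grid occupies only feasible cells", {
    one <- ReadVectorSet(matrix(c(1, 0, 1, 0, 1), 1), regionId = "r")
    g1 <- methStochGrid(one)
    expect_equal(g1, data.frame(meth_bin = 0.6, stoch_bin = 1, count = 1L))

    gAll <- methStochGrid(ReadVectorSet(allPatterns5(),
                                        regionId = rep("r", 32)))
    expect_true(all(gAll$stoch_bin[gAll$meth_bin == 1] == 0))
    expect_true(all(gAll$stoch_bin[gAll$meth_bin == 0] == 0))
    expect_equal(sum(gAll$count), 32L)

    ten <- ReadVectorSet(matrix(rep(c(1, 0), 5), 1), regionId = "r")
    g10 <- methStochGrid(ten)
    expect_equal(g10$meth_bin, 0.5)
    expect_equal(g10$stoch_bin, 1)
})

test_that("element aggregation applies the filter cascade", {
    rt <- data.frame(
        region_id = paste0("r", 1:5),
        element_id = c("e1", "e1", "e2", "e2", "e2"),
        n_reads = c(5, 6, 5, 5, 3),
        mean_read_meth = c(0.05, 0.5, 0.3, 0.4, 0.9),
        sd_read_meth = c(0.1, 0.2, 0.2, 0.4, 0.9),
        mean_stochasticity = c(0.1, 0.2, 0.3, 0.5, 0.9),
        sd_site_meth = c(0, 0.1, 0.1, 0.3, 0.9), gc = NA)
    agg <- aggregateElements(rt)
    # e1: one region below 10% methylation -> only one survivor -> dropped
    expect_equal(agg$element_id, "e2")
    # e2: low-read region excluded; features are unweighted means
    expect_equal(agg$n_regions_used, 2L)
    expect_equal(agg$sd_read_meth, 0.3)
    expect_equal(agg$mean_read_meth, 0.35)
})

test_that("hypermethylation selection is strict and id-matched", {
    ta <- data.frame(region_id = c("r1", "r2", "r3"),
                     mean_read_meth = c(0.20, 0.20, 0.5))
    tb <- data.frame(region_id = c("r1", "r2", "r4"),
                     mean_read_meth = c(0.35, 0.30, 0.9))
    expect_equal(selectHypermethylated(ta, tb), "r1")
})

test_that("simple regression matches the closed-form normal equations", {
    x <- c(0, 1, 2, 3); y <- c(1, 3, 2, 5)
    r <- featureRegression(x, y)
    slopeOracle <- sum((x - mean(x)) * (y - mean(y))) /
        sum((x - mean(x))^2)
    expect_equal(r$slope, slopeOracle)
    expect_equal(r$intercept, mean(y) - slopeOracle * mean(x))
    expect_equal(r$r_squared, stats::cor(x, y)^2)

    exact <- featureRegression(1:5, 1:5)
    expect_equal(exact$slope, 1); expect_equal(exact$r_squared, 1)
    flat <- featureRegression(1:5, rep(2, 5))
    expect_equal(flat$slope, 0); expect_equal(flat$r_squared, 0)
})
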