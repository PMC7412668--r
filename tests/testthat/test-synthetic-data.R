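test_that("expected-reads formula substitutes directly", {
    expect_equal(expectedReads(10, 30, 100), 7.0)
    expect_equal(expectedReads(10, 100, 100), 0.0)
    expect_equal(expectedReads(20, 50, 100), 10.0)
    expect_error(expectedReads(10, 150, 100))
    expect_error(expectedReads(0, 30, 100))
})

test_that("generated genomes hit the GC target and are reproducible", {
    gen <- generateGenome(2e4, gc = 0.5, seed = 4)
    expect_equal(gcContent(gen$genome[[1]]), 0.5, tolerance = 0.02)
    gen2 <- generateGenome(2e4, gc = 0.5, seed = 4)
    expect_identical(as.character(gen$genome), as.character(gen2$genome))
    f1 <- tempfile(); f2 <- tempfile()
    Biostrings::writeXStringSet(gen$genome, f1)
    Biostrings::writeXStringSet(gen2$genome, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("every generated element carries regions on both strands", {
    gen <- generateGenome(2e4, seed = 5)
    s <- findContextSites(gen$genome, gen$elements, "CHH")
    r <- buildRegions(s)
    perElementStrand <- table(r$element_id,
                              as.character(GenomicRanges::strand(r)))
    expect_equal(nrow(perElementStrand), length(gen$elements))
    expect_true(all(perElementStrand[, c("+", "-")] >= 1))
})

test_that("bisulfite encoding round-trips at p = 0 and p = 1", {
    gen <- generateGenome(5e3, seed = 6)
    s <- findContextSites(gen$genome, gen$elements, "CHH")
    reg <- buildRegions(s, genome = gen$genome)
    regime <- setNames(rep("cmt2_like", length(gen$elements)),
                       gen$elements$element_id)
    # p = 1 everywhere: region site bases survive as C (plus) / G (minus)
    sim1 <- simulateReads(gen$genome, reg, regime, coverage = 4,
                          pRange = c(1, 1), cwaBoost = 0, seed = 7)
    expect_true(all(unlist(strsplit(sim1$truth$states, "")) == "1"))
    rv1 <- extractReadVectors(reg, sim1$reads)
    expect_true(all(rv1@states == 1L))
    # p = 0: everything converted to T/A
    sim0 <- simulateReads(gen$genome, reg, regime, coverage = 4,
                          pRange = c(0, 0), cwaBoost = 0, seed = 8)
    expect_false(any(grepl("C", sim0$reads$seq[sim0$reads$bs_strand == "+"],
                           fixed = TRUE)))
    expect_false(any(grepl("G", sim0$reads$seq[sim0$reads$bs_strand == "-"],
                           fixed = TRUE)))
})

test_that("regime read mixtures have the designed score signatures", {
    gen <- generateGenome(2e4, seed = 9)
    s <- findContextSites(gen$genome, gen$elements, "CHH")
    reg <- buildRegions(s, genome = gen$genome)
    drm <- setNames(rep("drm2_like", length(gen$elements)),
                    gen$elements$element_id)
    # background probability 0: scores concentrate at 0 and n_sites
    sim <- simulateReads(gen$genome, reg, drm, coverage = 10,
                         pRange = c(0.4, 0.4), pBg = 0, seed = 10)
    rv <- extractReadVectors(reg, sim$reads)
    expect_setequal(unique(readScores(rv)), c(0, 5))
    # two-point mixture: sd of read methylation near sqrt(0.4 * 0.6) = 0.49
    m <- readMethylation(rv)
    expect_equal(sqrt(mean((m - mean(m))^2)), sqrt(0.4 * 0.6),
                 tolerance = 0.05)
    cmt <- setNames(rep("cmt2_like", length(gen$elements)),
                    gen$elements$element_id)
    simC <- simulateReads(gen$genome, reg, cmt, coverage = 10,
                          pRange = c(0.4, 0.4), cwaBoost = 0, seed = 11)
    rvC <- extractReadVectors(reg, simC$reads)
    expect_equal(mean(readStochasticity(rvC)), 2 * 0.4 * 0.6,
                 tolerance = 0.05)
})

test_that("fully-overlapping read counts match the coverage formula", {
    gen <- generateGenome(1e5, seed = 12)
    s <- findContextSites(gen$genome, gen$elements, "CHH")
    reg <- buildRegions(s, genome = gen$genome)
    expect_gte(length(reg), 100L)
    regime <- setNames(rep("cmt2_like", length(gen$elements)),
                       gen$elements$element_id)
    sim <- simulateReads(gen$genome, reg, regime, coverage = 10,
                         readLength = 100L, seed = 13)
    rv <- extractReadVectors(reg, sim$reads)
    observed <- table(factor(rv@regionId, reg$region_id))
    expected <- expectedReads(10, GenomicRanges::width(reg), 100)
    expect_equal(mean(observed), mean(expected), tolerance = 0.05)
})

test_that("written SAM is valid input for the alignment reader", {
    gen <- generateGenome(5e3, seed = 14)
    s <- findContextSites(gen$genome, gen$elements, "CHH")
    reg <- buildRegions(s, genome = gen$genome)
    regime <- setNames(rep("drm2_like", length(gen$elements)),
                       gen$elements$element_id)
    sim <- simulateReads(gen$genome, reg, regime, coverage = 3, seed = 15)
    p <- tempfile(fileext = ".sam")
    writeSam(sim$reads, gen$genome, p)
    back <- readBisulfiteAlignments(p, genome = gen$genome)
    expect_equal(nrow(back), nrow(sim$reads))
    o <- match(sim$reads$read_id, back$read_id)
    expect_equal(back$pos[o], sim$reads$pos)
    expect_equal(back$seq[o], sim$reads$seq)
    expect_equal(back$bs_strand[o], sim$reads$bs_strand)
})
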