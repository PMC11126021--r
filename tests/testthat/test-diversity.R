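test_that("Hill numbers hit their limiting cases", {
    ht <- noRareHaplotypes()               # 0.9 master + 10 x 0.01
    expect_equal(hillNumber(ht, 0), 11)
    expect_equal(hillNumber(ht, Inf), 1 / 0.9)
    # uniform assemblage: ^qD = H at every order
    flat <- flatQuasispecies(50, 4)
    for (q in c(0, 0.5, 1, 2, 4, Inf))
        expect_equal(hillNumber(flat, q), 50)
    # the Q.90.10 structure's master gives ^(Inf)D = 1/0.9
    expect_equal(hillNumber(singleDominant(1000, 0.9), Inf), 1 / 0.9,
                 tolerance = 1e-12)
    expect_error(hillNumber(ht, -1), ">= 0")
})

test_that("hillNumber is continuous at q = 1 (property)", {
    set.seed(13)
    for (i in 1:20) {
        ht <- randomTable()
        h1 <- hillNumber(ht, 1)
        expect_lt(abs(hillNumber(ht, 1 + 1e-6) - h1) / h1, 1e-6)
        expect_lt(abs(hillNumber(ht, 1 - 1e-6) - h1) / h1, 1e-6)
    }
})

test_that("diversity profiles are non-increasing in q (property)", {
    set.seed(14)
    for (i in 1:20) {
        prof <- diversityProfile(randomTable())
        expect_true(all(diff(prof@D) <= 1e-10))
        expect_equal(prof@D[1], unname(indexValues(prof)["richness"]))
        expect_equal(prof@D[length(prof@D)],
                     1 / unname(indexValues(prof)["master_frequency"]))
    }
})

test_that("Hill correspondences with classical indices hold to 1e-10", {
    set.seed(15)
    for (i in 1:20) {
        ht <- randomTable()
        expect_equal(hillNumber(ht, 1), exp(shannonEntropy(ht)),
                     tolerance = 1e-10)
        expect_equal(hillNumber(ht, 2), 1 / (1 - giniSimpson(ht)),
                     tolerance = 1e-10)
        expect_equal(hillNumber(ht, Inf), 1 / masterFrequency(ht),
                     tolerance = 1e-10)
    }
})

test_that("degenerate and uniform assemblages give textbook index values", {
    one <- HaplotypeTable("x", 9)
    expect_equal(shannonEntropy(one), 0)
    expect_equal(giniSimpson(one), 0)
    expect_equal(masterFrequency(one), 1)
    expect_identical(richness(one), 1L)

    n <- 128
    expect_equal(shannonEntropy(allSingletons(n)), log(n))
    expect_equal(shannonEntropy(allSingletons(n), base = 2), log2(n))
    expect_equal(masterFrequency(noRareHaplotypes()), 0.9)
})

test_that("singleton fraction counts single-read haplotypes over N", {
    expect_equal(singletonFraction(prominentHaplotypes()), 0.03077)
    expect_equal(singletonFraction(noRareHaplotypes()), 0)
    expect_equal(singletonFraction(allSingletons(500)), 1)
})

test_that("fractionBetween uses [lower, upper) bands (upper=1 inclusive)", {
    ht <- prominentHaplotypes()
    expect_equal(fractionBetween(ht, 0, 1), 1)
    # only the singletons (1e-5 each) sit below 1%
    expect_equal(fractionBetween(ht, 0, 0.01), 0.03077)
    # no-rare case: all minors at exactly 1%, excluded by the strict upper
    expect_equal(fractionBetween(noRareHaplotypes(), 0, 0.01), 0)
    expect_equal(fractionBetween(HaplotypeTable("x", 3), 0, 1), 1)
    expect_error(fractionBetween(ht, 0.5, 0.5), "lower < upper")

    # a disjoint cover of (0, 1] partitions the reads
    cuts <- c(0, 0.001, 0.01, 0.1, 0.5, 1)
    parts <- vapply(seq_len(length(cuts) - 1), function(i)
        fractionBetween(ht, cuts[i], cuts[i + 1]), numeric(1))
    expect_equal(sum(parts), 1, tolerance = 1e-12)
})

test_that("over1BelowTop isolates replicated non-prominent reads", {
    # benchmark composition: everything below the top 6 is a singleton
    expect_equal(over1BelowTop(prominentHaplotypes(), 6), 0)
    # [10,5,2,1,1], K=2: only the count-2 haplotype qualifies
    ht <- HaplotypeTable(letters[1:5], c(10, 5, 2, 1, 1))
    expect_equal(over1BelowTop(ht, 2), 2 / 19)
    # K=0 on a singleton-free table: all reads qualify
    expect_equal(over1BelowTop(flatQuasispecies(5, 3), 0), 1)
    expect_warning(val <- over1BelowTop(ht, 99), "exceeds")
    expect_equal(val, 0)
    # deterministic tie-break: count desc then id asc
    tie <- HaplotypeTable(c("b", "a", "c"), c(5, 5, 2))
    expect_equal(over1BelowTop(tie, 1), 7 / 12)  # "a" kept in top 1
})

test_that("sensitivity ranking reflects Hill-order weighting", {
    # balanced dominant + many singletons: the full expected ordering.
    # The Gini-Simpson vs master-frequency gap is a ~1/m plug-in bias, so
    # the library is kept small enough (B >> m) for a B-cycle median to
    # resolve it.
    ht <- singleDominant(1000, 0.5)
    rk <- sensitivityRank(ht, fractions = c(0.05, 0.1, 0.25, 0.5),
                          scheme = "with", B = 2000, seed = 1)
    expect_identical(as.character(rk),
        c("richness", "shannon", "gini_simpson", "master_frequency"))
    expect_true(all(diff(attr(rk, "bias")) <= 0))

    # all-singletons: richness loses the bootstrap 1 - 1/e share, far
    # beyond Shannon's bias
    rk2 <- sensitivityRank(allSingletons(2000), fractions = c(0.25, 0.5),
                           scheme = "with", B = 50, seed = 2)
    b2 <- attr(rk2, "bias")
    expect_gt(b2[["richness"]], 0.5)
    expect_gt(b2[["richness"]], b2[["shannon"]])

    # uniform two-haplotype table: master frequency is nearly unbiased
    rk3 <- sensitivityRank(HaplotypeTable(c("a", "b"), c(500, 500)),
                           fractions = 0.5, scheme = "with", B = 50,
                           seed = 3)
    expect_lt(attr(rk3, "bias")[["master_frequency"]], 0.05)

    expect_error(sensitivityRank(HaplotypeTable("x", 5)), "single-haplotype")
})
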