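test_that("full draw without replacement returns the sample itself", {
    ht <- prominentHaplotypes(counts = c(10, 5, 2), singletons = 3)
    set.seed(1)
    out <- subsampleWithoutReplacement(ht, totalReads(ht))
    expect_identical(readCounts(out), readCounts(ht))
})

test_that("without-replacement draws conserve m and are dominated", {
    set.seed(7)
    for (i in 1:30) {
        ht <- randomTable()
        N <- totalReads(ht)
        m <- sample.int(N, 1L)
        sub <- subsampleWithoutReplacement(ht, m)
        expect_identical(sum(readCounts(sub)), as.numeric(m))
        orig <- readCounts(ht)[haplotypeIds(sub)]
        expect_true(all(readCounts(sub) <= orig))
        expect_true(all(readCounts(sub) >= 1))
    }
})

test_that("with-replacement draws conserve m and may exceed N", {
    set.seed(8)
    for (i in 1:30) {
        ht <- randomTable()
        m <- sample.int(2L * totalReads(ht), 1L)
        sub <- subsampleWithReplacement(ht, m)
        expect_identical(sum(readCounts(sub)), as.numeric(m))
    }
    one <- HaplotypeTable("only", 3)
    expect_identical(unname(readCounts(subsampleWithReplacement(one, 17))),
                     17)
})

test_that("size bounds are enforced", {
    ht <- allSingletons(10)
    expect_error(subsampleWithoutReplacement(ht, 11), "cannot subsample")
    expect_error(subsampleWithoutReplacement(ht, 0), "m must be")
    expect_error(subsampleWithReplacement(ht, 0), "m must be")
})

test_that("rarefying an all-singletons sample yields exactly m haplotypes", {
    ht <- allSingletons(10000)
    set.seed(11)
    for (m in c(1L, 1000L, 9999L)) {
        sub <- subsampleWithoutReplacement(ht, m)
        expect_identical(nHaplotypes(sub), m)
        expect_true(all(readCounts(sub) == 1))
    }
})

test_that("counts [3,1], m=2: draw probabilities match enumeration", {
    # exhaustive: C(4,2)=6 subsets; P({2,0}) = 3/6, P({1,1}) = 3/6,
    # {0,2} impossible.
    ht <- HaplotypeTable(c("a", "b"), c(3, 1))
    mat <- drawCountMatrix(ht, 2L, "without", B = 20000L, seed = 5)
    expect_true(all(mat[, 2] <= 1))
    phat <- mean(mat[, 1] == 2)
    se <- sqrt(0.5 * 0.5 / 20000)
    expect_lt(abs(phat - 0.5), 4 * se)
})

test_that("counts [1,1], m=2 with replacement: P(one haplotype) = 1/2", {
    ht <- HaplotypeTable(c("a", "b"), c(1, 1))
    mat <- drawCountMatrix(ht, 2L, "with", B = 20000L, seed = 6)
    phat <- mean(rowSums(mat > 0) == 1)
    se <- sqrt(0.5 * 0.5 / 20000)
    expect_lt(abs(phat - 0.5), 4 * se)
})

test_that("repeatedSubsample is deterministic and summarizes correctly", {
    ht <- singleDominant(1000, 0.9)
    s1 <- repeatedSubsample(ht, fraction = 0.5, scheme = "with", B = 100,
                            seed = 42,
                            statistics = list(richness = richness,
                                              master = masterFrequency))
    s2 <- repeatedSubsample(ht, fraction = 0.5, scheme = "with", B = 100,
                            seed = 42,
                            statistics = list(richness = richness,
                                              master = masterFrequency))
    expect_identical(s1$median, s2$median)
    expect_identical(attr(s1, "cycles"), attr(s2, "cycles"))
    # a different seed moves the raw cycles
    s3 <- repeatedSubsample(ht, fraction = 0.5, scheme = "with", B = 100,
                            seed = 43,
                            statistics = list(richness = richness))
    expect_false(identical(attr(s1, "cycles")[, 1], attr(s3, "cycles")[, 1]))

    cyc <- attr(s1, "cycles")
    expect_true(all(s1$IQR >= 0) && all(s1$sd >= 0))
    for (j in 1:2) {
        expect_gte(s1$median[j], min(cyc[, j]))
        expect_lte(s1$median[j], max(cyc[, j]))
    }
    # median/IQR follow the interpolated-quantile convention
    expect_equal(s1$median[1], unname(stats::quantile(cyc[, 1], 0.5)))
    expect_equal(s1$IQR[1], unname(diff(stats::quantile(cyc[, 1],
                                                        c(0.25, 0.75)))))
})

test_that("a fixed-size statistic has zero spread without replacement", {
    ht <- prominentHaplotypes(counts = c(50, 25), singletons = 25)
    s <- repeatedSubsample(ht, fraction = 0.5, scheme = "without", B = 50,
                           seed = 1, statistics = list(N = totalReads))
    expect_identical(s$median, 50)
    expect_identical(s$sd, 0)
})

test_that("subsampled frequencies are unbiased over cycles (both schemes)", {
    ht <- singleDominant(2000, 0.6)
    B <- 500L
    for (scheme in c("without", "with")) {
        s <- repeatedSubsample(ht, fraction = 0.25, scheme = scheme, B = B,
                               seed = 99,
                               statistics = list(master = masterFrequency))
        tol <- 4 * s$sd / sqrt(B)
        expect_lt(abs(s$mean - 0.6), max(tol, 1e-3))
    }
})

test_that("statistic errors report the failing cycle", {
    ht <- allSingletons(50)
    boom <- function(t) stop("nope")
    expect_error(
        repeatedSubsample(ht, fraction = 0.5, B = 3, seed = 1,
                          statistics = list(bad = boom)),
        "cycle 1")
})

test_that("rarefyGroup rarefies all samples to a common size", {
    tabs <- list(big = allSingletons(2000), small = allSingletons(1000))
    res <- rarefyGroup(tabs, referenceSize = "min", B = 20, seed = 3,
                       statistics = list(richness = richness))
    expect_named(res, c("big", "small"))
    expect_identical(attr(res$big, "m"), 1000)
    expect_identical(attr(res$small, "m"), 1000)
    # without replacement, rarefying all-singletons gives exactly m always
    expect_identical(res$small$median, 1000)
    expect_identical(res$small$sd, 0)

    # a sample smaller than the reference is reported by name
    expect_error(
        rarefyGroup(tabs, referenceSize = 1500, B = 5),
        "small")

    # identical tables yield identical summaries under one master seed
    twin <- rarefyGroup(list(a = allSingletons(500), b = allSingletons(500)),
                        scheme = "with", B = 20, seed = 7)
    expect_identical(twin$a$median, twin$b$median)
})

test_that("summaries serialize to CSV and JSON with metadata", {
    ht <- allSingletons(200)
    s <- repeatedSubsample(ht, fraction = 0.5, scheme = "with", B = 10,
                           seed = 1)
    f <- withr::local_tempfile(fileext = ".csv")
    writeResamplingSummary(list(s1 = s), f)
    got <- read.csv(f)
    expect_identical(names(got),
        c("sample", "statistic", "scheme", "fraction", "m", "B",
          "median", "IQR", "sd", "mean"))
    expect_identical(got$m, 100L)
    j <- withr::local_tempfile(fileext = ".json")
    writeResamplingSummary(s, j, format = "json")
    expect_identical(jsonlite::read_json(j)[[1]]$B, 10L)
})
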