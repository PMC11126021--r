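## Orchestration: each function reproduces one benchmark result set as a
## data.frame (written to CSV by runAllTables or the CLI). Deterministic
## cells come from the closed forms; stochastic cells are B-cycle medians
## and carry their (B, seed, scheme) in the returned attributes.

.qsFractions <- c(0.5, 0.25, 0.1, 0.05)

#' Seen/unseen proportions when subsampling a fraction with replacement
#'
#' Evaluates the large-n limits: at fraction f, a with-replacement cycle
#' sees 1 - e^(-f) of the items and misses e^(-f). (Without replacement
#' the seen proportion is exactly f.)
#'
#' @param fractions Grid of subsampling fractions (default 0.1 to 1.0).
#' @param digits Rounding of the reported proportions (default 4).
#' @return data.frame with columns fraction, seen, unseen.
#' @examples
#' runTable1()
#' @export
runTable1 <- function(fractions = seq(0.1, 1, by = 0.1), digits = 4) {
    seen <- round(pSeenFraction(fractions), digits)
    data.frame(fraction = fractions, seen = seen,
               unseen = round(1 - pSeenFraction(fractions), digits))
}

#' All-singletons benchmark: richness under with-replacement subsampling
#'
#' For an all-singletons sample of n reads, subsampled with replacement at
#' a grid of fractions: the true richness of an m-read rarefied sample
#' (exactly m), the closed-form expectation n[1 - (1 - 1/n)^m], and the
#' median/IQR/SD of observed richness over B cycles, plus the proportion
#' of the subsample made of unique draws (median richness / m) and its
#' complement, the replicated proportion.
#'
#' @param n Sample size = number of singleton haplotypes (default 10,000).
#' @param fractions Subsampling fractions (default 0.1 to 1.0).
#' @param B Resampling cycles (default 500).
#' @param seed Master seed.
#' @return data.frame with columns fraction, true, expected, median, IQR,
#'   sd, unique, replicated.
#' @export
runTable2 <- function(n = 10000, fractions = seq(0.1, 1, by = 0.1),
                      B = 500L, seed = 1L) {
    ht <- allSingletons(n)
    rows <- lapply(fractions, function(f) {
        m <- round(n * f)
        s <- repeatedSubsample(ht, m = m, scheme = "with", B = B,
                               seed = seed,
                               statistics = list(richness = richness))
        data.frame(fraction = f, true = m,
                   expected = expectedRichnessWith(ht, m),
                   median = s$median, IQR = s$IQR, sd = s$sd,
                   unique = s$median / m, replicated = 1 - s$median / m)
    })
    out <- do.call(rbind, rows)
    attr(out, "B") <- B; attr(out, "seed") <- seed
    out
}

.sdStats <- list(richness = richness, master = masterFrequency)

#' Single-dominant benchmark: richness and master frequency
#'
#' For each master frequency (structures Q.10.90 ... Q.90.10, N reads,
#' master plus singletons) and each subsampling fraction, runs B cycles
#' under both schemes and reports the median richness (with the
#' hypergeometric expectation as the exact column) and the median master
#' frequency.
#'
#' @param masters Master frequencies (default 0.9 down to 0.1).
#' @param N Library size (default 100,000).
#' @param fractions Subsampling fractions (default 0.5, 0.25, 0.1, 0.05).
#' @inheritParams runTable2
#' @return List of two data.frames, \code{richness} (columns id, fraction,
#'   noRepl, withRepl, exact) and \code{master} (same, exact = true master
#'   frequency).
#' @export
runSingleDominant <- function(masters = seq(0.9, 0.1, by = -0.1),
                              N = 100000, fractions = .qsFractions,
                              B = 500L, seed = 1L) {
    rich <- list(); mast <- list()
    for (mf in masters) {
        ht <- singleDominant(N, mf)
        id <- sprintf("Q.%02.0f.%02.0f", 100 * mf, 100 * (1 - mf))
        for (f in fractions) {
            m <- round(N * f)
            sW <- repeatedSubsample(ht, m = m, scheme = "without", B = B,
                                    seed = seed, statistics = .sdStats)
            sR <- repeatedSubsample(ht, m = m, scheme = "with", B = B,
                                    seed = seed, statistics = .sdStats)
            rich[[length(rich) + 1L]] <- data.frame(
                id = id, fraction = f,
                noRepl = sW$median[1], withRepl = sR$median[1],
                exact = expectedRichnessWithout(ht, m))
            mast[[length(mast) + 1L]] <- data.frame(
                id = id, fraction = f,
                noRepl = sW$median[2], withRepl = sR$median[2],
                exact = mf)
        }
    }
    out <- list(richness = do.call(rbind, rich),
                master = do.call(rbind, mast))
    attr(out, "B") <- B; attr(out, "seed") <- seed
    out
}

.promStats <- function(promIds) {
    stats_ <- list(SngFr = singletonFraction)
    for (i in seq_along(promIds)) {
        local({
            id <- promIds[i]
            stats_[[sprintf("Hpl_%d", i)]] <<- function(t) {
                j <- match(id, haplotypeIds(t))
                if (is.na(j)) 0 else readCounts(t)[[j]] / totalReads(t)
            }
        })
    }
    stats_$Ov1 <- function(t) over1BelowTop(t, 6L)
    stats_
}

#' Prominent-haplotypes benchmark
#'
#' The six-prominent-haplotypes structure subsampled at a grid of
#' fractions under both schemes. Per fraction and scheme, reports
#' B-cycle medians of: the singleton read fraction, each prominent
#' haplotype's frequency, and the read fraction of over-one-read
#' haplotypes below the top 6 (the replicated-singletons statistic,
#' identically 0 without replacement and positive with replacement).
#'
#' @inheritParams runSingleDominant
#' @return List of two data.frames, \code{without} and \code{with}; first
#'   row \code{"True"} holds the full-sample values.
#' @export
runProminent <- function(fractions = .qsFractions, B = 500L, seed = 1L) {
    ht <- prominentHaplotypes()
    stats_ <- .promStats(haplotypeIds(ht)[1:6])
    trueRow <- data.frame(subs = "True", t(vapply(
        stats_, function(s) s(ht), numeric(1))))
    run <- function(scheme) {
        rows <- lapply(fractions, function(f) {
            s <- repeatedSubsample(ht, fraction = f, scheme = scheme,
                                   B = B, seed = seed, statistics = stats_)
            data.frame(subs = format(f), t(stats::setNames(s$median,
                                                           s$statistic)))
        })
        do.call(rbind, c(list(trueRow), rows))
    }
    out <- list(without = run("without"), with = run("with"))
    attr(out, "B") <- B; attr(out, "seed") <- seed
    out
}

#' No-rare-haplotypes benchmark
#'
#' The 90%-master / ten-1%-minors structure subsampled at a grid of
#' fractions under both schemes: B-cycle medians of the number of
#' haplotypes and of all eleven haplotype frequencies. With no rare
#' haplotypes present, both schemes recover the composition almost
#' exactly at every fraction.
#'
#' @inheritParams runSingleDominant
#' @return List of two data.frames (\code{without}, \code{with}) with
#'   columns subs, HplNo, Hpl_01 ... Hpl_11; first row "True".
#' @export
runNoRare <- function(fractions = .qsFractions, B = 500L, seed = 1L) {
    ht <- noRareHaplotypes()
    ids <- haplotypeIds(ht)
    stats_ <- list(HplNo = richness)
    for (i in seq_along(ids)) {
        local({
            id <- ids[i]
            stats_[[sprintf("Hpl_%02d", i)]] <<- function(t) {
                j <- match(id, haplotypeIds(t))
                if (is.na(j)) 0 else readCounts(t)[[j]] / totalReads(t)
            }
        })
    }
    trueRow <- data.frame(subs = "True", t(vapply(
        stats_, function(s) s(ht), numeric(1))))
    run <- function(scheme) {
        rows <- lapply(fractions, function(f) {
            s <- repeatedSubsample(ht, fraction = f, scheme = scheme,
                                   B = B, seed = seed, statistics = stats_)
            data.frame(subs = format(f), t(stats::setNames(s$median,
                                                           s$statistic)))
        })
        do.call(rbind, c(list(trueRow), rows))
    }
    out <- list(without = run("without"), with = run("with"))
    attr(out, "B") <- B; attr(out, "seed") <- seed
    out
}

#' Flat-quasispecies benchmark: full-bootstrap seen probabilities
#'
#' For a flat quasispecies of n haplotypes at k = 1 ... kMax reads each,
#' the probability that a given haplotype is seen in a full bootstrap
#' cycle, 1 - (1 - 1/n)^(n k), and its large-n limit 1 - (1/e)^k.
#'
#' @param n Number of haplotypes (default 1000).
#' @param kMax Largest per-haplotype count (default 10).
#' @return data.frame with columns nHpl, k, reads, prob, limit.
#' @examples
#' runFlat()
#' @export
runFlat <- function(n = 1000, kMax = 10) {
    k <- seq_len(kMax)
    data.frame(nHpl = n, k = k, reads = n * k,
               prob = vapply(k, function(kk) flatPSeen(n, kk), numeric(1)),
               limit = vapply(k, function(kk) flatPSeen(n, kk, limit = TRUE),
                              numeric(1)))
}

#' Flat-quasispecies expected-richness grid (both schemes and their ratio)
#'
#' Over a grid of per-haplotype counts k and subsampling fractions f,
#' evaluates the rarefaction expectation E1 (without replacement), the
#' with-replacement expectation E2 = n[1 - (1 - 1/n)^(nkf)], and their
#' ratio E2/E1 -- the accuracy of with-replacement subsampling on a flat
#' quasispecies.
#'
#' @param n Number of haplotypes (default 10,000).
#' @param k Per-haplotype counts (default 1:10).
#' @param fractions Subsampling fractions (default 0.1 to 1.0).
#' @return data.frame with columns n, k, f, m, E1, E2, ratio.
#' @export
flatRichnessGrid <- function(n = 10000, k = 1:10,
                             fractions = seq(0.1, 1, by = 0.1)) {
    grid <- expand.grid(k = k, f = fractions)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        kk <- grid$k[i]; f <- grid$f[i]
        ht <- flatQuasispecies(n, kk)
        m <- round(n * kk * f)
        e1 <- expectedRichnessWithout(ht, m)
        e2 <- expectedRichnessWith(ht, m)
        data.frame(n = n, k = kk, f = f, m = m, E1 = e1, E2 = e2,
                   ratio = e2 / e1)
    })
    do.call(rbind, rows)
}

#' Reproduce every benchmark result set as CSV
#'
#' Runs all the experiment functions with one master seed and writes one
#' CSV per result set into \code{outDir}. Fully deterministic given the
#' seed.
#'
#' @param outDir Output directory (created if needed).
#' @param B Resampling cycles for the stochastic sets (default 500).
#' @param seed Master seed.
#' @param verbose Log progress to standard error.
#' @return Invisibly, the character vector of files written.
#' @export
runAllTables <- function(outDir, B = 500L, seed = 1L, verbose = TRUE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (verbose) message(sprintf(...))
    files <- character(0)
    put <- function(df, name) {
        p <- file.path(outDir, paste0(name, ".csv"))
        utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
        files <<- c(files, p)
    }
    say("seen/unseen limits ...");      put(runTable1(), "table1")
    say("all-singletons (B=%d) ...", B)
    put(runTable2(B = B, seed = seed), "table2")
    say("single-dominant grid (B=%d) ...", B)
    sd <- runSingleDominant(B = B, seed = seed)
    put(sd$richness, "table4"); put(sd$master, "table5")
    say("prominent haplotypes (B=%d) ...", B)
    pr <- runProminent(B = B, seed = seed)
    put(pr$without, "table7"); put(pr$with, "table8")
    say("no-rare haplotypes (B=%d) ...", B)
    nr <- runNoRare(B = B, seed = seed)
    put(nr$without, "table9"); put(nr$with, "table10")
    say("flat quasispecies ...")
    put(runFlat(), "table11")
    put(flatRichnessGrid(), "flat_grid")
    invisible(files)
}
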