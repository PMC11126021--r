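## Subsampling engines and the repeated-resampling harness.
##
## Without replacement, a subsample of m reads is a uniform random m-subset
## of the N-read multiset, i.e. the count vector is a multivariate
## hypergeometric draw. We generate it by sequential conditional
## hypergeometric draws over haplotypes (memory O(H), never materializing
## the N-read vector); the block of singleton haplotypes is exchangeable
## (one read each), so its draw reduces to a uniform subset of the
## singleton ids, taken in one C-level sample.int call.

.drawCountsWithout <- function(counts, m) {
    out <- numeric(length(counts))
    heavy <- which(counts > 1)
    remaining <- sum(counts)
    need <- m
    for (i in heavy) {
        if (need == 0) break
        x <- stats::rhyper(1L, counts[i], remaining - counts[i], need)
        out[i] <- x
        need <- need - x
        remaining <- remaining - counts[i]
    }
    if (need > 0) {
        sing <- which(counts == 1)
        out[sing[sample.int(length(sing), need)]] <- 1
    }
    out
}

.subsetTable <- function(x, drawn) {
    keep <- drawn > 0
    sq <- if (length(x@sequences)) x@sequences[keep] else character(0)
    .newTable(x@ids[keep], drawn[keep], sq)
}

#' Subsample a haplotype table without replacement (rarefaction draw)
#'
#' Draws a uniform random subset of \code{m} reads from the N reads of the
#' sample; the resulting count vector is a multivariate hypergeometric
#' draw. This is one cycle of classical rarefaction: every drawn read is
#' removed from the pool, so no read can be extracted twice, each output
#' count is bounded by its input count, and for an all-singletons sample
#' the subsample always contains exactly \code{m} haplotypes.
#'
#' Randomness comes from the R session RNG; seed with \code{set.seed} (the
#' repeated harness \code{\link{repeatedSubsample}} manages seeding itself).
#'
#' @param x A \linkS4class{HaplotypeTable}.
#' @param m Subsample size, 1 <= m <= N. Rarefying upward is impossible
#'   without replacement.
#' @return A \linkS4class{HaplotypeTable} with \code{sum(readCounts) == m};
#'   haplotypes drawn zero times are omitted.
#' @seealso \code{\link{subsampleWithReplacement}},
#'   \code{\link{expectedRichnessWithout}}
#' @examples
#' set.seed(1)
#' subsampleWithoutReplacement(allSingletons(100), 10)
#' @export
subsampleWithoutReplacement <- function(x, m) {
    N <- sum(x@counts)
    if (length(m) != 1L || !is.finite(m) || m != floor(m) || m < 1)
        stop("m must be a single integer >= 1")
    if (m > N)
        stop(sprintf("cannot subsample %d reads without replacement from %d",
                     as.integer(m), as.integer(N)))
    if (m == N) return(x)
    .subsetTable(x, .drawCountsWithout(x@counts, m))
}

#' Subsample a haplotype table with replacement (bootstrap draw)
#'
#' Draws \code{m} reads with replacement, each read landing on haplotype i
#' with probability count_i / N: the count vector is a multinomial draw.
#' Because extractions are independent, rare haplotypes may be replicated
#' or missed entirely; a full bootstrap cycle (m = N) of a large
#' all-singletons sample recovers only about 1 - 1/e (0.632) of the
#' haplotypes.
#'
#' @inheritParams subsampleWithoutReplacement
#' @param m Subsample size, any integer >= 1 (may exceed N).
#' @return A \linkS4class{HaplotypeTable} with \code{sum(readCounts) == m}.
#' @seealso \code{\link{pSeenBootstrap}}, \code{\link{expectedRichnessWith}}
#' @examples
#' set.seed(1)
#' subsampleWithReplacement(allSingletons(100), 100)
#' @export
subsampleWithReplacement <- function(x, m) {
    if (length(m) != 1L || !is.finite(m) || m != floor(m) || m < 1)
        stop("m must be a single integer >= 1")
    drawn <- as.numeric(stats::rmultinom(1L, as.integer(m), x@counts))
    .subsetTable(x, drawn)
}

.resolveSize <- function(N, fraction = NULL, m = NULL) {
    if (is.null(m)) {
        if (is.null(fraction))
            stop("supply either a subsample fraction or an absolute size m")
        if (fraction <= 0 || fraction > 1)
            stop("fraction must lie in (0, 1]")
        m <- round(N * fraction)   # round-half-even, as in the host language
    }
    max(1, m)
}

#' Repeated subsampling with summary statistics
#'
#' Runs \code{B} independent subsampling cycles under one scheme and
#' summarizes user-supplied statistics across cycles by median, IQR, SD and
#' mean -- the standard presentation of rarefaction simulations. Each cycle
#' runs on its own RNG substream derived deterministically from
#' \code{seed}, so results are reproducible and independent of evaluation
#' order.
#'
#' @param x A \linkS4class{HaplotypeTable}.
#' @param fraction Subsampling fraction f in (0, 1]; the subsample size is
#'   \code{round(N * f)}. Ignored when \code{m} is given.
#' @param m Absolute subsample size (overrides \code{fraction}).
#' @param scheme \code{"without"} (rarefaction, default) or \code{"with"}
#'   (bootstrap-style) replacement.
#' @param B Number of resampling cycles (default 500).
#' @param seed Integer master seed.
#' @param statistics Named list of functions, each mapping a
#'   \code{HaplotypeTable} to a single number, e.g.
#'   \code{list(richness = richness, master = masterFrequency)}.
#' @return A \code{data.frame} (one row per statistic) with columns
#'   \code{statistic, median, IQR, sd, mean}, carrying attributes
#'   \code{m, B, scheme, seed, fraction} and \code{cycles} (the B-by-k
#'   matrix of raw per-cycle values). Median and quartiles use the linear
#'   interpolation convention (R type 7); SD uses the n-1 denominator.
#' @examples
#' ht <- singleDominant(1000, 0.9)
#' repeatedSubsample(ht, fraction = 0.5, scheme = "without", B = 50,
#'                   seed = 1, statistics = list(richness = richness))
#' @export
repeatedSubsample <- function(x, fraction = NULL, m = NULL,
                              scheme = c("without", "with"),
                              B = 500L, seed = 1L,
                              statistics = list(richness = richness)) {
    scheme <- match.arg(scheme)
    if (B < 1) stop("B must be >= 1")
    if (!length(statistics) || is.null(names(statistics)) ||
        any(!nzchar(names(statistics))))
        stop("statistics must be a non-empty named list of functions")
    N <- sum(x@counts)
    m <- .resolveSize(N, fraction, m)
    if (scheme == "without" && m > N)
        stop("subsample size exceeds library size under without-replacement")
    draw <- if (scheme == "without")
        function() .subsetTable(x, .drawCountsWithout(x@counts, m))
    else
        function() .subsetTable(x,
            as.numeric(stats::rmultinom(1L, as.integer(m), x@counts)))
    set.seed(seed)
    cycleSeeds <- sample.int(2147483647L, B)
    k <- length(statistics)
    vals <- matrix(NA_real_, nrow = B, ncol = k,
                   dimnames = list(NULL, names(statistics)))
    for (b in seq_len(B)) {
        set.seed(cycleSeeds[b])
        sub <- draw()
        for (j in seq_len(k)) {
            v <- tryCatch(statistics[[j]](sub), error = function(e)
                stop(sprintf("statistic '%s' failed at cycle %d: %s",
                             names(statistics)[j], b, conditionMessage(e)),
                     call. = FALSE))
            vals[b, j] <- as.numeric(v)
        }
    }
    out <- data.frame(
        statistic = names(statistics),
        median = apply(vals, 2L, stats::median),
        IQR = apply(vals, 2L, stats::IQR),
        sd = apply(vals, 2L, stats::sd),
        mean = colMeans(vals),
        row.names = NULL
    )
    if (B == 1L) out$sd <- 0   # a single cycle has no dispersion
    attr(out, "m") <- m
    attr(out, "B") <- B
    attr(out, "scheme") <- scheme
    attr(out, "seed") <- seed
    attr(out, "fraction") <- if (is.null(fraction)) m / N else fraction
    attr(out, "cycles") <- vals
    class(out) <- c("ResamplingSummary", "data.frame")
    out
}

#' Rarefy a group of samples to a common library size
#'
#' The normalization workflow: every sample is repeatedly subsampled to the
#' same reference size so their diversity summaries become comparable.
#' Samples smaller than the reference cannot be rarefied without
#' replacement and are reported as an error (candidates for rejection
#' under a minimum-coverage rule fixed at design time).
#'
#' @param tables Named list of \linkS4class{HaplotypeTable}s.
#' @param referenceSize Common target size, or \code{"min"} (default) for
#'   the smallest library in the group.
#' @inheritParams repeatedSubsample
#' @return Named list of \code{ResamplingSummary} data frames, one per
#'   sample. All samples are resampled from the same master seed, so
#'   identical tables yield identical summaries.
#' @export
rarefyGroup <- function(tables, referenceSize = "min",
                        scheme = c("without", "with"), B = 500L, seed = 1L,
                        statistics = list(richness = richness)) {
    scheme <- match.arg(scheme)
    if (!length(tables)) stop("no samples supplied")
    if (is.null(names(tables)))
        names(tables) <- sprintf("sample_%d", seq_along(tables))
    Ns <- vapply(tables, function(t) sum(t@counts), numeric(1))
    ref <- if (identical(referenceSize, "min")) min(Ns)
           else as.numeric(referenceSize)
    if (scheme == "without" && any(Ns < ref)) {
        off <- names(tables)[Ns < ref]
        stop(sprintf(
            "sample(s) smaller than reference size %d: %s",
            as.integer(ref), paste(off, collapse = ", ")))
    }
    lapply(tables, repeatedSubsample, m = ref, scheme = scheme, B = B,
           seed = seed, statistics = statistics)
}

#' Write a resampling summary to CSV or JSON
#'
#' Serializes a \code{ResamplingSummary} (or a named list of them, as
#' returned by \code{\link{rarefyGroup}}) with its resampling metadata:
#' columns \code{sample, statistic, scheme, fraction, m, B, median, IQR,
#' sd, mean}.
#'
#' @param x A \code{ResamplingSummary} or a named list of them.
#' @param path Output path.
#' @param format \code{"csv"} (default) or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeResamplingSummary <- function(x, path, format = c("csv", "json")) {
    format <- match.arg(format)
    if (inherits(x, "ResamplingSummary")) x <- list(sample = x)
    rows <- do.call(rbind, lapply(names(x), function(nm) {
        s <- x[[nm]]
        data.frame(sample = nm, statistic = s$statistic,
                   scheme = attr(s, "scheme"),
                   fraction = attr(s, "fraction"),
                   m = attr(s, "m"), B = attr(s, "B"),
                   median = s$median, IQR = s$IQR, sd = s$sd,
                   mean = s$mean, row.names = NULL)
    }))
    if (format == "csv")
        utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    else
        jsonlite::write_json(rows, path, dataframe = "rows", digits = NA)
    invisible(path)
}
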