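## Deterministic generators for the benchmark quasispecies structures used
## throughout the package's simulations. No RNG is involved: the same
## parameters always yield the identical table, ids included.
##
## Id conventions: the dominant haplotype is "master", non-singleton minor
## haplotypes are "hpl_01", ..., singletons are "sng_000001", ... --
## stable, sortable, human-readable.

.singletonIds <- function(n) sprintf("sng_%06d", seq_len(n))

## largest-remainder apportionment of N reads to the target frequencies,
## so counts always sum exactly to N even when N*freq is non-integral.
.apportion <- function(N, freqs) {
    raw <- N * freqs
    cnt <- floor(raw)
    left <- round(N - sum(cnt))
    if (left > 0) {
        ord <- order(raw - cnt, decreasing = TRUE)
        cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
    }
    cnt
}

#' All-singletons quasispecies
#'
#' The maximally diverse structure: n reads, each its own haplotype, so
#' H = N = n and every haplotype is rare. It is the worst case for
#' with-replacement subsampling (a full bootstrap cycle recovers only
#' about 63.21% of haplotypes) and the identity case for rarefaction
#' (a without-replacement subsample of m reads contains exactly m
#' haplotypes).
#'
#' @param n Number of reads (= haplotypes), >= 1.
#' @return A \linkS4class{HaplotypeTable} with every count equal to 1.
#' @examples
#' allSingletons(10)
#' @export
allSingletons <- function(n) {
    if (length(n) != 1L || n < 1 || n != floor(n))
        stop("n must be a single integer >= 1")
    .newTable(.singletonIds(n), rep(1, n))
}

#' Single-dominant quasispecies
#'
#' A master haplotype at a given frequency, all remaining reads being
#' singletons. With N = 100,000 and master frequencies 0.1 to 0.9 these
#' are the benchmark structures Q.10.90 through Q.90.10 (e.g. Q.90.10 has
#' 90,000 master reads and 10,000 singletons, H = 10,001).
#'
#' @param N Library size (default 100,000).
#' @param masterFreq Master haplotype frequency in (0, 1).
#' @return A \linkS4class{HaplotypeTable} with
#'   H = N - round(N * masterFreq) + 1.
#' @examples
#' nHaplotypes(singleDominant(100000, 0.9))  # 10001
#' @export
singleDominant <- function(N = 100000, masterFreq) {
    if (masterFreq <= 0 || masterFreq >= 1)
        stop("masterFreq must lie strictly in (0, 1)")
    mc <- round(N * masterFreq)
    if (mc < 1) stop("master count rounds to 0; increase N or masterFreq")
    if (mc >= N) stop("master count leaves no reads for singletons")
    nSng <- N - mc
    .newTable(c("master", .singletonIds(nSng)), c(mc, rep(1, nSng)))
}

#' Prominent-haplotypes quasispecies
#'
#' Six prominent haplotypes, each at half the frequency of the preceding
#' one, plus a block of singletons. The default is the benchmark
#' composition: counts 49231, 24615, 12308, 6154, 3077, 1538 plus 3077
#' singletons, N = 100,000, H = 3083, singleton read fraction 0.03077.
#' Every haplotype outside the top 6 is a singleton, so the read fraction
#' of over-one-read haplotypes below the top 6 is exactly 0 -- the
#' statistic that with-replacement subsampling inflates.
#'
#' @param counts Positive, non-increasing read counts of the prominent
#'   haplotypes.
#' @param singletons Number of singleton haplotypes (>= 0).
#' @return A \linkS4class{HaplotypeTable}.
#' @examples
#' ht <- prominentHaplotypes()
#' totalReads(ht); nHaplotypes(ht)
#' @export
prominentHaplotypes <- function(counts = c(49231, 24615, 12308,
                                           6154, 3077, 1538),
                                singletons = 3077) {
    if (any(counts < 1) || any(diff(counts) > 0))
        stop("prominent counts must be positive and non-increasing")
    if (singletons < 0) stop("singletons must be >= 0")
    ids <- sprintf("hpl_%d", seq_along(counts))
    if (singletons > 0) {
        ids <- c(ids, .singletonIds(singletons))
        counts <- c(counts, rep(1, singletons))
    }
    .newTable(ids, as.numeric(counts))
}

#' No-rare-haplotypes quasispecies
#'
#' A master haplotype plus a few minor haplotypes at moderate frequency,
#' with no singletons or rare haplotypes at all: by default a 90% master
#' and 10 minors at 1% each (H = 11). With every haplotype abundant, both
#' subsampling schemes recover the composition almost exactly, which is
#' why structures of this kind may be rarefied with replacement, or
#' compared without rarefaction.
#'
#' @param N Library size (default 100,000).
#' @param master Master frequency (default 0.9).
#' @param nMinor Number of minor haplotypes (default 10).
#' @param minor Frequency of each minor haplotype (default 0.01). The
#'   frequencies must satisfy master + nMinor * minor = 1 (within the
#'   rounding granularity 1/N).
#' @return A \linkS4class{HaplotypeTable} with H = 1 + nMinor.
#' @examples
#' frequencies(noRareHaplotypes())
#' @export
noRareHaplotypes <- function(N = 100000, master = 0.9, nMinor = 10,
                             minor = 0.01) {
    if (nMinor < 1) stop("nMinor must be >= 1")
    tot <- master + nMinor * minor
    if (abs(tot - 1) > 1 / N)
        stop(sprintf("frequencies sum to %g, not 1", tot))
    freqs <- c(master, rep(minor, nMinor))
    cnt <- .apportion(N, freqs / sum(freqs))
    if (any(cnt < 1)) stop("a haplotype count rounds to 0; increase N")
    .newTable(c("master", sprintf("hpl_%02d", seq_len(nMinor))), cnt)
}

#' Flat (perfectly even) quasispecies
#'
#' n haplotypes with exactly k reads each, N = n*k: a perfectly even
#' assemblage whose Hill number equals n at every order. It models a
#' sample after a low-level abundance filter (minimum k reads per
#' haplotype); as k grows, the with- and without-replacement schemes
#' converge (see \code{\link{flatPSeen}} and
#' \code{\link{richnessRatio}}).
#'
#' @param n Number of haplotypes, >= 1.
#' @param k Reads per haplotype, >= 1. \code{flatQuasispecies(n, 1)} is
#'   the all-singletons structure (with flat-style ids).
#' @return A \linkS4class{HaplotypeTable}.
#' @examples
#' totalReads(flatQuasispecies(1000, 10))  # 10000
#' @export
flatQuasispecies <- function(n, k) {
    if (n < 1 || k < 1 || n != floor(n) || k != floor(k))
        stop("n and k must be integers >= 1")
    .newTable(sprintf("hpl_%06d", seq_len(n)), rep(as.numeric(k), n))
}

#' Build a benchmark scenario by name
#'
#' Convenience dispatcher over the five generators, useful for scripting
#' and the command-line interface.
#'
#' @param scenario One of \code{"all_singletons"}, \code{"single_dominant"},
#'   \code{"prominent"}, \code{"no_rare"}, \code{"flat"}. (Deliberately
#'   not named \code{kind} or \code{name}: generator parameters like
#'   \code{k} and \code{n} must not partial-match it through \code{...}.)
#' @param ... Parameters forwarded to the matching generator.
#' @return A \linkS4class{HaplotypeTable}.
#' @export
makeScenario <- function(scenario = c("all_singletons", "single_dominant",
                                      "prominent", "no_rare", "flat"),
                         ...) {
    scenario <- match.arg(scenario)
    switch(scenario,
        all_singletons = allSingletons(...),
        single_dominant = singleDominant(...),
        prominent = prominentHaplotypes(...),
        no_rare = noRareHaplotypes(...),
        flat = flatQuasispecies(...))
}
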