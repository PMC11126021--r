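## Closed-form sampling probabilities and expected richness under both
## subsampling schemes. Binomial coefficients are evaluated in log space
## (lchoose) so library sizes of 10^7 reads pose no overflow risk.

#' Probability that an item is seen in a full bootstrap cycle
#'
#' In a bootstrap cycle of n independent draws with replacement from n
#' items, a given item is missed with probability (1 - 1/n)^n, so it is
#' seen with probability 1 - (1 - 1/n)^n. As n grows this converges to
#' 1 - 1/e = 0.6321...: a large bootstrap resample contains about 63.21%
#' of the original unique items, the rest being replicates.
#'
#' @param n Number of items (reads), or \code{Inf} for the limit.
#' @return Probability in (0, 1].
#' @examples
#' pSeenBootstrap(2)      # 0.75
#' pSeenBootstrap(Inf)    # 1 - 1/e
#' @export
pSeenBootstrap <- function(n) {
    if (length(n) != 1L || is.na(n) || n < 1)
        stop("n must be a single value >= 1 (or Inf)")
    if (is.infinite(n)) return(1 - exp(-1))
    1 - (1 - 1 / n)^n
}

#' Probability that an item is seen when subsampling a fraction with
#' replacement
#'
#' With f*n independent draws with replacement from n items, a given item
#' is seen with probability 1 - (1 - 1/n)^(f*n); in the large-n limit,
#' 1 - e^(-f). Without replacement the proportion of items seen is exactly
#' f, so 1 - e^(-f) < f quantifies the deficit of the with-replacement
#' scheme, maximal at f = 1 (the pure bootstrap).
#'
#' @param f Subsampling fraction in (0, 1].
#' @param n Number of items, or \code{Inf} (default) for the limit.
#' @return Probability.
#' @examples
#' pSeenFraction(0.5)        # 0.3935
#' 1 - pSeenFraction(0.1)    # unseen fraction, 0.9048
#' @export
pSeenFraction <- function(f, n = Inf) {
    if (any(f <= 0 | f > 1)) stop("f must lie in (0, 1]")
    if (length(n) != 1L || is.na(n) || n < 1)
        stop("n must be a single value >= 1 (or Inf)")
    if (is.infinite(n)) 1 - exp(-f) else 1 - (1 - 1 / n)^(f * n)
}

#' Probability that a haplotype of a flat quasispecies is seen
#'
#' For a perfectly even ("flat") quasispecies of n haplotypes with k reads
#' each (sample size N = n*k), the probability that a given haplotype is
#' drawn at least once in f*N extractions with replacement is
#' 1 - (1 - 1/n)^(n*k*f); as n grows this tends to 1 - (1/e)^(k*f). Already
#' at k = 5 reads per haplotype a full bootstrap cycle sees more than 99%
#' of haplotypes, which is why a low-level abundance filter makes the two
#' subsampling schemes nearly equivalent.
#'
#' This is a per-haplotype probability; multiply by n (see
#' \code{\link{expectedRichnessWith}}) for the expected haplotype count.
#'
#' @param n Number of haplotypes.
#' @param k Reads per haplotype.
#' @param f Subsampling fraction in (0, 1] (default 1, a full bootstrap
#'   cycle).
#' @param limit If \code{TRUE}, return the large-n limit 1 - (1/e)^(k*f).
#' @return Probability.
#' @examples
#' flatPSeen(1000, 1)               # 0.6323046
#' flatPSeen(1000, 5)               # 0.9932789
#' flatPSeen(1000, 5, limit = TRUE) # 0.9932621
#' @export
flatPSeen <- function(n, k, f = 1, limit = FALSE) {
    if (n < 1 || k < 1 || f <= 0 || f > 1)
        stop("need n >= 1, k >= 1 and f in (0, 1]")
    if (limit) 1 - exp(-k * f) else 1 - (1 - 1 / n)^(n * k * f)
}

## log of C(a, b) with the conventions lchoose handles (returns -Inf when
## b > a), kept as a named step for readability.
.lchoose <- function(a, b) lchoose(a, b)

#' Expected richness when subsampling without replacement
#'
#' The classical rarefaction equation: drawing m of the N reads uniformly
#' without replacement, haplotype i (count c_i) is missed with the
#' hypergeometric probability C(N - c_i, m) / C(N, m), so the expected
#' number of haplotypes observed is
#' \deqn{E[H_m] = \sum_i 1 - \frac{{N - c_i \choose m}}{{N \choose m}}.}
#' For a flat table (all counts equal to k) this reduces to
#' n - n * C(nk - k, m) / C(nk, m). Evaluated in log space; exact at
#' N = 10^7 and beyond.
#'
#' @param x A \linkS4class{HaplotypeTable}.
#' @param m Subsample size, 0 <= m <= N.
#' @return Expected number of distinct haplotypes (real; equals H at
#'   m = N and 0 at m = 0).
#' @seealso \code{\link{expectedRichnessWith}}, \code{\link{richnessRatio}}
#' @examples
#' expectedRichnessWithout(allSingletons(10000), 1000)  # exactly 1000
#' @export
expectedRichnessWithout <- function(x, m) {
    N <- sum(x@counts)
    if (m < 0 || m > N) stop("m must lie in [0, N]")
    if (m == 0) return(0)
    lcNm <- .lchoose(N, m)
    cnt <- x@counts
    ## collapse equal counts: the per-haplotype term depends only on c_i
    tab <- table(cnt)
    c_u <- as.numeric(names(tab))
    w <- as.numeric(tab)
    terms <- 1 - exp(.lchoose(N - c_u, m) - lcNm)
    sum(w * terms)
}

#' Expected richness when subsampling with replacement
#'
#' Drawing m reads with replacement (probabilities c_i / N), haplotype i is
#' missed with probability (1 - c_i/N)^m, so the expected number observed
#' is \deqn{E[H_m] = \sum_i 1 - (1 - c_i/N)^m.} For a flat table this is
#' n * [1 - (1 - 1/n)^(n*k*f)], i.e. n times \code{\link{flatPSeen}}. It
#' never exceeds the without-replacement expectation: replacement wastes
#' draws on replicates at the expense of unseen rare haplotypes.
#'
#' @param x A \linkS4class{HaplotypeTable}.
#' @param m Subsample size, any integer >= 0.
#' @return Expected number of distinct haplotypes.
#' @examples
#' expectedRichnessWith(allSingletons(10000), 10000)  # about 6321.4
#' @export
expectedRichnessWith <- function(x, m) {
    if (m < 0) stop("m must be >= 0")
    if (m == 0) return(0)
    N <- sum(x@counts)
    tab <- table(x@counts)
    c_u <- as.numeric(names(tab))
    w <- as.numeric(tab)
    ## (1 - c/N)^m via exp(m * log1p(-c/N)) for accuracy at tiny c/N
    miss <- ifelse(c_u >= N, 0, exp(m * log1p(-c_u / N)))
    sum(w * (1 - miss))
}

#' Richness ratio of the two schemes on a flat quasispecies
#'
#' For a flat quasispecies (n haplotypes, k reads each) subsampled to
#' fraction f (m = round(n*k*f) reads), returns the ratio of the expected
#' haplotype count with replacement to the expected count without
#' replacement (the rarefaction equation). The ratio lies in (0, 1] and
#' measures how much of the rarefaction result a with-replacement scheme
#' recovers; it approaches 1 as k grows, which is the basis for treating
#' abundance-filtered samples as safe to bootstrap.
#'
#' @inheritParams flatPSeen
#' @return Ratio in (0, 1].
#' @examples
#' richnessRatio(10000, 1, 1)    # about 0.632
#' richnessRatio(10000, 10, 1)   # near 1
#' @export
richnessRatio <- function(n, k, f) {
    if (n < 1 || k < 1 || f <= 0 || f > 1)
        stop("need n >= 1, k >= 1 and f in (0, 1]")
    N <- n * k
    m <- round(N * f)
    if (m == 0) stop("subsample size round(n*k*f) is 0; ratio undefined")
    e2 <- n * (1 - (1 - 1 / n)^m)
    e1 <- n - n * exp(.lchoose(N - k, m) - .lchoose(N, m))
    e2 / e1
}

#' Variance of a proportion
#'
#' Var(p) = p (1 - p) / n for a proportion estimated from n reads. With
#' coverages around 10^5 the standard error of a prominent haplotype's
#' frequency is of order 10^-3, which is why prominent frequencies are
#' stable across subsample sizes and may be compared without rarefaction.
#'
#' @param p Proportion in [0, 1].
#' @param n Sample size (reads), >= 1.
#' @return The variance p (1 - p) / n.
#' @examples
#' varProportion(0.5, 100)          # 0.0025
#' sqrt(varProportion(0.49231, 1e5))
#' @export
varProportion <- function(p, n) {
    if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
    if (any(n < 1)) stop("n must be >= 1")
    p * (1 - p) / n
}
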