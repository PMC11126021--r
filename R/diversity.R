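## Diversity indices on haplotype tables: the Hill-number family and the
## quasispecies-specific read-fraction statistics.

.freqsOf <- function(x) {
    if (methods::is(x, "HaplotypeTable")) as.numeric(x@counts / sum(x@counts))
    else {
        p <- as.numeric(x)
        if (any(p <= 0 | p > 1)) stop("frequencies must lie in (0, 1]")
        if (abs(sum(p) - 1) > 1e-12)
            stop("frequencies must sum to 1 (within 1e-12)")
        p
    }
}

#' Hill number of order q
#'
#' The diversity of order q of a frequency vector p,
#' \deqn{^qD(p) = \left(\sum_i p_i^q\right)^{1/(1-q)},}
#' with the limiting cases q = 0 (richness), q = 1 (exp of Shannon
#' entropy) and q = Inf (inverse of the dominant frequency). As q grows,
#' rare haplotypes lose weight, so sensitivity to sample size decreases
#' with q: richness is the most sample-size-sensitive member of the
#' family and the master frequency the least.
#'
#' @param x A \linkS4class{HaplotypeTable} or a numeric frequency vector
#'   summing to 1.
#' @param q Order, a single value >= 0 (Inf allowed).
#' @return The Hill number, a value in [1, H].
#' @examples
#' ht <- noRareHaplotypes()
#' hillNumber(ht, 0)    # 11, the richness
#' hillNumber(ht, Inf)  # 1/0.9
#' @export
hillNumber <- function(x, q) {
    p <- .freqsOf(x)
    if (length(q) != 1L || is.na(q) || q < 0)
        stop("q must be a single order >= 0 (Inf allowed)")
    if (is.infinite(q)) return(1 / max(p))
    if (q == 0) return(length(p))
    if (q == 1) return(exp(-sum(p * log(p))))
    sum(p^q)^(1 / (1 - q))
}

#' Shannon entropy (nats)
#'
#' -sum p_i log p_i, in natural logarithm units so that
#' exp(shannonEntropy(x)) equals the Hill number of order 1.
#'
#' @inheritParams hillNumber
#' @param base Logarithm base (default \code{exp(1)}).
#' @return Entropy, >= 0.
#' @export
shannonEntropy <- function(x, base = exp(1)) {
    p <- .freqsOf(x)
    -sum(p * log(p, base = base))
}

#' Gini-Simpson index
#'
#' 1 - sum p_i^2, the probability that two reads drawn at random belong to
#' different haplotypes; 1/(1 - giniSimpson(x)) is the Hill number of
#' order 2.
#'
#' @inheritParams hillNumber
#' @return Value in [0, 1).
#' @export
giniSimpson <- function(x) {
    p <- .freqsOf(x)
    1 - sum(p^2)
}

#' Frequency of the master (dominant) haplotype
#'
#' @inheritParams hillNumber
#' @return max p_i; its inverse is the Hill number of order Inf.
#' @export
masterFrequency <- function(x) max(.freqsOf(x))

#' Observed richness
#'
#' @param x A \linkS4class{HaplotypeTable}.
#' @return The number of haplotypes H (the Hill number of order 0).
#' @export
richness <- function(x) {
    if (!methods::is(x, "HaplotypeTable")) return(length(.freqsOf(x)))
    length(x@counts)
}

#' Fraction of reads in singleton haplotypes
#'
#' The aggregated frequency of haplotypes observed with exactly one read,
#' (number of singletons) / N. Under with-replacement subsampling this
#' statistic is biased downward, because replicated singletons migrate
#' into the over-one-read class; see \code{\link{over1BelowTop}}.
#'
#' @param x A \linkS4class{HaplotypeTable}.
#' @return Value in [0, 1].
#' @examples
#' singletonFraction(prominentHaplotypes())  # 0.03077
#' @export
singletonFraction <- function(x) {
    sum(x@counts == 1) / sum(x@counts)
}

#' Aggregated read fraction of haplotypes in a frequency band
#'
#' Sum of p_i over haplotypes whose frequency satisfies
#' lower <= p_i < upper. This is the rare haplotype load (RHL) when the
#' band is (0, 0.01) or (0, 0.001), and the general quasispecies fitness
#' fraction (QFF) for arbitrary bands. The upper bound is exclusive --
#' haplotypes sitting exactly at a threshold such as 1% are not counted as
#' below it -- except at upper = 1, which is inclusive so the full band
#' (0, 1] captures all reads.
#'
#' @param x A \linkS4class{HaplotypeTable} or frequency vector.
#' @param lower,upper Frequency bounds, 0 <= lower < upper <= 1.
#' @return Aggregated read fraction in [0, 1].
#' @examples
#' fractionBetween(prominentHaplotypes(), 0, 0.01)  # the RHL, 0.03077
#' @export
fractionBetween <- function(x, lower, upper) {
    if (lower < 0 || upper > 1 || lower >= upper)
        stop("need 0 <= lower < upper <= 1")
    p <- .freqsOf(x)
    inBand <- p >= lower & (p < upper | (upper == 1 & p == 1))
    sum(p[inBand])
}

#' Read fraction of replicated non-prominent haplotypes
#'
#' The fraction of reads carried by haplotypes with more than one read
#' that are not among the K most abundant (ranking by count descending,
#' ties broken by id ascending). In a sample whose non-prominent
#' haplotypes are all singletons this is exactly 0; after with-replacement
#' subsampling it becomes positive, quantifying the singleton replicates
#' the scheme manufactures.
#'
#' @param x A \linkS4class{HaplotypeTable}.
#' @param K Number of top haplotypes to exclude (default 6).
#' @return Read fraction in [0, 1]. If K exceeds the number of haplotypes,
#'   returns 0 with a warning.
#' @examples
#' over1BelowTop(prominentHaplotypes(), 6)  # 0
#' @export
over1BelowTop <- function(x, K = 6L) {
    if (K < 0) stop("K must be >= 0")
    H <- length(x@counts)
    if (K > H) {
        warning(sprintf("K = %d exceeds the %d haplotypes; returning 0",
                        as.integer(K), H))
        return(0)
    }
    ord <- order(-x@counts, x@ids, method = "radix")
    rest <- if (K > 0) ord[-seq_len(K)] else ord
    qual <- rest[x@counts[rest] >= 2]
    sum(x@counts[qual]) / sum(x@counts)
}

#' DiversityProfile: Hill numbers over a grid of orders
#'
#' Result container of \code{\link{diversityProfile}}: the Hill numbers
#' ^qD over a grid of orders q together with the named classical indices
#' they correspond to.
#'
#' @slot q numeric grid of orders (Inf allowed).
#' @slot D Hill number per order.
#' @slot indices named numeric: richness, shannon, gini_simpson,
#'   master_frequency, singleton_fraction.
#' @name DiversityProfile-class
#' @aliases DiversityProfile-class
#' @exportClass DiversityProfile
setClass("DiversityProfile",
    representation(q = "numeric", D = "numeric", indices = "numeric"))

setValidity("DiversityProfile", function(object) {
    if (length(object@q) != length(object@D))
        return("q and D lengths differ")
    if (any(object@q < 0)) return("orders q must be >= 0")
    TRUE
})

#' Diversity profile of a haplotype table
#'
#' Computes the Hill numbers over a grid of orders plus the classical
#' indices (richness, Shannon entropy, Gini-Simpson, master frequency,
#' singleton fraction). The profile is non-increasing in q, bounded above
#' by richness (q = 0) and below by the inverse master frequency
#' (q = Inf).
#'
#' @param x A \linkS4class{HaplotypeTable}.
#' @param q Numeric grid of orders (default 0, 0.5, 1, 2, 4, Inf).
#' @return A \linkS4class{DiversityProfile}.
#' @examples
#' diversityProfile(noRareHaplotypes())
#' @export
diversityProfile <- function(x, q = c(0, 0.5, 1, 2, 4, Inf)) {
    D <- vapply(q, function(qq) hillNumber(x, qq), numeric(1))
    idx <- c(richness = richness(x),
             shannon = shannonEntropy(x),
             gini_simpson = giniSimpson(x),
             master_frequency = masterFrequency(x),
             singleton_fraction = singletonFraction(x))
    methods::new("DiversityProfile", q = q, D = D, indices = idx)
}

setMethod("show", "DiversityProfile", function(object) {
    cat("DiversityProfile\n  Hill numbers:\n")
    for (i in seq_along(object@q))
        cat(sprintf("    q = %-4s  %g\n",
                    format(object@q[i]), object@D[i]))
    cat("  indices:\n")
    for (nm in names(object@indices))
        cat(sprintf("    %-18s %g\n", nm, object@indices[nm]))
    invisible(NULL)
})

#' @describeIn DiversityProfile-class profile as a data.frame (q, D).
#' @param x A \code{DiversityProfile}.
#' @param row.names,optional,... passed for generic compatibility; unused.
#' @export
setMethod("as.data.frame", "DiversityProfile",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(q = x@q, D = x@D)
    })

#' @describeIn DiversityProfile-class named classical index values.
#' @export
setGeneric("indexValues", function(x) standardGeneric("indexValues"))
#' @rdname DiversityProfile-class
#' @export
setMethod("indexValues", "DiversityProfile", function(x) x@indices)

#' Rank diversity indices by sensitivity to subsampling
#'
#' Quantifies how strongly each classical index depends on sample size:
#' for every subsampling fraction, the sample is repeatedly resampled and
#' the relative absolute bias of the B-cycle median against the
#' full-sample value is recorded; biases are averaged over fractions and
#' indices returned most-sensitive first. On structures rich in rare
#' haplotypes the expected ordering is richness > Shannon entropy >
#' Gini-Simpson > master frequency, mirroring the decreasing weight of
#' rare haplotypes as the Hill order grows.
#'
#' @param x A \linkS4class{HaplotypeTable} with at least 2 haplotypes.
#' @param fractions Subsampling fractions (default 0.05, 0.1, 0.25, 0.5).
#' @param scheme Subsampling scheme (default \code{"with"}, where the
#'   sensitivity differences are starkest).
#' @inheritParams repeatedSubsample
#' @return Character vector of index names, most sensitive first, with
#'   attribute \code{"bias"} (the mean relative absolute bias per index).
#' @export
sensitivityRank <- function(x, fractions = c(0.05, 0.1, 0.25, 0.5),
                            scheme = c("with", "without"),
                            B = 500L, seed = 1L) {
    scheme <- match.arg(scheme)
    if (length(x@counts) < 2L)
        stop("sensitivity ranking is undefined for a single-haplotype table")
    stats_ <- list(richness = richness,
                   shannon = shannonEntropy,
                   gini_simpson = giniSimpson,
                   master_frequency = masterFrequency)
    full <- vapply(stats_, function(f) f(x), numeric(1))
    biasMat <- vapply(fractions, function(f) {
        s <- repeatedSubsample(x, fraction = f, scheme = scheme, B = B,
                               seed = seed, statistics = stats_)
        abs(s$median - full) / abs(full)
    }, numeric(length(stats_)))
    bias <- rowMeans(matrix(biasMat, nrow = length(stats_),
                            dimnames = list(names(stats_), NULL)))
    out <- names(sort(bias, decreasing = TRUE))
    attr(out, "bias") <- bias[out]
    out
}
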