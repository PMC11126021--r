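# Independent oracles used across the suite, kept deliberately brute-force
# and separate from the package's own algorithms.

# Exact distribution of without-replacement draws by exhaustive enumeration
# of all C(N, m) read subsets. Returns a named numeric of probabilities,
# names are comma-joined count vectors (aligned with `counts`).
enumWithoutDist <- function(counts, m) {
    reads <- rep(seq_along(counts), counts)     # one entry per read
    subsets <- utils::combn(length(reads), m)
    keys <- apply(subsets, 2L, function(ix) {
        paste(tabulate(reads[ix], nbins = length(counts)), collapse = ",")
    })
    tab <- table(keys)
    p <- as.numeric(tab) / ncol(subsets)
    names(p) <- names(tab)
    p
}

# Exact multinomial probability of one with-replacement outcome.
multinomProb <- function(counts, drawn) {
    stats::dmultinom(drawn, prob = counts / sum(counts))
}

# All compositions of m over k cells (small instances only).
allCompositions <- function(m, k) {
    if (k == 1L) return(matrix(m, nrow = 1L))
    out <- NULL
    for (first in 0:m) {
        rest <- allCompositions(m - first, k - 1L)
        out <- rbind(out, cbind(first, rest))
    }
    unname(out)
}

countKey <- function(cnt) paste(cnt, collapse = ",")

# Draw B subsamples of a table and return the matrix of full-length count
# vectors (zeros retained), rows = draws.
drawCountMatrix <- function(ht, m, scheme, B, seed) {
    ids <- haplotypeIds(ht)
    set.seed(seed)
    out <- matrix(0, nrow = B, ncol = length(ids))
    for (b in seq_len(B)) {
        sub <- if (scheme == "without") subsampleWithoutReplacement(ht, m)
               else subsampleWithReplacement(ht, m)
        out[b, match(haplotypeIds(sub), ids)] <- readCounts(sub)
    }
    out
}

# Chi-square goodness-of-fit statistic p-value against exact outcome
# probabilities (named by count key).
chisqAgainst <- function(observedKeys, probs) {
    obs <- table(factor(observedKeys, levels = names(probs)))
    n <- length(observedKeys)
    stopifnot(sum(obs) == n)      # every observed outcome must be possible
    expd <- n * probs
    stat <- sum((as.numeric(obs) - expd)^2 / expd)
    stats::pchisq(stat, df = length(probs) - 1L, lower.tail = FALSE)
}

randomTable <- function(maxH = 20L, maxCount = 50L) {
    H <- sample.int(maxH, 1L)
    HaplotypeTable(sprintf("h%03d", seq_len(H)),
                   sample.int(maxCount, H, replace = TRUE))
}
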