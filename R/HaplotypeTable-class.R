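#' HaplotypeTable: a quasispecies sample as haplotype read counts
#'
#' The central container of the package. A quasispecies sample is a set of
#' amplicon haplotypes, each observed as an integer number of reads. All
#' resampling and diversity computations operate purely on the count vector;
#' sequences, when read from FASTA, are carried along as an optional payload
#' but never interpreted.
#'
#' @slot ids character vector of unique haplotype identifiers.
#' @slot counts numeric vector of integral read counts, one per haplotype,
#'   all >= 1. Stored as doubles so that library sizes beyond 2^31 reads
#'   remain exact (doubles are exact integers up to 2^53).
#' @slot sequences optional character vector of sequences aligned with
#'   \code{ids}; length 0 when absent.
#'
#' @details Derived quantities: \code{totalReads(x)} is the library size
#' (coverage) N, the sum of counts; \code{nHaplotypes(x)} is the observed
#' richness H. A haplotype with zero reads is absent from the table, so
#' always H <= N, with equality exactly when every haplotype is a singleton.
#'
#' @examples
#' ht <- HaplotypeTable(c("h1", "h2"), c(90, 10))
#' totalReads(ht)
#' frequencies(ht)
#' @name HaplotypeTable-class
#' @aliases HaplotypeTable-class
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
    representation(
        ids = "character",
        counts = "numeric",
        sequences = "character"
    ),
    prototype(sequences = character(0))
)

setValidity("HaplotypeTable", function(object) {
    ids <- object@ids
    counts <- object@counts
    if (length(ids) != length(counts))
        return(sprintf("lengths differ: %d ids vs %d counts",
                       length(ids), length(counts)))
    if (length(ids) < 1L)
        return("a HaplotypeTable must contain at least one haplotype")
    bad <- which(!is.finite(counts) | counts < 1 | counts != floor(counts))
    if (length(bad))
        return(sprintf(
            "counts must be positive integers; offending id(s): %s",
            paste(utils::head(ids[bad], 5L), collapse = ", ")))
    dup <- anyDuplicated(ids)
    if (dup)
        return(sprintf("duplicate haplotype id: '%s'", ids[dup]))
    ns <- length(object@sequences)
    if (ns != 0L && ns != length(ids))
        return("sequences must be absent or aligned with ids")
    TRUE
})

#' Construct a HaplotypeTable
#'
#' @param ids character vector of unique haplotype identifiers.
#' @param counts integer-valued vector of read counts (all >= 1), aligned
#'   with \code{ids}.
#' @param sequences optional character vector of sequences aligned with
#'   \code{ids}.
#' @return A valid \linkS4class{HaplotypeTable}.
#' @examples
#' HaplotypeTable(c("master", "s1"), c(9, 1))
#' @export
HaplotypeTable <- function(ids, counts, sequences = character(0)) {
    methods::new("HaplotypeTable",
        ids = as.character(ids),
        counts = as.numeric(counts),
        sequences = as.character(sequences))
}

## internal: construct skipping validity, for hot paths where validity is
## guaranteed by construction (subsampling).
.newTable <- function(ids, counts, sequences = character(0)) {
    S4Vectors::new2("HaplotypeTable",
        ids = ids, counts = counts, sequences = sequences,
        check = FALSE)
}

#' @describeIn HaplotypeTable-class haplotype identifiers.
#' @param x A \code{HaplotypeTable}.
#' @export
setGeneric("haplotypeIds", function(x) standardGeneric("haplotypeIds"))
#' @rdname HaplotypeTable-class
#' @export
setMethod("haplotypeIds", "HaplotypeTable", function(x) x@ids)

#' @describeIn HaplotypeTable-class read counts per haplotype, named by id.
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))
#' @rdname HaplotypeTable-class
#' @export
setMethod("readCounts", "HaplotypeTable", function(x) {
    stats::setNames(x@counts, x@ids)
})

#' @describeIn HaplotypeTable-class library size N (total reads).
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname HaplotypeTable-class
#' @export
setMethod("totalReads", "HaplotypeTable", function(x) sum(x@counts))

#' @describeIn HaplotypeTable-class observed richness H (number of
#'   haplotypes).
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname HaplotypeTable-class
#' @export
setMethod("nHaplotypes", "HaplotypeTable", function(x) length(x@counts))

#' @describeIn HaplotypeTable-class carried sequences (character(0) when
#'   absent).
#' @export
setGeneric("haplotypeSequences",
    function(x) standardGeneric("haplotypeSequences"))
#' @rdname HaplotypeTable-class
#' @export
setMethod("haplotypeSequences", "HaplotypeTable", function(x) x@sequences)

#' Haplotype relative frequencies
#'
#' Converts read counts to relative frequencies p_i = count_i / N. Because
#' counts are integers, frequencies live on a grid with resolution 1/N (the
#' granularity of the sample): each p_i is an integer multiple of 1/N, and
#' no frequency difference below 1/N is representable. The granularity is
#' attached as an attribute.
#'
#' @param x A \linkS4class{HaplotypeTable}.
#' @return Named numeric vector of frequencies summing to 1, with attribute
#'   \code{"granularity"} equal to 1/N.
#' @examples
#' frequencies(HaplotypeTable(c("a", "b"), c(3, 1)))
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname frequencies
#' @export
setMethod("frequencies", "HaplotypeTable", function(x) {
    N <- sum(x@counts)
    p <- stats::setNames(x@counts / N, x@ids)
    attr(p, "granularity") <- 1 / N
    p
})

setMethod("show", "HaplotypeTable", function(object) {
    N <- sum(object@counts)
    H <- length(object@counts)
    cat(sprintf("HaplotypeTable: %s haplotypes, %s reads\n",
                format(H, big.mark = ",", scientific = FALSE),
                format(N, big.mark = ",", scientific = FALSE)))
    ord <- order(-object@counts, object@ids)
    k <- min(5L, H)
    top <- ord[seq_len(k)]
    cat(sprintf("  %-12s %10s %10s\n", "id", "count", "freq"))
    for (i in top)
        cat(sprintf("  %-12s %10d %10.5f\n", object@ids[i],
                    as.integer(object@counts[i]), object@counts[i] / N))
    if (H > k) cat(sprintf("  ... and %d more\n", H - k))
    sng <- sum(object@counts == 1)
    cat(sprintf("  singletons: %d (%.5f of reads); granularity 1/N = %g\n",
                sng, sng / N, 1 / N))
    invisible(NULL)
})
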