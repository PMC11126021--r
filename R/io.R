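## Readers/writers for the two standard serializations of a haplotype
## abundance sample: two-column TSV count tables, and FASTA with the
## abundance encoded in the header (usearch/vsearch ";size=N;" or "id|N").

.canonicalOrder <- function(x) order(-x@counts, x@ids, method = "radix")

#' Read a haplotype count table from TSV
#'
#' Expects a UTF-8 tab-separated file with two columns, haplotype id and
#' read count. A header line "haplotype\tcount" (any non-integer second
#' field on line 1) is detected and skipped.
#'
#' @param path Path to the TSV file.
#' @return A \linkS4class{HaplotypeTable}; row order of the file is
#'   preserved.
#' @export
readCountsTsv <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty count table: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 2L))
        stop(sprintf("malformed line %d in %s: expected 2 tab-separated %s",
                     which(nf != 2L)[1L], path, "fields"))
    ids <- vapply(parts, `[[`, character(1), 1L)
    cnt <- vapply(parts, `[[`, character(1), 2L)
    start <- 1L
    # a header has a non-numeric count field ("count"); a numeric-looking
    # but non-integer field like "12.5" is a data error, not a header
    if (!grepl("^[0-9]+(\\.[0-9]+)?$", cnt[1L])) start <- 2L
    if (start > length(ids)) stop("no data rows in ", path)
    idx <- start:length(ids)
    bad <- idx[!grepl("^[0-9]+$", cnt[idx])]
    if (length(bad))
        stop(sprintf("non-integer count '%s' at line %d of %s",
                     cnt[bad[1L]], bad[1L], path))
    HaplotypeTable(ids[idx], as.numeric(cnt[idx]))
}

#' Write a haplotype count table as TSV
#'
#' @param x A \linkS4class{HaplotypeTable}.
#' @param path Output path.
#' @param canonical Sort rows by descending count, ties by id ascending
#'   (the package's canonical on-disk order, making outputs deterministic).
#'   Set \code{FALSE} to keep in-memory order.
#' @param header Write the "haplotype\tcount" header line.
#' @return \code{path}, invisibly.
#' @export
writeCountsTsv <- function(x, path, canonical = TRUE, header = TRUE) {
    ord <- if (canonical) .canonicalOrder(x) else seq_along(x@ids)
    rows <- sprintf("%s\t%d", x@ids[ord], as.integer(x@counts[ord]))
    if (header) rows <- c("haplotype\tcount", rows)
    writeLines(rows, path, useBytes = TRUE)
    invisible(path)
}

.parseAbundanceHeader <- function(headers, dialect) {
    if (dialect == "size") {
        m <- regmatches(headers, regexpr("(;|^)size=[0-9]+", headers))
        ok <- lengths(regmatches(headers,
                                 gregexpr("(;|^)size=[0-9]+", headers))) > 0
        counts <- rep(NA_real_, length(headers))
        counts[ok] <- as.numeric(sub("^(;|)size=", "",
                                     unlist(m, use.names = FALSE)))
        ids <- sub(";.*$", "", headers)
    } else {
        ok <- grepl("\\|[0-9]+$", headers)
        counts <- rep(NA_real_, length(headers))
        counts[ok] <- as.numeric(sub("^.*\\|", "", headers[ok]))
        ids <- sub("\\|[0-9]+$", "", headers)
    }
    if (any(!ok))
        stop(sprintf("no parseable abundance in FASTA record '%s' (%s %s)",
                     headers[!ok][1L], "dialect", dialect))
    list(ids = ids, counts = counts)
}

#' Read haplotype abundances from an annotated FASTA
#'
#' Reads dereplicated haplotypes whose abundances are encoded in FASTA
#' headers. Two dialects are supported: \code{"size"}, the usearch/vsearch
#' convention \code{>id;size=N;}, and \code{"pipe"}, \code{>id|N}.
#' Sequences are stored in the table as an inert payload; no computation in
#' the package interprets them.
#'
#' @param path Path to the FASTA file.
#' @param dialect \code{"size"} (default) or \code{"pipe"}.
#' @return A \linkS4class{HaplotypeTable} with sequences attached.
#' @export
readFastaAbundance <- function(path, dialect = c("size", "pipe")) {
    dialect <- match.arg(dialect)
    seqs <- Biostrings::readBStringSet(path)
    if (!length(seqs)) stop("empty FASTA: ", path)
    parsed <- .parseAbundanceHeader(names(seqs), dialect)
    HaplotypeTable(parsed$ids, parsed$counts,
                   sequences = as.character(seqs))
}

#' Write haplotype abundances as an annotated FASTA
#'
#' @inheritParams writeCountsTsv
#' @param dialect Header dialect, \code{"size"} (default) or \code{"pipe"}.
#' @details Tables lacking sequences are written with a single-\code{N}
#'   placeholder sequence per haplotype.
#' @return \code{path}, invisibly.
#' @export
writeFastaAbundance <- function(x, path, dialect = c("size", "pipe"),
                                canonical = TRUE) {
    dialect <- match.arg(dialect)
    ord <- if (canonical) .canonicalOrder(x) else seq_along(x@ids)
    sq <- if (length(x@sequences)) x@sequences[ord]
          else rep("N", length(ord))
    headers <- if (dialect == "size")
        sprintf("%s;size=%d;", x@ids[ord], as.integer(x@counts[ord]))
    else sprintf("%s|%d", x@ids[ord], as.integer(x@counts[ord]))
    set <- Biostrings::BStringSet(stats::setNames(sq, headers))
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}
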