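## exact full-length membership of each sequence in subject, either strand
.exactEitherStrand <- function(seqs, subject, seedK = 31L) {
    if (!length(seqs)) return(logical(0))
    cpp_exact_substring(seqs, subject, seedK) |
        cpp_exact_substring(.revcompChar(seqs), subject, seedK)
}

#' Screen vector-derived read pairs
#'
#' A mate is vector-derived iff it is an exact full-length substring of the
#' doubled (circularized) vector backbone or its reverse complement — the
#' strict reading of a 100 percent identity criterion. A pair is removed
#' when either mate is vector-derived. When a host genome is supplied, host
#' pairs (mate 1 an exact substring of the host, either strand) are counted
#' in the report but kept.
#'
#' @param reads a [ReadPairSet-class].
#' @param vector a [VectorBackbone-class].
#' @param host optional host genome (see [estimateContamination()]).
#' @return `list(kept = <ReadPairSet>, report = <ScreenReport>)`.
#' @export
screenVector <- function(reads, vector, host = NULL) {
    stopifnot(is(reads, "ReadPairSet"), is(vector, "VectorBackbone"))
    v <- as.character(backboneSeq(vector))
    if (!nzchar(v)) stop("vector backbone must be non-empty")
    doubled <- paste0(v, v)
    m1 <- as.character(mate1(reads))
    m2 <- as.character(mate2(reads))
    isVec <- .exactEitherStrand(m1, doubled) | .exactEitherStrand(m2, doubled)
    kept <- reads[!isVec]
    total <- length(reads)
    nHost <- NA_integer_
    hostFrac <- NA_real_
    if (!is.null(host)) {
        hostChar <- .asSeqChar(host)[1]
        nHost <- sum(.exactEitherStrand(m1, hostChar))
        hostFrac <- if (total > 0) nHost / total else 0
    }
    report <- new("ScreenReport",
                  totalPairs = as.integer(total),
                  vectorPairs = as.integer(sum(isVec)),
                  hostPairs = as.integer(nHost),
                  keptPairs = as.integer(total - sum(isVec)),
                  hostFraction = hostFrac)
    list(kept = kept, report = report)
}

#' Estimate host genomic DNA contamination
#'
#' Fraction of pairs whose mate 1 is an exact full-length substring of the
#' host genome or its reverse complement (100 percent identity criterion);
#' membership is tested through a k-mer index with full verification.
#'
#' @param reads a [ReadPairSet-class].
#' @param host host genome (`DNAStringSet` of length 1, `DNAString`, or
#'   character).
#' @return the estimated contamination fraction in `[0, 1]`.
#' @export
estimateContamination <- function(reads, host) {
    stopifnot(is(reads, "ReadPairSet"))
    hostChar <- .asSeqChar(host)[1]
    if (!nzchar(hostChar)) stop("host genome must be non-empty")
    if (length(reads) == 0) return(0)
    mean(.exactEitherStrand(as.character(mate1(reads)), hostChar))
}

#' Bin assembly outcomes by contamination fraction
#'
#' Samples are binned by host fraction into half-open bins of `binWidth`
#' (the last bin is closed at 1); each populated bin reports the fraction
#' of failed assemblies, empty bins are reported with count 0.
#'
#' @param hostFraction numeric vector of per-sample host fractions in
#'   `[0, 1]`.
#' @param assemblyOk logical vector: did the sample assemble successfully?
#' @param binWidth bin width in `(0, 1]`.
#' @return a data.frame: `binStart`, `binEnd`, `count`, `failures`,
#'   `failureFraction` (`NA` for empty bins).
#' @export
binFailures <- function(hostFraction, assemblyOk, binWidth = 0.1) {
    if (binWidth <= 0 || binWidth > 1)
        stop("binWidth must be in (0, 1]")
    stopifnot(length(hostFraction) == length(assemblyOk))
    if (any(hostFraction < 0 | hostFraction > 1))
        stop("host fractions must be in [0, 1]")
    nb <- ceiling(1 / binWidth)
    idx <- pmin(floor(hostFraction / binWidth), nb - 1) + 1
    count <- tabulate(idx, nbins = nb)
    failures <- tabulate(idx[!assemblyOk], nbins = nb)
    data.frame(binStart = (seq_len(nb) - 1) * binWidth,
               binEnd = pmin(seq_len(nb) * binWidth, 1),
               count = count, failures = failures,
               failureFraction = ifelse(count > 0, failures / count,
                                        NA_real_))
}
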