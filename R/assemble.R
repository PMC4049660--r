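#' Count canonical k-mers
#'
#' Counts k-mers over all mates (or sequences), each k-mer recorded as its
#' canonical form (lexicographic minimum of itself and its reverse
#' complement). k must be odd so no k-mer is its own reverse complement.
#' K-mers containing N are skipped.
#'
#' @param reads a [ReadPairSet-class], `DNAStringSet`, or character vector.
#' @param k odd k-mer size (<= longest sequence; <= 63).
#' @return a [KmerTable-class], k-mers in sorted order.
#' @examples
#' countKmers(c("ACGTACGTACGT"), k = 5)
#' @export
countKmers <- function(reads, k) {
    k <- as.integer(k)
    if (k %% 2L == 0L) stop("k must be odd (canonical k-mers)")
    if (k > 63L) stop("k must be <= 63")
    seqs <- if (is(reads, "ReadPairSet")) {
        c(as.character(mate1(reads)), as.character(mate2(reads)))
    } else {
        .asSeqChar(reads)
    }
    if (length(seqs) && k > max(nchar(seqs)))
        stop("k exceeds the read length")
    r <- cpp_count_kmers(seqs, k)
    new("KmerTable", k = k, kmer = as.character(r$kmer),
        count = as.integer(r$count))
}

## order contigs deterministically and attach ids + coverage
.finalizeContigs <- function(seqs, covs) {
    if (!length(seqs)) {
        out <- DNAStringSet()
        mcols(out)$meanKmerCoverage <- numeric(0)
        return(out)
    }
    ord <- order(-nchar(seqs), seqs, method = "radix")
    seqs <- seqs[ord]
    covs <- covs[ord]
    out <- DNAStringSet(seqs)
    names(out) <- sprintf("ctg%05d", seq_along(seqs))
    mcols(out)$meanKmerCoverage <- covs
    out
}

#' Extract unitigs from a k-mer table
#'
#' Drops k-mers below `minCount`, then emits the maximal non-branching
#' paths of the bidirected de Bruijn graph as contigs. Each surviving
#' k-mer appears in exactly one contig, in one orientation. Isolated cycles
#' (circular molecules) are cut at their lexicographically smallest k-mer.
#' Contigs are ordered by descending length then lexicographic sequence and
#' named `ctg00001`, ...; `mcols()$meanKmerCoverage` holds the mean count of
#' the constituent k-mers.
#'
#' @param table a [KmerTable-class].
#' @param minCount k-mer count floor.
#' @return a `DNAStringSet` of contigs (possibly empty).
#' @export
extractUnitigs <- function(table, minCount = 1L) {
    stopifnot(is(table, "KmerTable"))
    r <- cpp_extract_unitigs(table@kmer, table@count, table@k,
                             as.integer(minCount))
    .finalizeContigs(as.character(r$sequence), as.numeric(r$coverage))
}

#' Assemble a pooled read set
#'
#' Canonical k-mer counting at `cfg@kAssembly`, optional masking of k-mers
#' that occur in the (doubled, both-strand) vector backbone, a count floor
#' (`cfg@minKmerCount`, defaulting to 2 when `errorRate > 0` and 1
#' otherwise), unitig extraction, and removal of contigs shorter than
#' `cfg@minContigLen`.
#'
#' Supplying the backbone turns on the k-space counterpart of pre-assembly
#' vector subtraction: junction-spanning mates survive the strict 100
#' percent identity read screen, so their vector portion — which on a
#' circular cosmid is always anchored at the cloning site — is trimmed off
#' each read end, and any k-mer occurring in the doubled backbone (either
#' strand) is masked from the graph. Without this, every vector-insert
#' junction would seed a branch point shared by all clones.
#'
#' @param reads a [ReadPairSet-class] (or sequences accepted by
#'   [countKmers()]).
#' @param cfg a [PoolConfig-class].
#' @param vector optionally a [VectorBackbone-class]; enables junction
#'   trimming and vector k-mer masking.
#' @return a `DNAStringSet` of contigs (see [extractUnitigs()]).
#' @export
assemblePool <- function(reads, cfg, vector = NULL) {
    stopifnot(is(cfg, "PoolConfig"))
    if (!is.null(vector)) {
        seqs <- if (is(reads, "ReadPairSet")) {
            c(as.character(mate1(reads)), as.character(mate2(reads)))
        } else {
            .asSeqChar(reads)
        }
        v <- as.character(backboneSeq(vector))
        seqs <- cpp_junction_trim(seqs, v, cloningSite(vector))
        reads <- seqs[nchar(seqs) >= cfg@kAssembly]
    }
    tab <- countKmers(reads, cfg@kAssembly)
    if (!is.null(vector)) {
        v <- as.character(backboneSeq(vector))
        vtab <- cpp_count_kmers(paste0(v, v), cfg@kAssembly)
        keep <- !(tab@kmer %in% as.character(vtab$kmer))
        tab <- new("KmerTable", k = tab@k, kmer = tab@kmer[keep],
                   count = tab@count[keep])
    }
    minCount <- cfg@minKmerCount
    if (is.na(minCount)) minCount <- if (cfg@errorRate > 0) 2L else 1L
    contigs <- extractUnitigs(tab, minCount)
    contigs <- contigs[width(contigs) >= cfg@minContigLen]
    .finalizeContigs(as.character(contigs),
                     mcols(contigs)$meanKmerCoverage)
}

#' Assembly summary statistics
#'
#' @param contigs a contig `DNAStringSet`.
#' @return a one-row data.frame: `nContigs`, `minLen`, `meanLen`, `maxLen`,
#'   `totalLen`.
#' @export
assemblyStats <- function(contigs) {
    w <- width(contigs)
    data.frame(nContigs = length(w),
               minLen = if (length(w)) min(w) else 0L,
               meanLen = if (length(w)) mean(w) else 0,
               maxLen = if (length(w)) max(w) else 0L,
               totalLen = sum(w))
}
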