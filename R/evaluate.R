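## HSPs of every contig (query) against one reference (subject), with the
## contig id carried along
.contigRefHsps <- function(ref, contigs, seedLen, scoring, xDrop) {
    refSeq <- .asSeqChar(ref)[1]
    ## the reference is indexed once as the query; rows are then reported
    ## with the contig as q and the reference as s (HSPs are symmetric)
    h <- .seedExtendMany(refSeq, as.character(contigs), seedLen = seedLen,
                         scoring = scoring, xDrop = xDrop)
    data.frame(qStart = h$sStart, qEnd = h$sEnd,
               sStart = h$qStart, sEnd = h$qEnd,
               strand = h$strand, score = h$score, matches = h$matches,
               columns = h$columns, identity = h$identity,
               contigId = names(contigs)[h$subjectIdx])
}

#' Alignment identity of retrieved sequence against a reference
#'
#' Column-weighted identity over all qualifying HSPs (alignment length >=
#' `minLen`, the same length floor used by the coverage metrics):
#' `sum(matches) / sum(columns) * 100`. The `"best-hsp"` aggregation uses
#' only the single highest-scoring qualifying HSP.
#'
#' @param ref the clone's reference sequence.
#' @param retrieved a `DNAStringSet` of retrieved contigs.
#' @param minLen minimum HSP length (bp).
#' @param aggregate `"column-weighted"` (default) or `"best-hsp"`.
#' @param seedLen,scoring,xDrop passed to [seedExtend()].
#' @return identity in percent, or `NA` when nothing qualifies.
#' @export
alignmentIdentity <- function(ref, retrieved, minLen = 250,
                              aggregate = c("column-weighted", "best-hsp"),
                              seedLen = 28L, scoring = ScoringScheme(),
                              xDrop = 20L) {
    aggregate <- match.arg(aggregate)
    if (length(retrieved) == 0) return(NA_real_)
    h <- .contigRefHsps(ref, retrieved, seedLen, scoring, xDrop)
    h <- h[h$columns >= minLen, , drop = FALSE]
    if (!nrow(h)) return(NA_real_)
    if (aggregate == "best-hsp") h <- h[which.max(h$score), , drop = FALSE]
    100 * sum(h$matches) / sum(h$columns)
}

## shared implementation of the two coverage metrics
.referenceCoverage <- function(ref, contigs, lenCutoff, idCutoff,
                               seedLen, scoring, xDrop) {
    refLen <- nchar(.asSeqChar(ref)[1])
    if (length(contigs) == 0) return(0)
    h <- .contigRefHsps(ref, contigs, seedLen, scoring, xDrop)
    h <- h[h$columns >= lenCutoff & 100 * h$identity >= idCutoff, ,
           drop = FALSE]
    if (!nrow(h)) return(0)
    m <- mergeIntervals(cbind(h$sStart, h$sEnd))
    100 * m$covered / refLen
}

#' Retrieved coverage of a clone reference
#'
#' Fraction of the reference covered by the contigs retrieved through the
#' clone's end-tags. HSPs must pass the same length and identity filter as
#' [actualCoverage()] (250 bp, 99.6 percent by default) so that retrieved
#' coverage can never exceed actual coverage; reference-side intervals are
#' merged before counting.
#'
#' @param ref the clone's reference sequence.
#' @param retrieved the retrieved contig `DNAStringSet`.
#' @param lenCutoff,idCutoff HSP filters (bp, percent).
#' @param seedLen,scoring,xDrop passed to [seedExtend()].
#' @return coverage in percent of the reference length.
#' @export
retrievedCoverage <- function(ref, retrieved, lenCutoff = 250,
                              idCutoff = 99.6, seedLen = 28L,
                              scoring = ScoringScheme(), xDrop = 20L) {
    .referenceCoverage(ref, retrieved, lenCutoff, idCutoff, seedLen,
                       scoring, xDrop)
}

#' Actual coverage of a clone reference by the whole pool
#'
#' As [retrievedCoverage()], but the reference queries *every* pool contig,
#' correcting for clone fragments that exist in the pooled assembly yet
#' were not retrieved by the end-tags (gaps between tagged fragments).
#'
#' @param ref the clone's reference sequence.
#' @param allContigs every contig of the pooled assembly.
#' @param lenCutoff,idCutoff HSP filters (defaults 250 bp, 99.6 percent).
#' @param seedLen,scoring,xDrop passed to [seedExtend()].
#' @return coverage in percent of the reference length.
#' @export
actualCoverage <- function(ref, allContigs, lenCutoff = 250,
                           idCutoff = 99.6, seedLen = 28L,
                           scoring = ScoringScheme(), xDrop = 20L) {
    .referenceCoverage(ref, allContigs, lenCutoff, idCutoff, seedLen,
                       scoring, xDrop)
}

#' Bin coverage percentages
#'
#' Half-open bins `[0,w) ... [100-w,100]`; the top bin is closed so 100
#' percent falls inside it, and a value exactly at a bin boundary falls in
#' the upper bin.
#'
#' @param values coverage percentages in `[0, 100]`.
#' @param width bin width in percent; must divide 100.
#' @return a data.frame: `binStart`, `binEnd`, `count`.
#' @export
binCoverage <- function(values, width = 10) {
    if (100 %% width != 0) stop("width must divide 100")
    nb <- 100 %/% width
    idx <- pmin(floor(values / width), nb - 1) + 1
    data.frame(binStart = (seq_len(nb) - 1) * width,
               binEnd = seq_len(nb) * width,
               count = tabulate(idx, nbins = nb))
}

#' Pairwise clone sequence similarity
#'
#' For each clone pair, qualifying HSPs (length >= `minLen`, identity >=
#' `minIdentity` percent) between the two references are interval-merged on
#' the shorter clone; similarity is merged covered bases divided by the
#' shorter clone length, hence in `[0, 1]`. Pairs with no qualifying
#' alignment get 0; the diagonal is 1; each pair is computed once and
#' mirrored, so the matrix is exactly symmetric.
#'
#' @param refs a named `DNAStringSet` of clone references.
#' @param minLen,minIdentity HSP filters (bp, percent).
#' @param seedLen,scoring,xDrop passed to [seedExtend()].
#' @return an n x n numeric matrix with clone ids as dimnames.
#' @export
pairwiseSimilarity <- function(refs, minLen = 50, minIdentity = 80,
                               seedLen = 28L, scoring = ScoringScheme(),
                               xDrop = 20L) {
    n <- length(refs)
    stopifnot(n >= 1)
    ids <- names(refs)
    out <- diag(1, n)
    dimnames(out) <- list(ids, ids)
    seqs <- as.character(refs)
    lens <- nchar(seqs)
    for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
            shorter <- if (lens[i] <= lens[j]) i else j
            longer <- if (shorter == i) j else i
            h <- seedExtend(seqs[longer], seqs[shorter], seedLen = seedLen,
                            scoring = scoring, xDrop = xDrop)
            h <- h[h$columns >= minLen & 100 * h$identity >= minIdentity, ,
                   drop = FALSE]
            sim <- if (nrow(h)) {
                min(1, mergeIntervals(cbind(h$sStart, h$sEnd))$covered /
                        lens[shorter])
            } else 0
            out[i, j] <- sim
            out[j, i] <- sim
        }
    }
    out
}

#' Per-base read depth over a reference
#'
#' Each mate is anchored by its first exact `seedLen`-mer with a hit in the
#' reference index, then verified ungapped with at most `maxMismatches`
#' substitutions; a mate anchoring at several loci counts at every verified
#' locus. Both read orientations are tried. With `circular = TRUE` the
#' reference is treated as a circle (junction-spanning placements allowed).
#'
#' @param reads a [ReadPairSet-class] (both mates are mapped).
#' @param ref the reference sequence.
#' @param maxMismatches ungapped verification threshold.
#' @param seedLen anchor k-mer length.
#' @param circular treat the reference as circular.
#' @return `list(perBase = <integer vector, one count per reference base>,
#'   meanDepth = <mean of perBase>)`.
#' @export
depthProfile <- function(reads, ref, maxMismatches = 4L, seedLen = 31L,
                         circular = FALSE) {
    refSeq <- .asSeqChar(ref)[1]
    mates <- if (is(reads, "ReadPairSet")) {
        c(as.character(mate1(reads)), as.character(mate2(reads)))
    } else {
        .asSeqChar(reads)
    }
    if (length(mates) && nchar(refSeq) <= max(nchar(mates)) && !circular)
        stop("reference must be longer than the reads")
    perBase <- cpp_depth_map(mates, refSeq, as.integer(seedLen),
                             as.integer(maxMismatches), circular)
    list(perBase = perBase, meanDepth = mean(perBase))
}

#' Per-clone coverage report
#'
#' Combines clone types, identity, retrieved and actual coverage into the
#' per-clone evaluation table. `retrievedCoverage <= actualCoverage` is
#' asserted for every clone.
#'
#' @param refs named `DNAStringSet` of clone references.
#' @param contigs the pooled assembly.
#' @param classification result of [classifyClones()].
#' @param lenCutoff,idCutoff coverage HSP filters.
#' @param seedLen,scoring,xDrop passed to [seedExtend()].
#' @return a data.frame: `cloneId`, `cloneType`, `identity`,
#'   `retrievedCoverage`, `actualCoverage`.
#' @export
coverageReport <- function(refs, contigs, classification, lenCutoff = 250,
                           idCutoff = 99.6, seedLen = 28L,
                           scoring = ScoringScheme(), xDrop = 20L) {
    ids <- names(refs)
    rows <- lapply(ids, function(id) {
        retrievedIds <- classification$retrieved[[id]]
        retrieved <- contigs[retrievedIds[!is.na(retrievedIds)]]
        rc <- retrievedCoverage(refs[[id]], retrieved, lenCutoff, idCutoff,
                                seedLen, scoring, xDrop)
        ac <- actualCoverage(refs[[id]], contigs, lenCutoff, idCutoff,
                             seedLen, scoring, xDrop)
        stopifnot(rc <= ac + 1e-9)
        data.frame(cloneId = id,
                   cloneType = classification$types$cloneType[
                       classification$types$cloneId == id],
                   identity = alignmentIdentity(refs[[id]], retrieved,
                                                minLen = lenCutoff,
                                                seedLen = seedLen,
                                                scoring = scoring,
                                                xDrop = xDrop),
                   retrievedCoverage = rc, actualCoverage = ac)
    })
    do.call(rbind, rows)
}
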