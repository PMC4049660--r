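## empty HSP table with the canonical column set
.emptyHspFrame <- function() {
    data.frame(qStart = integer(), qEnd = integer(),
               sStart = integer(), sEnd = integer(),
               strand = character(), score = integer(),
               matches = integer(), columns = integer(),
               identity = numeric())
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact dynamic-programming local alignment with affine gap costs (a gap of
#' length g costs `gapOpen + g * gapExtend`) and a deterministic traceback
#' (ties prefer diagonal, then up, then left). Intended as the exact oracle
#' for [seedExtend()] on short-to-moderate sequences; the full matrix is
#' materialized.
#'
#' @param a,b non-empty DNA sequences (character or `DNAString`).
#' @param scoring a [ScoringScheme-class].
#' @return a one-row data.frame with 0-based half-open `qStart`/`qEnd` (on
#'   `a`), `sStart`/`sEnd` (on `b`), `strand` (always `"+"`), `score`,
#'   `matches`, `columns` and `identity` (fraction). A score of 0 yields an
#'   empty alignment (zero-width intervals, identity `NA`).
#' @examples
#' smithWaterman("ACGTACGT", "ACGTACGT")
#' @export
smithWaterman <- function(a, b, scoring = ScoringScheme()) {
    a <- .asSeqChar(a)[1]
    b <- .asSeqChar(b)[1]
    if (!nzchar(a) || !nzchar(b))
        stop("both sequences must be non-empty")
    r <- cpp_sw(a, b, scoring@match, scoring@mismatch,
                scoring@gapOpen, scoring@gapExtend)
    data.frame(qStart = r$q_start, qEnd = r$q_end,
               sStart = r$s_start, sEnd = r$s_end,
               strand = "+", score = r$score,
               matches = r$matches, columns = r$columns,
               identity = if (r$columns > 0) r$matches / r$columns
                          else NA_real_)
}

#' Seed-and-extend local alignment
#'
#' Fast local aligner in the Megablast mould: exact shared `seedLen`-mers
#' seed an ungapped x-drop extension followed by a banded gapped refinement;
#' overlapping hits on the same diagonal are merged; both strands of the
#' subject are searched. Minus-strand HSPs are reported in plus coordinates
#' of the subject after back-mapping. Deterministic, and never scores above
#' the [smithWaterman()] optimum for the same pair.
#'
#' @param query,subject non-empty DNA sequences.
#' @param seedLen exact seed length (>= 11).
#' @param scoring a [ScoringScheme-class].
#' @param xDrop ungapped extension termination threshold.
#' @return a data.frame of HSPs (columns as in [smithWaterman()], `strand`
#'   in `"+"`/`"-"`), sorted by descending score, then descending aligned
#'   columns, then `sStart`, `qStart`, `strand`. Empty when `seedLen`
#'   exceeds either sequence length or no seed matches exist.
#' @examples
#' seedExtend("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT", seedLen = 11)
#' @export
seedExtend <- function(query, subject, seedLen = 28L,
                       scoring = ScoringScheme(), xDrop = 20L) {
    query <- .asSeqChar(query)[1]
    subject <- .asSeqChar(subject)[1]
    if (!nzchar(query) || !nzchar(subject))
        stop("query and subject must be non-empty")
    if (seedLen < 11L) stop("seedLen must be >= 11")
    if (seedLen > nchar(query) || seedLen > nchar(subject))
        return(.emptyHspFrame())

    ns <- nchar(subject)
    one <- function(subj, strand) {
        r <- cpp_seed_extend(query, subj, seedLen,
                             scoring@match, scoring@mismatch,
                             scoring@gapOpen, scoring@gapExtend, xDrop)
        if (!length(r$score)) return(.emptyHspFrame())
        sS <- r$s_start
        sE <- r$s_end
        if (strand == "-") {
            tmp <- ns - sE
            sE <- ns - sS
            sS <- tmp
        }
        data.frame(qStart = r$q_start, qEnd = r$q_end,
                   sStart = sS, sEnd = sE, strand = strand,
                   score = r$score, matches = r$matches,
                   columns = r$columns,
                   identity = r$matches / r$columns)
    }
    out <- rbind(one(subject, "+"), one(.revcompChar(subject), "-"))
    if (nrow(out)) {
        ord <- order(-out$score, -out$columns, out$sStart, out$qStart,
                     out$strand)
        out <- out[ord, , drop = FALSE]
        rownames(out) <- NULL
    }
    out
}

## batched seed-and-extend: one query indexed once against many subjects,
## both strands; rows carry subjectIdx
.seedExtendMany <- function(query, subjects, seedLen = 28L,
                            scoring = ScoringScheme(), xDrop = 20L) {
    ns <- nchar(subjects)
    run <- function(subj, strand) {
        r <- cpp_seed_extend_many(query, subj, seedLen,
                                  scoring@match, scoring@mismatch,
                                  scoring@gapOpen, scoring@gapExtend, xDrop)
        if (!length(r$score)) return(NULL)
        idx <- r$subject_idx
        sS <- r$s_start
        sE <- r$s_end
        if (strand == "-") {
            L <- ns[idx]
            tmp <- L - sE
            sE <- L - sS
            sS <- tmp
        }
        data.frame(subjectIdx = idx, qStart = r$q_start, qEnd = r$q_end,
                   sStart = sS, sEnd = sE, strand = strand, score = r$score,
                   matches = r$matches, columns = r$columns,
                   identity = r$matches / r$columns)
    }
    out <- rbind(run(subjects, "+"),
                 if (length(subjects)) run(.revcompChar(subjects), "-"))
    if (is.null(out))
        out <- cbind(data.frame(subjectIdx = integer()), .emptyHspFrame())
    out
}

#' Merge genomic intervals and report covered bases
#'
#' 0-based half-open intervals are merged into disjoint sorted intervals
#' (via `IRanges::reduce`); the covered base count is the sum of merged
#' widths. Idempotent. Zero-width intervals contribute nothing.
#'
#' @param intervals a two-column matrix or data.frame of `start`, `end`
#'   (0-based half-open).
#' @return `list(intervals = <two-column matrix>, covered = <bases>)`.
#' @examples
#' mergeIntervals(rbind(c(0, 4000), c(3000, 6000)))
#' @export
mergeIntervals <- function(intervals) {
    m <- as.matrix(intervals)
    if (length(m) == 0) m <- matrix(numeric(0), ncol = 2)
    if (ncol(m) != 2) stop("intervals must have two columns (start, end)")
    if (any(m < 0)) stop("negative coordinates are not allowed")
    if (any(m[, 2] < m[, 1])) stop("interval start must be <= end")
    m <- m[m[, 2] > m[, 1], , drop = FALSE]
    if (nrow(m) == 0)
        return(list(intervals = matrix(numeric(0), ncol = 2,
                                       dimnames = list(NULL, c("start", "end"))),
                    covered = 0))
    ir <- reduce(IRanges(start = m[, 1] + 1, end = m[, 2]))
    out <- cbind(start = start(ir) - 1, end = end(ir))
    list(intervals = out, covered = sum(out[, 2] - out[, 1]))
}

#' Write an HSP table as TSV
#'
#' Fixed column order: query, subject, percent identity, alignment length,
#' query and subject coordinates, strand, score.
#'
#' @param hsps a data.frame of HSPs carrying `queryId` and `subjectId`
#'   columns in addition to the [seedExtend()] columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeHspTable <- function(hsps, path) {
    df <- data.frame(query = hsps$queryId, subject = hsps$subjectId,
                     pident = 100 * hsps$identity,
                     length = hsps$columns,
                     q_start = hsps$qStart, q_end = hsps$qEnd,
                     s_start = hsps$sStart, s_end = hsps$sEnd,
                     strand = hsps$strand, score = hsps$score)
    writeTable(df, path)
}
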