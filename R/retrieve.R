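## all qualifying HSPs of a tag against one contig
.tagContigHsps <- function(tagSeq, contigSeq, minIdentity, minTagCov,
                           seedLen, scoring, xDrop) {
    h <- seedExtend(tagSeq, contigSeq, seedLen = seedLen, scoring = scoring,
                    xDrop = xDrop)
    if (!nrow(h)) return(h)
    h[100 * h$identity >= minIdentity &
      h$columns >= minTagCov * nchar(tagSeq), , drop = FALSE]
}

#' Query the contig pool with one end-tag
#'
#' Aligns the tag against every contig with [seedExtend()]; qualifying hits
#' have identity >= `minIdentity` percent and alignment length >=
#' `minTagCov` of the tag length. The best hit maximizes score, ties broken
#' by longer alignment then lexicographic contig id. No qualifying hit
#' yields an `NA` contig.
#'
#' @param tagSeq the tag sequence (character or `DNAString`); must be
#'   non-empty (failed tags are the caller's responsibility to filter).
#' @param contigs a named contig `DNAStringSet`.
#' @param minIdentity minimum percent identity of a qualifying hit.
#' @param minTagCov minimum fraction of the tag covered by the alignment.
#' @param seedLen,scoring,xDrop passed to [seedExtend()].
#' @param tagId id used in the returned record (defaults to the name of
#'   `tagSeq`, else `"tag"`).
#' @return a one-row hit-record data.frame: `tagId`, `tagLen`, `contigId`,
#'   `contigLen`, `identity` (percent), `alignmentLen`.
#' @export
queryPool <- function(tagSeq, contigs, minIdentity = 95, minTagCov = 0.5,
                      seedLen = 28L, scoring = ScoringScheme(),
                      xDrop = 20L, tagId = NULL) {
    if (is.null(tagId))
        tagId <- if (!is.null(names(tagSeq))) names(tagSeq)[1] else "tag"
    tagSeq <- .asSeqChar(tagSeq)[1]
    if (!nzchar(tagSeq))
        stop("cannot query with a failed (empty) end-tag")
    h <- .seedExtendMany(tagSeq, as.character(contigs), seedLen = seedLen,
                         scoring = scoring, xDrop = xDrop)
    h <- h[100 * h$identity >= minIdentity &
           h$columns >= minTagCov * nchar(tagSeq), , drop = FALSE]
    best <- NULL
    if (nrow(h)) {
        cid <- names(contigs)[h$subjectIdx]
        ord <- order(-h$score, -h$columns, cid, method = "radix")
        top <- h[ord[1], ]
        best <- data.frame(contigId = cid[ord[1]],
                           contigLen = width(contigs)[top$subjectIdx],
                           score = top$score, columns = top$columns,
                           identity = top$identity)
    }
    if (is.null(best)) {
        data.frame(tagId = tagId, tagLen = nchar(tagSeq),
                   contigId = NA_character_, contigLen = NA_integer_,
                   identity = NA_real_, alignmentLen = NA_integer_)
    } else {
        data.frame(tagId = tagId, tagLen = nchar(tagSeq),
                   contigId = best$contigId,
                   contigLen = as.integer(best$contigLen),
                   identity = 100 * best$identity,
                   alignmentLen = as.integer(best$columns))
    }
}

#' Retrieve a clone's contigs through its end-tags
#'
#' @param tags an [EndTagSet-class] restricted to one clone (0-2 ok tags).
#' @param contigs a named contig `DNAStringSet`.
#' @param ... passed to [queryPool()].
#' @return `list(contigs = <DNAStringSet of best-hit contigs>,
#'   hits = <hit-record data.frame, one row per ok tag>)`.
#' @export
retrieveClone <- function(tags, contigs, ...) {
    stopifnot(is(tags, "EndTagSet"))
    ok <- which(tagStatus(tags) == "ok")
    hits <- do.call(rbind, lapply(ok, function(i) {
        queryPool(as.character(tagSequences(tags)[[i]]), contigs,
                  tagId = names(tagSequences(tags))[i], ...)
    }))
    if (is.null(hits))
        hits <- data.frame(tagId = character(), tagLen = integer(),
                           contigId = character(), contigLen = integer(),
                           identity = numeric(), alignmentLen = integer())
    ids <- unique(hits$contigId[!is.na(hits$contigId)])
    list(contigs = contigs[ids], hits = hits)
}

#' Classify a clone's retrieval outcome
#'
#' Clone types: `A` — two tags retrieved the same contig; `B` — two tags
#' retrieved different contigs; `C` — of two tags only one retrieved a
#' contig; `D` — a single available tag retrieved a contig;
#' `unretrieved` — tags were available but none retrieved a contig;
#' `excluded` — no usable tags.
#'
#' @param tags the clone's [EndTagSet-class] (both ends).
#' @param hits hit records for the clone's ok tags (from
#'   [retrieveClone()]).
#' @return one of `"A"`, `"B"`, `"C"`, `"D"`, `"unretrieved"`,
#'   `"excluded"`.
#' @export
classifyClone <- function(tags, hits) {
    stopifnot(is(tags, "EndTagSet"))
    nOk <- sum(tagStatus(tags) == "ok")
    if (nrow(hits) != nOk)
        stop("consistency error: one hit record per ok tag is required")
    if (nOk == 0L) return("excluded")
    nHit <- sum(!is.na(hits$contigId))
    if (nOk == 2L) {
        if (nHit == 2L) {
            if (hits$contigId[1] == hits$contigId[2]) return("A")
            return("B")
        }
        if (nHit == 1L) return("C")
        return("unretrieved")
    }
    if (nHit == 1L) return("D")
    "unretrieved"
}

#' Retrieve and classify every clone in a pool
#'
#' @param tags the full [EndTagSet-class].
#' @param contigs a named contig `DNAStringSet`.
#' @param ... passed to [queryPool()].
#' @return `list(types = <data.frame cloneId, cloneType>,
#'   hits = <hit table over all ok tags>,
#'   retrieved = <named list of per-clone contig id vectors>)`.
#' @export
classifyClones <- function(tags, contigs, ...) {
    stopifnot(is(tags, "EndTagSet"))
    cloneIds <- unique(tagClone(tags))
    hitList <- list()
    types <- character(length(cloneIds))
    retrieved <- vector("list", length(cloneIds))
    names(retrieved) <- cloneIds
    for (i in seq_along(cloneIds)) {
        ct <- tags[tagClone(tags) == cloneIds[i]]
        r <- retrieveClone(ct, contigs, ...)
        types[i] <- classifyClone(ct, r$hits)
        hitList[[i]] <- r$hits
        retrieved[[i]] <- names(r$contigs)
    }
    list(types = data.frame(cloneId = cloneIds, cloneType = types),
         hits = do.call(rbind, hitList),
         retrieved = retrieved)
}

#' Delineate a clone inside a consensus contig
#'
#' When both of a clone's end-tags hit the same (possibly multi-clone
#' consensus) contig, the clone's extent on the contig is the interval from
#' the outermost coordinate of one tag's best HSP to the outermost
#' coordinate of the other's, orientation-normalized.
#'
#' @param tags the clone's [EndTagSet-class]; both tags must be ok.
#' @param contig a single contig (`DNAStringSet` of length 1 or
#'   `DNAString`).
#' @param minIdentity,minTagCov,seedLen,scoring,xDrop as in [queryPool()].
#' @return an integer vector `c(start, end)` (0-based half-open on the
#'   contig), or `NULL` when the clone is not delineable on this contig.
#' @export
delineateInConsensus <- function(tags, contig, minIdentity = 95,
                                 minTagCov = 0.5, seedLen = 28L,
                                 scoring = ScoringScheme(), xDrop = 20L) {
    stopifnot(is(tags, "EndTagSet"))
    ok <- which(tagStatus(tags) == "ok")
    if (length(ok) < 2L) return(NULL)
    contigSeq <- .asSeqChar(contig)[1]
    bounds <- matrix(NA_integer_, nrow = 0, ncol = 2)
    for (i in ok) {
        ts <- as.character(tagSequences(tags)[[i]])
        h <- .tagContigHsps(ts, contigSeq, minIdentity, minTagCov,
                            seedLen, scoring, xDrop)
        if (!nrow(h)) return(NULL)
        bounds <- rbind(bounds, c(h$sStart[1], h$sEnd[1]))
    }
    out <- c(start = min(bounds[, 1]), end = max(bounds[, 2]))
    stopifnot(out["end"] - out["start"] <= nchar(contigSeq))
    as.integer(out) -> res
    names(res) <- c("start", "end")
    res
}
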