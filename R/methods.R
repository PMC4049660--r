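## ---- generics -------------------------------------------------------------

#' @export
setGeneric("inserts", function(x) standardGeneric("inserts"))
#' @export
setGeneric("cosmids", function(x) standardGeneric("cosmids"))
#' @export
setGeneric("cloneInfo", function(x) standardGeneric("cloneInfo"))
#' @export
setGeneric("similarityInfo", function(x) standardGeneric("similarityInfo"))
#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))
#' @export
setGeneric("tagStatus", function(x) standardGeneric("tagStatus"))
#' @export
setGeneric("tagClone", function(x) standardGeneric("tagClone"))
#' @export
setGeneric("tagEnd", function(x) standardGeneric("tagEnd"))
#' @export
setGeneric("mate1", function(x) standardGeneric("mate1"))
#' @export
setGeneric("mate2", function(x) standardGeneric("mate2"))
#' @export
setGeneric("truthOrigin", function(x) standardGeneric("truthOrigin"))
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))
#' @export
setGeneric("backboneSeq", function(x) standardGeneric("backboneSeq"))
#' @export
setGeneric("cloningSite", function(x) standardGeneric("cloningSite"))

## ---- accessors ------------------------------------------------------------

#' Accessors for pooltag classes
#'
#' @param x a pooltag S4 object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases inserts cosmids cloneInfo similarityInfo tagSequences tagStatus
#'   tagClone tagEnd mate1 mate2 truthOrigin kmerSize kmerCounts backboneSeq
#'   cloningSite
NULL

#' @rdname accessors
setMethod("inserts", "ClonePool", function(x) x@inserts)
#' @rdname accessors
setMethod("cosmids", "ClonePool", function(x) x@cosmids)
#' @rdname accessors
setMethod("cloneInfo", "ClonePool", function(x) x@info)
#' @rdname accessors
setMethod("similarityInfo", "ClonePool", function(x) x@similarity)
#' @rdname accessors
setMethod("tagSequences", "EndTagSet", function(x) x@sequences)
#' @rdname accessors
setMethod("tagStatus", "EndTagSet", function(x) x@status)
#' @rdname accessors
setMethod("tagClone", "EndTagSet", function(x) x@cloneId)
#' @rdname accessors
setMethod("tagEnd", "EndTagSet", function(x) x@end)
#' @rdname accessors
setMethod("mate1", "ReadPairSet", function(x) x@mate1)
#' @rdname accessors
setMethod("mate2", "ReadPairSet", function(x) x@mate2)
#' @rdname accessors
setMethod("truthOrigin", "ReadPairSet", function(x) x@truthOrigin)
#' @rdname accessors
setMethod("kmerSize", "KmerTable", function(x) x@k)
#' @rdname accessors
setMethod("kmerCounts", "KmerTable",
          function(x) setNames(x@count, x@kmer))
#' @rdname accessors
setMethod("backboneSeq", "VectorBackbone", function(x) x@sequence)
#' @rdname accessors
setMethod("cloningSite", "VectorBackbone", function(x) x@cloningSite)

#' @export
setMethod("length", "ReadPairSet", function(x) length(x@mate1))

#' @export
setMethod("length", "EndTagSet", function(x) length(x@sequences))

#' @export
setMethod("[", "ReadPairSet", function(x, i, j, ..., drop = TRUE) {
    new("ReadPairSet", mate1 = x@mate1[i], mate2 = x@mate2[i],
        truthOrigin = x@truthOrigin[i])
})

#' @export
setMethod("[", "EndTagSet", function(x, i, j, ..., drop = TRUE) {
    new("EndTagSet", sequences = x@sequences[i], cloneId = x@cloneId[i],
        end = x@end[i], status = x@status[i])
})

## ---- show -----------------------------------------------------------------

setMethod("show", "PoolConfig", function(object) {
    cat("PoolConfig:", object@nClones, "clones |",
        sprintf("inserts %d (%d-%d) bp |", round(object@insertLenMean),
                object@insertLenMin, object@insertLenMax),
        sprintf("reads 2x%d bp at %gx |", object@readLen, object@depth),
        sprintf("error %g | contamination %g | k %d | seed %d",
                object@errorRate, object@contaminationFrac,
                object@kAssembly, object@seed), "\n")
})

setMethod("show", "VectorBackbone", function(object) {
    cat("VectorBackbone of", length(object@sequence),
        "bp, cloning site at", object@cloningSite, "(0-based)\n")
})

setMethod("show", "ClonePool", function(object) {
    cat("ClonePool with", length(object@inserts), "clones")
    if (length(object@inserts)) {
        cat(sprintf(": insert widths %d-%d bp (mean %.0f)",
                    min(width(object@inserts)), max(width(object@inserts)),
                    mean(width(object@inserts))))
    }
    ng <- sum(!is.na(object@info$groupId))
    if (ng) cat(";", ng, "clones in overlap groups")
    if (nrow(object@similarity))
        cat(";", nrow(object@similarity), "injected similarity segments")
    cat("\n")
})

setMethod("show", "EndTagSet", function(object) {
    cat("EndTagSet:", length(object@sequences), "tags (",
        sum(object@status == "ok"), "ok,",
        sum(object@status == "failed"), "failed )\n")
})

setMethod("show", "ReadPairSet", function(object) {
    cat("ReadPairSet with", length(object@mate1), "pairs")
    if (length(object@mate1))
        cat(" of width", width(object@mate1)[1])
    if (!all(is.na(object@truthOrigin))) {
        tab <- table(sub(":.*", "", object@truthOrigin))
        cat(" | origins:", paste(names(tab), tab, sep = "=", collapse = " "))
    }
    cat("\n")
})

setMethod("show", "ScreenReport", function(object) {
    cat("ScreenReport:", object@totalPairs, "pairs,",
        object@vectorPairs, "vector (removed),",
        ifelse(is.na(object@hostPairs), "host not assessed",
               paste0(object@hostPairs, " host (kept, fraction ",
                      signif(object@hostFraction, 3), ")")),
        "->", object@keptPairs, "kept\n")
})

setMethod("show", "KmerTable", function(object) {
    cat("KmerTable: k =", object@k, "|", length(object@kmer),
        "canonical k-mers |", sum(object@count), "occurrences\n")
})

setMethod("show", "ScoringScheme", function(object) {
    cat(sprintf("ScoringScheme: match %+d mismatch %+d gapOpen %+d gapExtend %+d\n",
                object@match, object@mismatch, object@gapOpen,
                object@gapExtend))
})
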