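#' Pool simulation and pipeline configuration
#'
#' Holds every tunable parameter of the clone-pool simulator and the pooled
#' assembly/retrieval pipeline. Defaults mirror the study design the package
#' emulates: ~33.5 kb inserts (truncated normal over 25-47 kb), 90-base
#' paired-end reads, pooled assembly k-mer 31 with a 0.5 kb contig floor,
#' 700-base Sanger end-tags whose per-end failure probability (0.313) makes
#' the expected fraction of clones with at least one usable tag match 83/92,
#' and 5 percent host genomic DNA contamination.
#'
#' @slot seed integer master seed; stages derive sub-seeds from it.
#' @slot nClones number of clones in the pool.
#' @slot insertLenMean,insertLenSd,insertLenMin,insertLenMax insert length
#'   distribution (bp): truncated normal clipped to `[min, max]`.
#' @slot readLen paired-end read length (bp).
#' @slot fragmentLenMean,fragmentLenSd sequencing fragment length (bp).
#' @slot depth target fold coverage of the pooled reads over each cosmid.
#' @slot errorRate per-base substitution probability.
#' @slot tagLen Sanger end-tag length (bp).
#' @slot tagFailProb independent failure probability of each end-tag.
#' @slot contaminationFrac fraction of all read pairs drawn from the host
#'   genome.
#' @slot overlapGroups list of `list(size=, overlap=)` entries; each group
#'   tiles nested windows of one source region so that all members pairwise
#'   overlap by at least `overlap` bp.
#' @slot similarityPairs list of `list(clone1=, clone2=, length=, identity=)`
#'   entries; a segment of `clone1`'s insert is copied into `clone2`'s insert
#'   at the stated per-base identity.
#' @slot kAssembly odd k-mer size for the pooled assembly.
#' @slot minContigLen minimum emitted contig length (bp).
#' @slot minKmerCount k-mer count floor for assembly; `NA` selects 2 when
#'   `errorRate > 0` and 1 otherwise.
#' @slot hostGenomeLen simulated host genome length (bp).
#' @slot nSources,sourceLen number and length of simulated source genomes.
#' @slot vectorLen simulated vector backbone length (bp).
#' @slot barcodedDepthFactor per-clone (barcoded-arm) depth as a multiple of
#'   the pooled depth.
#' @slot kBarcoded odd k-mer size for the per-clone reference assemblies.
#' @export
setClass("PoolConfig", representation(
    seed = "integer",
    nClones = "integer",
    insertLenMean = "numeric",
    insertLenSd = "numeric",
    insertLenMin = "integer",
    insertLenMax = "integer",
    readLen = "integer",
    fragmentLenMean = "numeric",
    fragmentLenSd = "numeric",
    depth = "numeric",
    errorRate = "numeric",
    tagLen = "integer",
    tagFailProb = "numeric",
    contaminationFrac = "numeric",
    overlapGroups = "list",
    similarityPairs = "list",
    kAssembly = "integer",
    minContigLen = "integer",
    minKmerCount = "integer",
    hostGenomeLen = "integer",
    nSources = "integer",
    sourceLen = "integer",
    vectorLen = "integer",
    barcodedDepthFactor = "numeric",
    kBarcoded = "integer"
))

setValidity("PoolConfig", function(object) {
    msg <- character()
    probs <- c(errorRate = object@errorRate,
               tagFailProb = object@tagFailProb,
               contaminationFrac = object@contaminationFrac)
    bad <- probs < 0 | probs > 1
    if (any(bad))
        msg <- c(msg, paste0("probabilities outside [0,1]: ",
                             paste(names(probs)[bad], collapse = ", ")))
    if (!(object@insertLenMin <= object@insertLenMean &&
          object@insertLenMean <= object@insertLenMax))
        msg <- c(msg, "need insertLenMin <= insertLenMean <= insertLenMax")
    if (object@kAssembly %% 2L == 0L)
        msg <- c(msg, "kAssembly must be odd (canonical k-mers)")
    if (object@kBarcoded %% 2L == 0L)
        msg <- c(msg, "kBarcoded must be odd (canonical k-mers)")
    if (object@kAssembly >= object@readLen)
        msg <- c(msg, "kAssembly must be smaller than readLen")
    if (object@nClones < 0L) msg <- c(msg, "nClones must be >= 0")
    if (object@depth < 0) msg <- c(msg, "depth must be >= 0")
    for (g in object@overlapGroups)
        if (!all(c("size", "overlap") %in% names(g)))
            msg <- c(msg, "overlapGroups entries need 'size' and 'overlap'")
    for (p in object@similarityPairs)
        if (!all(c("clone1", "clone2", "length", "identity") %in% names(p)))
            msg <- c(msg,
                "similarityPairs entries need 'clone1','clone2','length','identity'")
    if (length(msg)) msg else TRUE
})

#' @param seed,nClones,insertLenMean,insertLenSd,insertLenMin,insertLenMax
#'   see slots.
#' @param readLen,fragmentLenMean,fragmentLenSd,depth,errorRate see slots.
#' @param tagLen,tagFailProb,contaminationFrac,overlapGroups,similarityPairs
#'   see slots.
#' @param kAssembly,minContigLen,minKmerCount,hostGenomeLen see slots.
#' @param nSources,sourceLen,vectorLen,barcodedDepthFactor,kBarcoded see
#'   slots.
#' @return a validated `PoolConfig` object.
#' @examples
#' cfg <- PoolConfig(nClones = 5, depth = 30, insertLenMean = 10000,
#'                   insertLenMin = 9000, insertLenMax = 11000)
#' cfg
#' @rdname PoolConfig-class
#' @export
PoolConfig <- function(seed = 1L, nClones = 92L,
                       insertLenMean = 33500, insertLenSd = 5000,
                       insertLenMin = 25000L, insertLenMax = 47000L,
                       readLen = 90L,
                       fragmentLenMean = 350, fragmentLenSd = 35,
                       depth = 900, errorRate = 0.001,
                       tagLen = 700L, tagFailProb = 0.313,
                       contaminationFrac = 0.05,
                       overlapGroups = list(), similarityPairs = list(),
                       kAssembly = 31L, minContigLen = 500L,
                       minKmerCount = NA_integer_,
                       hostGenomeLen = 2000000L,
                       nSources = 8L, sourceLen = 2000000L,
                       vectorLen = 8000L,
                       barcodedDepthFactor = 10, kBarcoded = 63L) {
    new("PoolConfig",
        seed = as.integer(seed), nClones = as.integer(nClones),
        insertLenMean = as.numeric(insertLenMean),
        insertLenSd = as.numeric(insertLenSd),
        insertLenMin = as.integer(insertLenMin),
        insertLenMax = as.integer(insertLenMax),
        readLen = as.integer(readLen),
        fragmentLenMean = as.numeric(fragmentLenMean),
        fragmentLenSd = as.numeric(fragmentLenSd),
        depth = as.numeric(depth), errorRate = as.numeric(errorRate),
        tagLen = as.integer(tagLen), tagFailProb = as.numeric(tagFailProb),
        contaminationFrac = as.numeric(contaminationFrac),
        overlapGroups = overlapGroups, similarityPairs = similarityPairs,
        kAssembly = as.integer(kAssembly),
        minContigLen = as.integer(minContigLen),
        minKmerCount = as.integer(minKmerCount),
        hostGenomeLen = as.integer(hostGenomeLen),
        nSources = as.integer(nSources), sourceLen = as.integer(sourceLen),
        vectorLen = as.integer(vectorLen),
        barcodedDepthFactor = as.numeric(barcodedDepthFactor),
        kBarcoded = as.integer(kBarcoded))
}

#' Circular cosmid vector backbone
#'
#' The cloning site is the 0-based position on the circle after which the
#' insert is spliced; the two primer positions flank the cloning site and
#' read into the insert, mimicking the vector-anchored Sanger primers that
#' generate end-tags.
#'
#' @slot sequence circular backbone sequence.
#' @slot cloningSite 0-based splice position.
#' @slot primerFwd,primerRev 0-based primer positions flanking the site.
#' @export
setClass("VectorBackbone", representation(
    sequence = "DNAString",
    cloningSite = "integer",
    primerFwd = "integer",
    primerRev = "integer"
))

setValidity("VectorBackbone", function(object) {
    L <- length(object@sequence)
    msg <- character()
    if (object@cloningSite < 0L || object@cloningSite > L)
        msg <- c(msg, "cloningSite must lie within the sequence")
    if (!(object@primerFwd < object@cloningSite &&
          object@primerRev >= object@cloningSite))
        msg <- c(msg, "primer sites must flank the cloning site")
    if (L <= 2L * max(object@cloningSite - object@primerFwd,
                      object@primerRev - object@cloningSite))
        msg <- c(msg, "backbone too short for the primer offsets")
    if (length(msg)) msg else TRUE
})

#' Simulated clone pool
#'
#' Inserts and their circular cosmids (vector + insert), with full truth
#' provenance: source genome, 0-based half-open source interval, strand,
#' optional overlap-group id, and the injected shared-similarity segments.
#'
#' @slot inserts `DNAStringSet` of clone inserts, named by clone id.
#' @slot cosmids `DNAStringSet` of circular cosmid sequences.
#' @slot info data.frame with columns cloneId, sourceId, start, end, strand,
#'   groupId.
#' @slot similarity data.frame of injected shared segments (clone1, clone2,
#'   start1, end1, start2, end2, identity), 0-based half-open on the inserts.
#' @export
setClass("ClonePool", representation(
    inserts = "DNAStringSet",
    cosmids = "DNAStringSet",
    info = "data.frame",
    similarity = "data.frame"
))

setValidity("ClonePool", function(object) {
    msg <- character()
    n <- length(object@inserts)
    if (length(object@cosmids) != n)
        msg <- c(msg, "inserts and cosmids must have equal length")
    if (nrow(object@info) != n)
        msg <- c(msg, "info must have one row per clone")
    if (n > 0) {
        if (!identical(names(object@inserts), object@info$cloneId))
            msg <- c(msg, "insert names must equal info$cloneId")
        d <- width(object@cosmids) - width(object@inserts)
        if (length(unique(d)) > 1)
            msg <- c(msg, "cosmid length must be vector length + insert length")
    }
    if (length(msg)) msg else TRUE
})

#' Sanger end-tags for a clone pool
#'
#' Two tags per clone: the forward tag reads the start of the insert, the
#' reverse tag the reverse complement of its end. Failed tags carry an empty
#' sequence.
#'
#' @slot sequences `DNAStringSet` named `<clone>_F` / `<clone>_R`.
#' @slot cloneId,end,status parallel character vectors; `end` is
#'   `"forward"`/`"reverse"`, `status` is `"ok"`/`"failed"`.
#' @export
setClass("EndTagSet", representation(
    sequences = "DNAStringSet",
    cloneId = "character",
    end = "character",
    status = "character"
))

setValidity("EndTagSet", function(object) {
    n <- length(object@sequences)
    msg <- character()
    if (length(object@cloneId) != n || length(object@end) != n ||
        length(object@status) != n)
        msg <- c(msg, "metadata vectors must parallel the sequences")
    if (!all(object@status %in% c("ok", "failed")))
        msg <- c(msg, "status must be 'ok' or 'failed'")
    if (!all(object@end %in% c("forward", "reverse")))
        msg <- c(msg, "end must be 'forward' or 'reverse'")
    if (n > 0) {
        w <- width(object@sequences)
        if (any(w[object@status == "ok"] == 0))
            msg <- c(msg, "ok tags must have non-empty sequence")
        if (any(w[object@status == "failed"] != 0))
            msg <- c(msg, "failed tags must carry an empty sequence")
    }
    if (length(msg)) msg else TRUE
})

#' Paired-end reads with truth provenance
#'
#' @slot mate1,mate2 `DNAStringSet`s of equal length, named by read id.
#' @slot truthOrigin character: `"clone:<id>"`, `"host"` or `"vector"` for
#'   simulated reads; `NA` for reads of unknown (external) origin.
#' @export
setClass("ReadPairSet", representation(
    mate1 = "DNAStringSet",
    mate2 = "DNAStringSet",
    truthOrigin = "character"
))

setValidity("ReadPairSet", function(object) {
    msg <- character()
    if (length(object@mate1) != length(object@mate2))
        msg <- c(msg, "mate1 and mate2 must have equal length")
    if (length(object@truthOrigin) != length(object@mate1))
        msg <- c(msg, "truthOrigin must parallel the pairs")
    if (length(object@mate1) > 0 &&
        !all(width(object@mate1) == width(object@mate2)))
        msg <- c(msg, "mates of a pair must have equal width")
    if (length(msg)) msg else TRUE
})

#' Vector / host screening report
#'
#' Pair counts from read screening: vector pairs are removed (a pair is
#' vector-derived if either mate is an exact full-length substring of the
#' doubled circular backbone or its reverse complement), host pairs are
#' counted but kept.
#'
#' @slot totalPairs,vectorPairs,hostPairs,keptPairs pair counts
#'   (`hostPairs` is `NA` when no host genome was supplied).
#' @slot hostFraction `hostPairs / totalPairs`.
#' @export
setClass("ScreenReport", representation(
    totalPairs = "integer",
    vectorPairs = "integer",
    hostPairs = "integer",
    keptPairs = "integer",
    hostFraction = "numeric"
))

setValidity("ScreenReport", function(object) {
    msg <- character()
    if (!is.na(object@keptPairs) &&
        object@keptPairs != object@totalPairs - object@vectorPairs)
        msg <- c(msg, "keptPairs must equal totalPairs - vectorPairs")
    if (!is.na(object@hostFraction) &&
        (object@hostFraction < 0 || object@hostFraction > 1))
        msg <- c(msg, "hostFraction must be in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Canonical k-mer count table
#'
#' @slot k k-mer size (odd).
#' @slot kmer canonical k-mers (each the lexicographic minimum of itself and
#'   its reverse complement), in sorted order.
#' @slot count occurrence counts (>= 1).
#' @export
setClass("KmerTable", representation(
    k = "integer",
    kmer = "character",
    count = "integer"
))

setValidity("KmerTable", function(object) {
    msg <- character()
    if (length(object@kmer) != length(object@count))
        msg <- c(msg, "kmer and count must have equal length")
    if (length(object@count) && any(object@count < 1L))
        msg <- c(msg, "counts must be >= 1")
    if (length(object@kmer) && any(nchar(object@kmer) != object@k))
        msg <- c(msg, "all k-mers must have length k")
    if (length(msg)) msg else TRUE
})

#' Alignment scoring scheme
#'
#' Affine-gap scoring: a gap of length g costs `gapOpen + g * gapExtend`.
#' Defaults approximate Megablast-style scoring.
#'
#' @slot match positive match reward.
#' @slot mismatch,gapOpen,gapExtend non-positive penalties.
#' @export
setClass("ScoringScheme", representation(
    match = "integer",
    mismatch = "integer",
    gapOpen = "integer",
    gapExtend = "integer"
))

setValidity("ScoringScheme", function(object) {
    msg <- character()
    if (object@match <= 0L) msg <- c(msg, "match reward must be > 0")
    if (object@mismatch > 0L || object@gapOpen > 0L || object@gapExtend > 0L)
        msg <- c(msg, "penalties must be <= 0")
    if (length(msg)) msg else TRUE
})

#' @param match,mismatch,gapOpen,gapExtend see slots.
#' @return a `ScoringScheme` object.
#' @examples
#' ScoringScheme()
#' @rdname ScoringScheme-class
#' @export
ScoringScheme <- function(match = 1L, mismatch = -2L,
                          gapOpen = -5L, gapExtend = -2L) {
    new("ScoringScheme", match = as.integer(match),
        mismatch = as.integer(mismatch), gapOpen = as.integer(gapOpen),
        gapExtend = as.integer(gapExtend))
}
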