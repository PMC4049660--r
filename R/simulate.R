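#' Generate random source genomes
#'
#' I.i.d. uniform-base sequences standing in for the environmental DNA from
#' which clone inserts are sampled. Deterministic for a fixed seed.
#'
#' @param n number of sources.
#' @param length length of each source (bp).
#' @param seed integer seed.
#' @return a `DNAStringSet` named `src01`, `src02`, ...
#' @examples
#' generateSources(2, 1000, seed = 1)
#' @export
generateSources <- function(n, length, seed = 1L) {
    stopifnot(n >= 0, length > 0)
    set.seed(seed)
    seqs <- vapply(seq_len(n), function(i) .randomDnaOne(length), character(1))
    out <- DNAStringSet(seqs)
    if (n > 0) names(out) <- sprintf("src%02d", seq_len(n))
    out
}

#' Simulate a circular cosmid vector backbone
#'
#' A uniform-random circular sequence with the cloning site at its midpoint
#' and Sanger primer positions 60 bp on either side, reading into the
#' insert.
#'
#' @param length backbone length (bp).
#' @param seed integer seed.
#' @return a [VectorBackbone-class].
#' @export
simulateVector <- function(length = 8000L, seed = 1L) {
    stopifnot(length >= 200)
    set.seed(seed)
    site <- as.integer(length %/% 2L)
    new("VectorBackbone", sequence = DNAString(.randomDnaOne(length)),
        cloningSite = site,
        primerFwd = site - 60L, primerRev = site + 60L)
}

## truncated-normal insert lengths clipped to [min, max]
.drawInsertLengths <- function(n, cfg) {
    out <- integer(0)
    while (length(out) < n) {
        x <- round(rnorm(n * 2 + 10, cfg@insertLenMean, cfg@insertLenSd))
        x <- x[x >= cfg@insertLenMin & x <= cfg@insertLenMax]
        out <- c(out, as.integer(x))
    }
    out[seq_len(n)]
}

#' Generate a simulated clone pool
#'
#' Draws `nClones` inserts from the source genomes (truncated-normal
#' lengths), honours overlap groups by tiling nested windows of one source
#' region so that group members pairwise overlap by at least the configured
#' amount, injects shared-similarity segments between configured clone
#' pairs, and splices each insert into the circular vector at its cloning
#' site.
#'
#' @param sources a `DNAStringSet` of source genomes (see
#'   [generateSources()]).
#' @param vector a [VectorBackbone-class].
#' @param cfg a [PoolConfig-class]; the stage seed is derived from
#'   `cfg@seed`.
#' @return a [ClonePool-class].
#' @export
generateClonePool <- function(sources, vector, cfg) {
    stopifnot(is(vector, "VectorBackbone"), is(cfg, "PoolConfig"))
    if (length(sources) == 0 && cfg@nClones > 0)
        stop("at least one source genome is required")
    if (cfg@nClones > 0 && max(width(sources)) < cfg@insertLenMax)
        stop("sources must be at least as long as the maximum insert")
    set.seed(.stageSeed(cfg@seed, 3L))
    n <- cfg@nClones
    cloneId <- sprintf("clone%02d", seq_len(n))
    lens <- .drawInsertLengths(n, cfg)
    srcChar <- as.character(sources)
    srcIdx <- integer(n)
    startPos <- integer(n)
    strand <- character(n)
    groupId <- rep(NA_character_, n)

    ## overlap groups claim the first clones, in order
    nextClone <- 1L
    gi <- 0L
    for (g in cfg@overlapGroups) {
        gi <- gi + 1L
        size <- as.integer(g$size)
        ov <- as.integer(g$overlap)
        members <- seq(nextClone, length.out = size)
        if (max(members) > n)
            stop("overlap groups require more clones than configured")
        if (ov >= min(lens[members]))
            stop("configuration error: overlap (", ov,
                 " bp) must be smaller than the shortest insert in the group")
        step <- if (size > 1L) (min(lens[members]) - ov) %/% (size - 1L) else 0L
        span <- max((seq_len(size) - 1L) * step + lens[members])
        ok <- which(width(sources) >= span)
        if (!length(ok))
            stop("no source long enough for overlap group ", gi,
                 " (span ", span, " bp)")
        s <- ok[1]
        base <- sample.int(width(sources)[s] - span + 1L, 1L) - 1L
        for (j in seq_len(size)) {
            i <- members[j]
            srcIdx[i] <- s
            startPos[i] <- base + (j - 1L) * step
            strand[i] <- "+"
            groupId[i] <- sprintf("group%02d", gi)
        }
        nextClone <- nextClone + size
    }
    ## non-group clones occupy disjoint source windows: incidental overlap
    ## would confound the controlled design, and overlapGroups is the
    ## explicit mechanism for overlapping clones
    placed <- lapply(seq_along(sources), function(s) {
        g <- which(srcIdx == s)
        cbind(startPos[g], startPos[g] + lens[g])
    })
    for (i in seq(from = nextClone, length.out = n - nextClone + 1L)) {
        ok <- which(width(sources) >= lens[i])
        done <- FALSE
        for (try in seq_len(200L)) {
            s <- if (length(ok) > 1) sample(ok, 1L) else ok
            st <- sample.int(width(sources)[s] - lens[i] + 1L, 1L) - 1L
            clash <- any(placed[[s]][, 1] < st + lens[i] &
                         placed[[s]][, 2] > st)
            if (!clash) {
                srcIdx[i] <- s
                startPos[i] <- st
                strand[i] <- sample(c("+", "-"), 1L)
                placed[[s]] <- rbind(placed[[s]], c(st, st + lens[i]))
                done <- TRUE
                break
            }
        }
        if (!done)
            stop("could not place non-overlapping clones; ",
                 "increase sourceLen or nSources")
    }

    ins <- character(n)
    for (i in seq_len(n)) {
        sl <- substr(srcChar[srcIdx[i]], startPos[i] + 1L,
                     startPos[i] + lens[i])
        ins[i] <- if (strand[i] == "-") .revcompChar(sl) else sl
    }

    ## inject shared-similarity segments
    sim <- data.frame(clone1 = character(), clone2 = character(),
                      start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      identity = numeric())
    for (p in cfg@similarityPairs) {
        i <- as.integer(p$clone1)
        j <- as.integer(p$clone2)
        segLen <- as.integer(p$length)
        idn <- as.numeric(p$identity)
        if (segLen > min(lens[i], lens[j]))
            stop("similarity segment longer than the shorter insert")
        p1 <- sample.int(lens[i] - segLen + 1L, 1L) - 1L
        p2 <- sample.int(lens[j] - segLen + 1L, 1L) - 1L
        seg <- substr(ins[i], p1 + 1L, p1 + segLen)
        seg <- .injectSubstitutions(seg, 1 - idn)
        ins[j] <- paste0(substr(ins[j], 1L, p2),
                         seg,
                         substr(ins[j], p2 + segLen + 1L, lens[j]))
        sim <- rbind(sim, data.frame(
            clone1 = cloneId[i], clone2 = cloneId[j],
            start1 = p1, end1 = p1 + segLen,
            start2 = p2, end2 = p2 + segLen, identity = idn))
    }

    vec <- as.character(backboneSeq(vector))
    site <- cloningSite(vector)
    cos <- if (n) paste0(substr(vec, 1L, site), ins,
                         substr(vec, site + 1L, nchar(vec))) else character(0)

    insertSet <- DNAStringSet(ins)
    names(insertSet) <- cloneId
    cosmidSet <- DNAStringSet(cos)
    names(cosmidSet) <- cloneId
    info <- data.frame(cloneId = cloneId,
                       sourceId = if (n) names(sources)[srcIdx] else character(),
                       start = startPos, end = startPos + lens,
                       strand = strand, groupId = groupId)
    new("ClonePool", inserts = insertSet, cosmids = cosmidSet, info = info,
        similarity = sim)
}

#' Simulate Sanger end-tags
#'
#' Two tags per clone: the forward tag is the first `tagLen` bases of the
#' insert, the reverse tag the reverse complement of its last `tagLen`
#' bases (idealized error-free Sanger reads anchored at the vector-insert
#' junctions). Each tag fails independently with probability
#' `cfg@tagFailProb`; failed tags carry an empty sequence.
#'
#' @param clones a [ClonePool-class].
#' @param vector the [VectorBackbone-class] (the primer anchor; tag content
#'   is taken from the insert ends).
#' @param cfg a [PoolConfig-class].
#' @return an [EndTagSet-class] with ids `<clone>_F` / `<clone>_R`.
#' @export
simulateEndTags <- function(clones, vector, cfg) {
    stopifnot(is(clones, "ClonePool"), is(cfg, "PoolConfig"))
    set.seed(.stageSeed(cfg@seed, 4L))
    n <- length(inserts(clones))
    ins <- as.character(inserts(clones))
    lens <- nchar(ins)
    tl <- pmin(cfg@tagLen, lens)
    fwd <- substr(ins, 1L, tl)
    rev <- .revcompChar(substr(ins, lens - tl + 1L, lens))
    failed <- matrix(runif(2L * n) < cfg@tagFailProb, ncol = 2L)
    seqs <- c(rbind(ifelse(failed[, 1], "", fwd),
                    ifelse(failed[, 2], "", rev)))
    ids <- c(rbind(paste0(names(inserts(clones)), "_F"),
                   paste0(names(inserts(clones)), "_R")))
    out <- DNAStringSet(seqs)
    names(out) <- ids
    new("EndTagSet", sequences = out,
        cloneId = rep(names(inserts(clones)), each = 2L),
        end = rep(c("forward", "reverse"), n),
        status = ifelse(c(t(failed)), "failed", "ok"))
}

## truth label for cosmid pairs: "vector" when either mate lies wholly in
## the vector portion of the circular cosmid, or when its error-free
## sequence is indistinguishable from vector (exact full-length substring of
## the doubled backbone in either orientation)
.labelCosmidPairs <- function(m1, m2, s1, s2, rl, site, insLen, cosLen,
                              vecDoubled, cloneLabel) {
    n <- length(m1)
    lab <- rep(cloneLabel, n)
    insA <- site
    insB <- site + insLen          # the insert interval never wraps
    mateHits <- function(s) {
        s <- s %% cosLen
        wrap <- s + rl > cosLen
        ov <- (s < insB & s + rl > insA) |
            (wrap & (s + rl - cosLen) > insA & insB > 0)
        inside <- !wrap & s >= insA & s + rl <= insB
        list(overlap = ov, inside = inside)
    }
    h1 <- mateHits(s1)
    h2 <- mateHits(s2)
    lab[!h1$overlap | !h2$overlap] <- "vector"
    ## junction mates: overlap the insert but also contain vector sequence
    junc <- which(lab == cloneLabel &
                  ((h1$overlap & !h1$inside) | (h2$overlap & !h2$inside)))
    if (length(junc)) {
        cand <- c(m1[junc], m2[junc])
        hit <- cpp_exact_substring(cand, vecDoubled, 31L) |
            cpp_exact_substring(.revcompChar(cand), vecDoubled, 31L)
        hit <- hit[seq_along(junc)] | hit[seq_along(junc) + length(junc)]
        lab[junc[hit]] <- "vector"
    }
    lab
}

#' Simulate pooled paired-end reads
#'
#' Fragments are drawn uniformly from each circular cosmid (junction-
#' spanning fragments allowed), with Poisson pair counts targeting
#' `cfg@depth` fold coverage, normal fragment lengths, per-base substitution
#' errors at `cfg@errorRate`, and an additional `cfg@contaminationFrac`
#' fraction of all pairs drawn from the host genome. Mate 2 is the reverse
#' complement strand of the fragment end; pairs are randomly flipped so
#' either mate can be the forward one. Truth origins are recorded per pair.
#'
#' @param clones a [ClonePool-class].
#' @param host a single host genome (`DNAStringSet` of length 1,
#'   `DNAString`, or character), or `NULL` when `contaminationFrac` is 0.
#' @param cfg a [PoolConfig-class].
#' @param vector optionally, the [VectorBackbone-class]; when supplied,
#'   junction mates that are sequence-identical to the backbone are truth-
#'   labelled `"vector"` (see the vignette).
#' @return a [ReadPairSet-class].
#' @export
simulateReads <- function(clones, host, cfg, vector = NULL) {
    stopifnot(is(clones, "ClonePool"), is(cfg, "PoolConfig"))
    if (cfg@fragmentLenMean <= cfg@readLen)
        stop("fragmentLenMean must exceed readLen")
    set.seed(.stageSeed(cfg@seed, 5L))
    rl <- cfg@readLen
    cos <- as.character(cosmids(clones))
    vecDoubled <- if (!is.null(vector)) {
        v <- as.character(backboneSeq(vector))
        paste0(v, v)
    } else NULL

    allM1 <- character(0)
    allM2 <- character(0)
    allLab <- character(0)

    for (ci in seq_along(cos)) {
        L <- nchar(cos[ci])
        lambda <- cfg@depth * L / (2 * rl)
        np <- rpois(1L, lambda)
        if (np == 0) next
        doubled <- paste0(cos[ci], cos[ci])
        starts <- sample.int(L, np, replace = TRUE) - 1L
        flen <- pmax(rl, round(rnorm(np, cfg@fragmentLenMean,
                                     cfg@fragmentLenSd)))
        flen <- pmin(flen, L)
        m1 <- substring(doubled, starts + 1L, starts + rl)
        m2 <- .revcompChar(substring(doubled, starts + flen - rl + 1L,
                                     starts + flen))
        ## truth labelling (the insert sits at [site, site+insLen) on the
        ## circular cosmid; everything else is vector backbone)
        cloneLabel <- paste0("clone:", names(cosmids(clones))[ci])
        if (!is.null(vecDoubled)) {
            insLen <- width(inserts(clones))[ci]
            site <- cloningSite(vector)
            lab <- .labelCosmidPairs(m1, m2, starts, starts + flen - rl, rl,
                                     site, insLen, L, vecDoubled, cloneLabel)
        } else {
            lab <- rep(cloneLabel, np)
        }
        ## random strand flip
        flip <- runif(np) < 0.5
        t1 <- m1
        m1[flip] <- m2[flip]
        m2[flip] <- t1[flip]
        allM1 <- c(allM1, m1)
        allM2 <- c(allM2, m2)
        allLab <- c(allLab, lab)
    }

    nCloneTotal <- length(allM1)
    if (cfg@contaminationFrac > 0) {
        if (is.null(host)) stop("host genome required when contaminationFrac > 0")
        hostChar <- .asSeqChar(host)[1]
        G <- nchar(hostChar)
        nHost <- round(cfg@contaminationFrac / (1 - cfg@contaminationFrac) *
                       nCloneTotal)
        if (nHost > 0) {
            flen <- pmax(rl, round(rnorm(nHost, cfg@fragmentLenMean,
                                         cfg@fragmentLenSd)))
            flen <- pmin(flen, G)
            starts <- vapply(flen, function(f)
                sample.int(G - f + 1L, 1L) - 1L, integer(1))
            m1 <- substring(hostChar, starts + 1L, starts + rl)
            m2 <- .revcompChar(substring(hostChar, starts + flen - rl + 1L,
                                         starts + flen))
            flip <- runif(nHost) < 0.5
            t1 <- m1
            m1[flip] <- m2[flip]
            m2[flip] <- t1[flip]
            allM1 <- c(allM1, m1)
            allM2 <- c(allM2, m2)
            allLab <- c(allLab, rep("host", nHost))
        }
    }

    allM1 <- .injectSubstitutions(allM1, cfg@errorRate)
    allM2 <- .injectSubstitutions(allM2, cfg@errorRate)

    ids <- sprintf("read%07d", seq_along(allM1))
    m1set <- DNAStringSet(allM1)
    m2set <- DNAStringSet(allM2)
    names(m1set) <- ids
    names(m2set) <- ids
    new("ReadPairSet", mate1 = m1set, mate2 = m2set, truthOrigin = allLab)
}
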