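## hand-built contig pool and tags for retrieval tests
makeTags <- function(cloneId, fwd, rev,
                     status = c("ok", "ok")) {
    seqs <- Biostrings::DNAStringSet(c(ifelse(status[1] == "ok", fwd, ""),
                                       ifelse(status[2] == "ok", rev, "")))
    names(seqs) <- paste0(cloneId, c("_F", "_R"))
    new("EndTagSet", sequences = seqs, cloneId = rep(cloneId, 2),
        end = c("forward", "reverse"),
        status = status)
}

test_that("queryPool returns the best qualifying hit or none", {
    set.seed(51)
    c1 <- randomDna(5000)
    c2 <- randomDna(3000)
    contigs <- Biostrings::DNAStringSet(c(ctg00001 = c1, ctg00002 = c2))

    tag <- substr(c1, 4301, 5000)        # copied from a contig end
    h <- queryPool(tag, contigs)
    expect_equal(h$contigId, "ctg00001")
    expect_equal(h$identity, 100)
    expect_equal(h$alignmentLen, 700)
    expect_equal(h$tagLen, 700)

    ## no qualifying hit
    h0 <- queryPool(randomDna(700), contigs)
    expect_true(is.na(h0$contigId))

    ## full-length match outscores a half-length match
    tag2 <- substr(c1, 1, 600)
    c3 <- paste0(substr(tag2, 1, 300), randomDna(2000))
    contigs3 <- Biostrings::DNAStringSet(c(full = c1, half = c3))
    h3 <- queryPool(tag2, contigs3)
    expect_equal(h3$contigId, "full")

    expect_error(queryPool("", contigs), "failed")
})

test_that("retrieveClone unions best hits over ok tags", {
    set.seed(52)
    c1 <- randomDna(4000)
    c2 <- randomDna(4000)
    contigs <- Biostrings::DNAStringSet(c(ctgA = c1, ctgB = c2))

    both1 <- makeTags("x", substr(c1, 1, 700), revcomp(substr(c1, 3301, 4000)))
    r <- retrieveClone(both1, contigs)
    expect_equal(names(r$contigs), "ctgA")
    expect_equal(nrow(r$hits), 2)

    split <- makeTags("x", substr(c1, 1, 700), revcomp(substr(c2, 3301, 4000)))
    r2 <- retrieveClone(split, contigs)
    expect_setequal(names(r2$contigs), c("ctgA", "ctgB"))

    none <- makeTags("x", "", "", status = c("failed", "failed"))
    r3 <- retrieveClone(none, contigs)
    expect_length(r3$contigs, 0)
    expect_equal(nrow(r3$hits), 0)
})

test_that("classifyClone implements the clone typology totally", {
    set.seed(53)
    c1 <- randomDna(4000)
    c2 <- randomDna(4000)
    contigs <- Biostrings::DNAStringSet(c(ctgA = c1, ctgB = c2))
    hit <- function(tags) retrieveClone(tags, contigs)$hits

    tA <- makeTags("x", substr(c1, 1, 700), revcomp(substr(c1, 3301, 4000)))
    expect_equal(classifyClone(tA, hit(tA)), "A")

    tB <- makeTags("x", substr(c1, 1, 700), revcomp(substr(c2, 3301, 4000)))
    expect_equal(classifyClone(tB, hit(tB)), "B")

    tC <- makeTags("x", substr(c1, 1, 700), randomDna(700))
    expect_equal(classifyClone(tC, hit(tC)), "C")

    tD <- makeTags("x", substr(c1, 1, 700), "", status = c("ok", "failed"))
    expect_equal(classifyClone(tD, hit(tD)), "D")

    tU <- makeTags("x", randomDna(700), randomDna(700))
    expect_equal(classifyClone(tU, hit(tU)), "unretrieved")

    tE <- makeTags("x", "", "", status = c("failed", "failed"))
    expect_equal(classifyClone(tE, hit(tE)), "excluded")

    expect_error(classifyClone(tA, hit(tA)[1, , drop = FALSE]),
                 "consistency")
})

test_that("classifyClones labels every clone exactly once", {
    cfg <- smallCfg(seed = 54, nClones = 3, insertLen = 5000, depth = 40,
                    tagFailProb = 0.4)
    src <- generateSources(cfg@nSources, cfg@sourceLen, seed = 1)
    vec <- simulateVector(cfg@vectorLen, seed = 2)
    pool <- generateClonePool(src, vec, cfg)
    tags <- simulateEndTags(pool, vec, cfg)
    reads <- simulateReads(pool, NULL, cfg, vector = vec)
    contigs <- assemblePool(reads, cfg, vector = vec)
    cl <- classifyClones(tags, contigs)
    expect_equal(sort(cl$types$cloneId), sort(cloneInfo(pool)$cloneId))
    expect_equal(nrow(cl$types), 3)
    expect_true(all(cl$types$cloneType %in%
                    c("A", "B", "C", "D", "unretrieved", "excluded")))
})

test_that("delineateInConsensus spans the outermost tag coordinates", {
    set.seed(55)
    contig <- randomDna(35000)

    ## tags at the two ends -> full span
    tFull <- makeTags("x", substr(contig, 1, 700),
                      revcomp(substr(contig, 34301, 35000)))
    d <- delineateInConsensus(tFull, contig)
    expect_equal(unname(d), c(0, 35000))

    ## clone embedded mid-consensus -> interval strictly inside
    tMid <- makeTags("x", substr(contig, 5001, 5700),
                     revcomp(substr(contig, 19301, 20000)))
    d2 <- delineateInConsensus(tMid, contig)
    expect_equal(unname(d2), c(5000, 20000))

    ## a tag that misses the contig -> not delineable
    tMiss <- makeTags("x", substr(contig, 1, 700), randomDna(700))
    expect_null(delineateInConsensus(tMiss, contig))

    ## fewer than two ok tags -> not delineable
    tOne <- makeTags("x", substr(contig, 1, 700), "",
                     status = c("ok", "failed"))
    expect_null(delineateInConsensus(tOne, contig))
})
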