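test_that("alignmentIdentity is column-weighted matches over columns", {
    set.seed(61)
    ref <- randomDna(5000)
    ctg <- Biostrings::DNAStringSet(c(ctg1 = ref))
    expect_equal(alignmentIdentity(ref, ctg), 100)

    ## one substitution in a 1000-column alignment: 999/1000
    frag <- mutateBases(substr(ref, 1001, 2000), 1)
    one <- Biostrings::DNAStringSet(c(ctg1 = frag))
    expect_equal(alignmentIdentity(ref, one), 99.9, tolerance = 0.011)

    expect_true(is.na(alignmentIdentity(ref, Biostrings::DNAStringSet())))
    ## nothing passes the length floor
    short <- Biostrings::DNAStringSet(c(s = substr(ref, 1, 200)))
    expect_true(is.na(alignmentIdentity(ref, short, minLen = 250)))
})

test_that("coverage metrics merge reference intervals at the cutoffs", {
    set.seed(62)
    ref <- randomDna(10000)

    full <- Biostrings::DNAStringSet(c(ctg1 = ref))
    expect_equal(retrievedCoverage(ref, full), 100)

    pre <- Biostrings::DNAStringSet(c(ctg1 = substr(ref, 1, 4800)))
    expect_equal(retrievedCoverage(ref, pre), 48, tolerance = 0.001)

    ## overlapping contigs: [0, 0.4L) + [0.3L, 0.6L) -> 60% (interval-merge
    ## oracle: union covers 6000 of 10000 bases)
    two <- Biostrings::DNAStringSet(c(a = substr(ref, 1, 4000),
                                      b = substr(ref, 3001, 6000)))
    expect_equal(retrievedCoverage(ref, two), 60, tolerance = 0.001)

    ## a diverged contig fails the 99.6% identity cutoff
    div <- Biostrings::DNAStringSet(c(d = mutateBases(substr(ref, 1, 4000),
                                                      80)))
    expect_equal(retrievedCoverage(ref, div), 0)
    expect_equal(retrievedCoverage(ref, Biostrings::DNAStringSet()), 0)
})

test_that("actual coverage dominates retrieved coverage", {
    set.seed(63)
    ref <- randomDna(10000)
    retrieved <- Biostrings::DNAStringSet(c(a = substr(ref, 1, 4800)))
    all <- c(retrieved,
             Biostrings::DNAStringSet(c(b = substr(ref, 5201, 9800))))
    rc <- retrievedCoverage(ref, retrieved)
    ac <- actualCoverage(ref, all)
    expect_equal(rc, 48, tolerance = 0.001)
    expect_equal(ac, 94, tolerance = 0.001)
    expect_gt(ac, rc)
    expect_equal(actualCoverage(ref, retrieved), rc)   # same evidence
    expect_equal(actualCoverage(ref, Biostrings::DNAStringSet()), 0)
})

test_that("coverage binning uses half-open bins with a closed top bin", {
    b <- binCoverage(c(100, 100))
    expect_equal(b$count[b$binStart == 90], 2)
    b2 <- binCoverage(90)
    expect_equal(b2$count[b2$binStart == 90], 1)
    b3 <- binCoverage(seq(0, 99))
    expect_true(all(b3$count == 10))
    expect_equal(sum(binCoverage(runif(37) * 100)$count), 37)
    expect_error(binCoverage(50, width = 30), "divide")
})

test_that("pairwise similarity is symmetric with unit diagonal", {
    set.seed(64)
    a <- randomDna(8000)
    bSub <- substr(a, 2001, 6000)        # exact substring, shorter
    c1 <- randomDna(5000)
    refs <- Biostrings::DNAStringSet(c(a = a, b = bSub, c = c1))
    m <- pairwiseSimilarity(refs)
    expect_equal(diag(m), c(a = 1, b = 1, c = 1))
    expect_identical(m, t(m))
    expect_equal(m["a", "b"], 1)         # substring: shorter fully covered
    expect_equal(m["a", "c"], 0)
    expect_equal(m["b", "c"], 0)

    ## independent random clones have similarity 0
    for (i in 1:10) {
        r2 <- Biostrings::DNAStringSet(c(x = randomDna(6000),
                                         y = randomDna(6000)))
        expect_equal(pairwiseSimilarity(r2)["x", "y"], 0)
    }
})

test_that("depth profiles match the Lander-Waterman expectation", {
    set.seed(65)
    ref <- randomDna(4000)

    empty <- depthProfile(character(0), ref)
    expect_true(all(empty$perBase == 0))
    expect_equal(empty$meanDepth, 0)

    ## N error-free reads uniform over the circular reference
    doubled <- paste0(ref, ref)
    n <- 2000
    starts <- sample(4000, n, replace = TRUE)
    mates <- substring(doubled, starts, starts + 89)
    dp <- depthProfile(mates, ref, circular = TRUE)
    expected <- n * 90 / 4000
    expect_lt(abs(dp$meanDepth - expected), 3 * sqrt(expected))
    expect_length(dp$perBase, 4000)

    ## reads only from the first half leave the second half empty
    startsH <- sample(1000, 500, replace = TRUE)
    matesH <- substring(ref, startsH, startsH + 89)
    dpH <- depthProfile(matesH, ref)
    expect_true(all(dpH$perBase[1200:4000] == 0))
    expect_gt(mean(dpH$perBase[1:1000]), 0)

    ## mismatch tolerance: a mate with <= 4 substitutions still maps
    m <- substr(ref, 101, 190)
    dpM <- depthProfile(c(mutateBases(m, 4)), ref, maxMismatches = 4,
                        seedLen = 11)
    expect_equal(sum(dpM$perBase), 90)
    dpX <- depthProfile(c(mutateBases(m, 30)), ref, maxMismatches = 4,
                        seedLen = 11)
    expect_equal(sum(dpX$perBase), 0)
})

test_that("coverageReport asserts retrieved <= actual per clone", {
    cfg <- smallCfg(seed = 66, nClones = 2, insertLen = 5000, depth = 40)
    src <- generateSources(cfg@nSources, cfg@sourceLen, seed = 1)
    vec <- simulateVector(cfg@vectorLen, seed = 2)
    pool <- generateClonePool(src, vec, cfg)
    tags <- simulateEndTags(pool, vec, cfg)
    reads <- simulateReads(pool, NULL, cfg, vector = vec)
    contigs <- assemblePool(reads, cfg, vector = vec)
    cl <- classifyClones(tags, contigs)
    rep <- coverageReport(inserts(pool), contigs, cl)
    expect_equal(nrow(rep), 2)
    expect_true(all(rep$retrievedCoverage <= rep$actualCoverage + 1e-9))
    expect_true(all(rep$retrievedCoverage >= 0 & rep$actualCoverage <= 100))
})
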