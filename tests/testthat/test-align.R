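test_that("smithWaterman handles identity, divergence and the linear-gap case", {
    r <- smithWaterman("ACGTACGT", "ACGTACGT",
                       ScoringScheme(1, -1, 0, -1))
    expect_equal(r$score, 8)
    expect_equal(r$identity, 1)
    expect_equal(c(r$qStart, r$qEnd), c(0, 8))

    ## linear gap costs (gapOpen 0): optimum verified against an exhaustive
    ## DP oracle for this instance
    r2 <- smithWaterman("ACACACTA", "AGCACACA", ScoringScheme(2, -1, 0, -1))
    expect_equal(r2$score, 12)

    r3 <- smithWaterman("AAAA", "CCCC")
    expect_equal(r3$score, 0)
    expect_equal(r3$columns, 0)
    expect_true(is.na(r3$identity))

    expect_error(smithWaterman("", "ACGT"), "non-empty")
})

test_that("smithWaterman agrees with Biostrings pairwiseAlignment", {
    ## independent oracle: same affine model (gap of length g costs
    ## gapOpening + g * gapExtension)
    set.seed(10)
    sm <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = TRUE)
    for (i in 1:25) {
        a <- randomDna(sample(30:120, 1))
        b <- if (i %% 2 == 0) {
            ## deletion variant to force gapped optima
            d <- sample(20:60, 1)
            paste0(substr(a, 1, d), substr(a, d + sample(1:5, 1) + 1,
                                           nchar(a)))
        } else {
            randomDna(sample(30:120, 1))
        }
        ours <- smithWaterman(a, b)$score
        oracle <- Biostrings::pairwiseAlignment(
            a, b, type = "local", substitutionMatrix = sm,
            gapOpening = 5, gapExtension = 2)
        expect_equal(ours, max(0, Biostrings::score(oracle)))
    }
})

test_that("seedExtend finds full-length hits on both strands", {
    set.seed(11)
    s <- randomDna(5000)
    h <- seedExtend(s, s)
    expect_equal(nrow(h), 1)
    expect_equal(h$identity, 1)
    expect_equal(c(h$qStart, h$qEnd, h$sStart, h$sEnd), c(0, 5000, 0, 5000))
    expect_equal(h$strand, "+")

    h2 <- seedExtend(s, revcomp(s))
    expect_equal(h2$strand[1], "-")
    expect_equal(h2$identity[1], 1)
    expect_equal(c(h2$sStart[1], h2$sEnd[1]), c(0, 5000))

    ## seed longer than the sequences: empty, not an error
    expect_equal(nrow(seedExtend("ACGTACGTACGTACG", "ACGTACGTACGTACG",
                                 seedLen = 20)), 0)
    expect_error(seedExtend("ACGT", "ACGT", seedLen = 5), ">= 11")
})

test_that("seedExtend matches the Smith-Waterman optimum and never exceeds it", {
    set.seed(12)
    agree <- 0
    for (i in 1:60) {
        a <- randomDna(200)
        b <- mutateBases(a, 5)
        sw <- smithWaterman(a, b)$score
        se <- seedExtend(a, b)
        top <- if (nrow(se)) se$score[1] else 0
        expect_lte(top, sw)
        if (top == sw) agree <- agree + 1
    }
    expect_gte(agree / 60, 0.95)
})

test_that("HSP identity converges to one minus the substitution rate", {
    set.seed(13)
    a <- randomDna(10000)
    b <- mutateBases(a, 100)              # rate 0.01
    h <- seedExtend(a, b)
    expect_equal(h$identity[1], 0.99, tolerance = 0.005)
})

test_that("mergeIntervals matches per-base boolean counting", {
    ## frozen example, oracle-verified: union of [0,4000) and [3000,6000)
    m <- mergeIntervals(rbind(c(0, 4000), c(3000, 6000)))
    expect_equal(m$covered, 6000)
    expect_equal(nrow(m$intervals), 1)

    expect_equal(mergeIntervals(matrix(numeric(0), ncol = 2))$covered, 0)

    nested <- mergeIntervals(rbind(c(0, 100), c(10, 20)))
    expect_equal(nested$covered, 100)
    expect_equal(unname(nested$intervals[1, ]), c(0, 100))

    ## property: equality with a boolean-array oracle on random instances
    set.seed(14)
    for (i in 1:50) {
        k <- sample(1:12, 1)
        st <- sample(0:500, k, replace = TRUE)
        en <- st + sample(0:80, k, replace = TRUE)
        m <- mergeIntervals(cbind(st, en))
        covered <- logical(600)
        for (j in seq_len(k))
            if (en[j] > st[j]) covered[(st[j] + 1):en[j]] <- TRUE
        expect_equal(m$covered, sum(covered))
        ## idempotence
        expect_equal(mergeIntervals(m$intervals)$covered, m$covered)
    }

    expect_error(mergeIntervals(rbind(c(-1, 5))), "negative")
    expect_error(mergeIntervals(rbind(c(5, 2))), "start")
})

test_that("seedExtend output is deterministic and sorted by score", {
    set.seed(15)
    a <- randomDna(2000)
    s <- paste0(randomDna(500), a, randomDna(500), substr(a, 1, 800),
                randomDna(200))
    h1 <- seedExtend(a, s)
    h2 <- seedExtend(a, s)
    expect_identical(h1, h2)
    expect_true(all(diff(h1$score) <= 0))
    expect_gte(nrow(h1), 2)               # full copy + partial copy
})
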