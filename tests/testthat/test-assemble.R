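test_that("countKmers counts canonically and validates k", {
    set.seed(31)
    read <- randomDna(90)
    tab <- countKmers(read, 31)
    expect_equal(sum(kmerCounts(tab)), 60)          # L - k + 1

    ## canonical symmetry: a read and its reverse complement count the same
    tab2 <- countKmers(c(read, revcomp(read)), 31)
    expect_identical(tab2@kmer, tab@kmer)
    expect_identical(tab2@count, tab@count * 2L)

    ## per-position brute force on tiling reads
    g <- randomDna(100)
    reads <- tilingReads(g, readLen = 40, step = 1)
    tab3 <- countKmers(reads, 11)
    for (i in sample(length(tab3@kmer), 10)) {
        km <- tab3@kmer[i]
        brute <- 0
        for (r in reads) {
            for (p in 1:(nchar(r) - 10)) {
                w <- substr(r, p, p + 10)
                if (w == km || revcomp(w) == km) brute <- brute + 1
            }
        }
        expect_equal(tab3@count[i], brute)
    }

    expect_error(countKmers(read, 30), "odd")
    expect_error(countKmers(substr(read, 1, 40), 61), "read length")
    expect_error(countKmers(read, 65), "<= 63")

    ## k-mers containing N are skipped
    tabN <- countKmers("ACGTNACGTACGTAC", 11)
    expect_length(tabN@kmer, 0)
})

test_that("unitig extraction reconstructs a unique sequence perfectly", {
    set.seed(32)
    g <- randomDna(5000)
    ctg <- extractUnitigs(countKmers(tilingReads(g, step = 7), 31), 1)
    expect_length(ctg, 1)
    expect_true(as.character(ctg[[1]]) %in% c(g, revcomp(g)))

    ## min_count above the global maximum empties the graph
    expect_length(extractUnitigs(countKmers(tilingReads(g), 31), 1000), 0)
})

test_that("an internal repeat branches the graph into source substrings", {
    set.seed(33)
    rep100 <- randomDna(100)
    sA <- paste0(randomDna(950), rep100, randomDna(950))
    sB <- paste0(randomDna(950), rep100, randomDna(950))
    reads <- c(tilingReads(sA), tilingReads(sB))
    ctg <- extractUnitigs(countKmers(reads, 31), 1)
    expect_gte(length(ctg), 3)
    for (x in as.character(ctg)) {
        expect_true(grepl(x, sA, fixed = TRUE) ||
                    grepl(x, sB, fixed = TRUE) ||
                    grepl(revcomp(x), sA, fixed = TRUE) ||
                    grepl(revcomp(x), sB, fixed = TRUE))
    }
})

test_that("circular molecules are emitted once, cut deterministically", {
    set.seed(34)
    circ <- randomDna(3000)
    doubled <- paste0(circ, circ)
    starts <- seq(1, 3000, by = 5)
    reads <- substring(doubled, starts, starts + 89)
    ctg <- extractUnitigs(countKmers(reads, 31), 1)
    expect_length(ctg, 1)
    expect_equal(Biostrings::width(ctg), 3000 + 31 - 1)
    tripled <- paste0(doubled, circ)
    x <- as.character(ctg[[1]])
    expect_true(grepl(x, tripled, fixed = TRUE) ||
                grepl(revcomp(x), tripled, fixed = TRUE))
})

test_that("surviving k-mers are conserved in the contigs, exactly once", {
    set.seed(35)
    reads <- c(tilingReads(randomDna(2000)), tilingReads(randomDna(1500)))
    tab <- countKmers(reads, 31)
    ctg <- extractUnitigs(tab, 1)
    back <- countKmers(as.character(ctg), 31)
    expect_identical(back@kmer, tab@kmer)
    expect_true(all(back@count == 1L))
})

test_that("assembly is invariant to read input order", {
    set.seed(36)
    reads <- tilingReads(randomDna(4000), step = 9)
    c1 <- extractUnitigs(countKmers(reads, 31), 1)
    c2 <- extractUnitigs(countKmers(rev(reads), 31), 1)
    expect_identical(as.character(c1), as.character(c2))
})

test_that("assemblePool recovers a clone insert and filters short contigs", {
    cfg <- smallCfg(seed = 37, nClones = 1, insertLen = 6000, depth = 50)
    src <- generateSources(cfg@nSources, cfg@sourceLen, seed = 1)
    vec <- simulateVector(cfg@vectorLen, seed = 2)
    pool <- generateClonePool(src, vec, cfg)
    reads <- simulateReads(pool, NULL, cfg, vector = vec)
    contigs <- assemblePool(reads, cfg, vector = vec)
    expect_length(contigs, 1)
    expect_true(all(Biostrings::width(contigs) >= cfg@minContigLen))
    ins <- as.character(inserts(pool)[[1]])
    x <- as.character(contigs[[1]])
    expect_true(grepl(ins, x, fixed = TRUE) ||
                grepl(ins, revcomp(x), fixed = TRUE))

    expect_length(assemblePool(character(0), cfg), 0)
})

test_that("low-rate substitution errors do not corrupt assembled contigs", {
    ## every contig aligns to a true cosmid at >= 99.9% identity over its
    ## full length when errorRate <= 0.001 and the count floor is 2
    cfg <- smallCfg(seed = 38, nClones = 3, insertLen = 6000, depth = 60,
                    errorRate = 0.001)
    src <- generateSources(cfg@nSources, cfg@sourceLen, seed = 1)
    vec <- simulateVector(cfg@vectorLen, seed = 2)
    pool <- generateClonePool(src, vec, cfg)
    reads <- simulateReads(pool, NULL, cfg, vector = vec)
    contigs <- assemblePool(reads, cfg, vector = vec)
    expect_gte(length(contigs), 3)
    for (ci in seq_along(contigs)) {
        best <- NULL
        for (ins in as.character(inserts(pool))) {
            h <- seedExtend(as.character(contigs[[ci]]), ins)
            if (nrow(h) && (is.null(best) || h$score[1] > best$score))
                best <- h[1, ]
        }
        expect_false(is.null(best))
        expect_gte(best$identity, 0.999)
        ## near-full-length (a chimera would align only piecewise); tips may
        ## carry a few error-derived bases outside the local alignment
        expect_gte(best$columns, Biostrings::width(contigs)[ci] * 0.99)
    }
})

test_that("assembly statistics summarize the contig set", {
    x <- Biostrings::DNAStringSet(c(a = randomDna(1000), b = randomDna(500)))
    st <- assemblyStats(x)
    expect_equal(st$nContigs, 2)
    expect_equal(st$minLen, 500)
    expect_equal(st$meanLen, 750)
    expect_equal(st$maxLen, 1000)
    expect_equal(assemblyStats(Biostrings::DNAStringSet())$nContigs, 0)
})
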