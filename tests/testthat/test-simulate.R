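test_that("generateSources is deterministic with near-uniform composition", {
    expect_length(generateSources(0, 100), 0)

    s1 <- generateSources(2, 1e5, seed = 21)
    s2 <- generateSources(2, 1e5, seed = 21)
    expect_identical(as.character(s1), as.character(s2))

    ## GC fraction: binomial sd at n = 1e5 is ~0.0016, so 0.5 +/- 0.01
    gc <- Biostrings::letterFrequency(s1, "GC", as.prob = TRUE)
    expect_true(all(abs(gc - 0.5) < 0.01))
})

test_that("clone pools honour lengths, provenance, overlap and similarity", {
    cfg <- smallCfg(seed = 22, nClones = 6,
                    overlapGroups = list(list(size = 3, overlap = 2000)),
                    similarityPairs = list(list(clone1 = 5, clone2 = 6,
                                                length = 3000,
                                                identity = 1)))
    src <- generateSources(cfg@nSources, cfg@sourceLen, seed = 1)
    vec <- simulateVector(cfg@vectorLen, seed = 2)
    pool <- generateClonePool(src, vec, cfg)
    info <- cloneInfo(pool)
    expect_equal(nrow(info), 6)
    w <- Biostrings::width(inserts(pool))
    expect_true(all(w >= cfg@insertLenMin & w <= cfg@insertLenMax))
    expect_equal(Biostrings::width(cosmids(pool)) - w,
                 rep(cfg@vectorLen, 6))

    ## inserts equal the strand-adjusted source slice (no similarity edits
    ## for clones 1-4)
    for (i in 1:4) {
        sl <- substr(as.character(src[[info$sourceId[i]]]),
                     info$start[i] + 1, info$end[i])
        if (info$strand[i] == "-") sl <- revcomp(sl)
        expect_equal(as.character(inserts(pool)[[i]]), sl)
    }

    ## overlap group: pairwise source-interval intersections >= overlap
    g <- info[!is.na(info$groupId), ]
    expect_equal(nrow(g), 3)
    expect_length(unique(g$sourceId), 1)
    for (i in 1:2) for (j in (i + 1):3) {
        ov <- min(g$end[i], g$end[j]) - max(g$start[i], g$start[j])
        expect_gte(ov, 2000)
    }

    ## similarity pair: exact shared 3000-bp substring
    si <- similarityInfo(pool)
    expect_equal(nrow(si), 1)
    seg <- substr(as.character(inserts(pool)[["clone06"]]),
                  si$start2 + 1, si$end2)
    expect_true(grepl(seg, as.character(inserts(pool)[["clone05"]]),
                      fixed = TRUE))

    ## cosmid = vector spliced at the cloning site
    cosmid <- as.character(cosmids(pool)[[1]])
    v <- as.character(backboneSeq(vec))
    site <- cloningSite(vec)
    expect_equal(substr(cosmid, 1, site), substr(v, 1, site))
    expect_equal(substr(cosmid, site + w[1] + 1, nchar(cosmid)),
                 substr(v, site + 1, nchar(v)))

    ## n = 0 clones
    cfg0 <- smallCfg(nClones = 0)
    expect_length(inserts(generateClonePool(src, vec, cfg0)), 0)

    ## overlap >= shorter insert is a configuration error
    cfgBad <- smallCfg(nClones = 3, insertLen = 6000,
                       overlapGroups = list(list(size = 3, overlap = 6500)))
    expect_error(generateClonePool(src, vec, cfgBad), "overlap")
})

test_that("end-tags read the insert ends and fail all-or-nothing", {
    cfg <- smallCfg(seed = 23, nClones = 3, tagFailProb = 0)
    src <- generateSources(cfg@nSources, cfg@sourceLen, seed = 1)
    vec <- simulateVector(cfg@vectorLen, seed = 2)
    pool <- generateClonePool(src, vec, cfg)
    tags <- simulateEndTags(pool, vec, cfg)
    expect_length(tags, 6)
    expect_true(all(tagStatus(tags) == "ok"))
    ins <- as.character(inserts(pool)[[1]])
    expect_equal(as.character(tagSequences(tags)[["clone01_F"]]),
                 substr(ins, 1, cfg@tagLen))
    expect_equal(as.character(tagSequences(tags)[["clone01_R"]]),
                 revcomp(substr(ins, nchar(ins) - cfg@tagLen + 1,
                                nchar(ins))))

    cfg1 <- smallCfg(seed = 23, nClones = 3, tagFailProb = 1)
    tagsF <- simulateEndTags(pool, vec, cfg1)
    expect_true(all(tagStatus(tagsF) == "failed"))
    expect_true(all(Biostrings::width(tagSequences(tagsF)) == 0))
})

test_that("tag failures over many clones stay within the binomial band", {
    ## per-end failure probability p makes clones with zero usable tags
    ## Binomial(n, p^2); check a 99% interval at n = 92
    p <- 0.313
    cfg <- smallCfg(seed = 24, nClones = 92, insertLen = 2000,
                    tagFailProb = p,
                    nSources = 4L, sourceLen = 100000L)
    src <- generateSources(cfg@nSources, cfg@sourceLen, seed = 1)
    vec <- simulateVector(cfg@vectorLen, seed = 2)
    pool <- generateClonePool(src, vec, cfg)
    tags <- simulateEndTags(pool, vec, cfg)
    failedPerClone <- tapply(tagStatus(tags) == "failed", tagClone(tags), sum)
    zeroTagClones <- sum(failedPerClone == 2)
    band <- qbinom(c(0.005, 0.995), 92, p^2)
    expect_gte(zeroTagClones, band[1])
    expect_lte(zeroTagClones, band[2])
})

test_that("read simulation tracks truth, depth and the error model", {
    cfg <- smallCfg(seed = 25, nClones = 1, insertLen = 7000, depth = 50)
    src <- generateSources(cfg@nSources, cfg@sourceLen, seed = 1)
    vec <- simulateVector(cfg@vectorLen, seed = 2)
    pool <- generateClonePool(src, vec, cfg)
    reads <- simulateReads(pool, NULL, cfg, vector = vec)

    ## Poisson oracle: pair count within 3 sigma of depth * L / (2 * readLen)
    L <- Biostrings::width(cosmids(pool))[1]
    lambda <- cfg@depth * L / (2 * cfg@readLen)
    expect_lt(abs(length(reads) - lambda), 3 * sqrt(lambda))

    ## error-free mates are exact substrings of the circularized cosmid
    doubled <- paste0(as.character(cosmids(pool)[[1]]),
                      as.character(cosmids(pool)[[1]]))
    m <- c(as.character(mate1(reads)), as.character(mate2(reads)))
    hits <- pooltag:::.exactEitherStrand(m, doubled)
    expect_true(all(hits))

    ## truth labels: vector pairs have both mates vector-only or are
    ## sequence-identical to the backbone
    expect_setequal(unique(sub(":.*", "", truthOrigin(reads))),
                    c("clone", "vector"))

    ## depth 0 yields no reads
    cfg0 <- smallCfg(seed = 25, nClones = 1, depth = 0)
    expect_length(simulateReads(pool, NULL, cfg0, vector = vec), 0)
})

test_that("read simulation is deterministic and meets the target depth", {
    cfg <- smallCfg(seed = 26, nClones = 1, insertLen = 5000, depth = 100)
    src <- generateSources(cfg@nSources, cfg@sourceLen, seed = 1)
    vec <- simulateVector(cfg@vectorLen, seed = 2)
    pool <- generateClonePool(src, vec, cfg)
    r1 <- simulateReads(pool, NULL, cfg, vector = vec)
    r2 <- simulateReads(pool, NULL, cfg, vector = vec)
    expect_identical(as.character(mate1(r1)), as.character(mate1(r2)))
    expect_identical(truthOrigin(r1), truthOrigin(r2))

    ## realized depth over the cosmid (all pairs of this single clone,
    ## whatever their origin label) within 5% of target at depth >= 100
    realized <- length(r1) * 2 * cfg@readLen /
        Biostrings::width(cosmids(pool))[1]
    expect_lt(abs(realized - cfg@depth) / cfg@depth, 0.05)
})

test_that("host contamination adds the configured fraction of pairs", {
    cfg <- smallCfg(seed = 27, nClones = 1, insertLen = 5000, depth = 60,
                    contaminationFrac = 0.2)
    src <- generateSources(cfg@nSources, cfg@sourceLen, seed = 1)
    vec <- simulateVector(cfg@vectorLen, seed = 2)
    host <- generateSources(1, cfg@hostGenomeLen, seed = 3)
    pool <- generateClonePool(src, vec, cfg)
    reads <- simulateReads(pool, host, cfg, vector = vec)
    frac <- mean(truthOrigin(reads) == "host")
    expect_equal(frac, 0.2, tolerance = 0.02)
    expect_error(simulateReads(pool, NULL, cfg, vector = vec), "host")
})
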