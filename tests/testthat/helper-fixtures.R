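## random DNA and mutation helpers used across the suite

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## substitute exactly k positions, each to a different base
mutateBases <- function(s, k) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- sample(length(v), k)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
}

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## error-free reads tiling a linear sequence with full end coverage
tilingReads <- function(seq, readLen = 90, step = 5) {
    L <- nchar(seq)
    starts <- unique(c(seq(1, L - readLen + 1, by = step), L - readLen + 1))
    substring(seq, starts, starts + readLen - 1)
}

## a small pool configuration for fast end-to-end tests
smallCfg <- function(seed = 1, nClones = 4, insertLen = 6000, depth = 25,
                     errorRate = 0, contaminationFrac = 0, tagFailProb = 0,
                     ...) {
    args <- list(seed = seed, nClones = nClones,
                 insertLenMean = insertLen, insertLenSd = 1,
                 insertLenMin = insertLen - 10L,
                 insertLenMax = insertLen + 10L,
                 depth = depth, errorRate = errorRate,
                 contaminationFrac = contaminationFrac,
                 tagFailProb = tagFailProb, tagLen = 500L,
                 nSources = 2L, sourceLen = 100000L, vectorLen = 5000L,
                 hostGenomeLen = 50000L)
    args <- utils::modifyList(args, list(...))
    do.call(PoolConfig, args)
}
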