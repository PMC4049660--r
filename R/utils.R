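DNA_BASES4 <- c("A", "C", "G", "T")

## coerce DNAString / DNAStringSet / character to a plain character vector
.asSeqChar <- function(x) {
    if (is(x, "DNAString")) return(as.character(x))
    if (is(x, "XStringSet")) return(as.character(x))
    if (is.character(x)) return(toupper(x))
    stop("cannot interpret object of class '", class(x)[1], "' as DNA sequence")
}

.revcompChar <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}

## derived per-stage sub-seed so stages can be rerun independently
.stageSeed <- function(seed, offset) {
    (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

.randomDnaOne <- function(len) {
    paste(sample(DNA_BASES4, len, replace = TRUE), collapse = "")
}

## substitute bases at the given rate; each hit becomes a different base
.injectSubstitutions <- function(seqs, rate) {
    if (rate <= 0 || length(seqs) == 0) return(seqs)
    nch <- nchar(seqs)
    nerr <- rbinom(length(seqs), nch, rate)
    hit <- which(nerr > 0)
    for (i in hit) {
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(nch[i], nerr[i])
        for (p in pos) {
            s[p] <- sample(setdiff(DNA_BASES4, s[p]), 1)
        }
        seqs[i] <- paste(s, collapse = "")
    }
    seqs
}
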