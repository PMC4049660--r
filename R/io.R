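#' Read a FASTA file with line-level validation
#'
#' Thin reader that validates headers and sequence characters so malformed
#' input is reported with its line number, then returns the records as a
#' `DNAStringSet` (ids as names, any remaining header text in
#' `mcols()$description`). Lowercase is normalized to uppercase; multi-line
#' sequences are concatenated; the alphabet is restricted to A, C, G, T, N.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, empty for an empty file.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "AC", "GT"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    ids <- character()
    desc <- character()
    seqs <- character()
    cur <- NULL
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (grepl("^>", ln)) {
            header <- sub("^>", "", ln)
            id <- sub("\\s.*", "", header)
            if (!nzchar(id))
                stop("FASTA format error at line ", i, ": empty record id")
            ids <- c(ids, id)
            desc <- c(desc, trimws(sub("^\\S*\\s*", "", header)))
            seqs <- c(seqs, "")
            cur <- length(seqs)
        } else if (nzchar(trimws(ln))) {
            if (is.null(cur))
                stop("FASTA format error at line ", i,
                     ": sequence before any '>' header")
            s <- toupper(trimws(ln))
            if (grepl("[^ACGTN]", s))
                stop("FASTA format error at line ", i,
                     ": illegal character in sequence")
            seqs[cur] <- paste0(seqs[cur], s)
        }
    }
    out <- DNAStringSet(seqs)
    names(out) <- ids
    mcols(out)$description <- desc
    out
}

#' Write sequences to FASTA
#'
#' @param x a named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFasta <- function(x, path) {
    if (is.character(x)) x <- DNAStringSet(x)
    writeXStringSet(x, filepath = path, width = 70L)
    invisible(path)
}

#' Write paired reads as two synchronized FASTQ files
#'
#' Read ids are suffixed `"/1"` and `"/2"`. Qualities are a constant
#' placeholder (the downstream pipeline is quality-blind).
#'
#' @param pairs a [ReadPairSet-class].
#' @param path1,path2 output paths for mate 1 and mate 2.
#' @return invisibly, `c(path1, path2)`.
#' @export
writeFastqPairs <- function(pairs, path1, path2) {
    stopifnot(is(pairs, "ReadPairSet"))
    if (length(mate1(pairs)) != length(mate2(pairs)))
        stop("inconsistent pair set: unequal mate counts")
    m1 <- mate1(pairs)
    m2 <- mate2(pairs)
    ids <- names(m1)
    if (is.null(ids)) ids <- sprintf("read%07d", seq_along(m1))
    names(m1) <- if (length(ids)) paste0(ids, "/1") else character(0)
    names(m2) <- if (length(ids)) paste0(ids, "/2") else character(0)
    q1 <- BStringSet(strrep("I", width(m1)))
    q2 <- BStringSet(strrep("I", width(m2)))
    writeXStringSet(m1, filepath = path1, format = "fastq", qualities = q1)
    writeXStringSet(m2, filepath = path2, format = "fastq", qualities = q2)
    invisible(c(path1, path2))
}

#' Read two synchronized FASTQ files into a ReadPairSet
#'
#' Qualities are discarded; `"/1"`/`"/2"` suffixes are stripped; the two
#' files must list the same read ids in the same order.
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @return a [ReadPairSet-class] with `truthOrigin` set to `NA`.
#' @export
readFastqPairs <- function(path1, path2) {
    m1 <- readDNAStringSet(path1, format = "fastq")
    m2 <- readDNAStringSet(path2, format = "fastq")
    if (length(m1) != length(m2))
        stop("inconsistent FASTQ pair: unequal read counts")
    ids1 <- sub("/1$", "", sub("\\s.*", "", names(m1)))
    ids2 <- sub("/2$", "", sub("\\s.*", "", names(m2)))
    if (!identical(ids1, ids2))
        stop("inconsistent FASTQ pair: read ids differ between files")
    names(m1) <- ids1
    names(m2) <- ids2
    new("ReadPairSet", mate1 = m1, mate2 = m2,
        truthOrigin = rep(NA_character_, length(m1)))
}

#' Write a report table as TSV
#'
#' One header line, tab-separated, non-integer numeric columns rendered with
#' fixed 4-decimal precision so identical inputs produce byte-identical
#' files.
#'
#' @param df a data.frame; all columns must have equal length (enforced by
#'   the data.frame contract).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTable <- function(df, path) {
    stopifnot(is.data.frame(df))
    out <- df
    for (j in seq_along(out)) {
        if (is.double(out[[j]]))
            out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                               sprintf("%.4f", out[[j]]))
    }
    write.table(out, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    invisible(path)
}

## ---- flat key-value configuration files -----------------------------------

.configKeyMap <- c(
    seed = "seed", n_clones = "nClones",
    insert_len_mean = "insertLenMean", insert_len_sd = "insertLenSd",
    insert_len_min = "insertLenMin", insert_len_max = "insertLenMax",
    read_len = "readLen",
    fragment_len_mean = "fragmentLenMean", fragment_len_sd = "fragmentLenSd",
    depth = "depth", error_rate = "errorRate",
    tag_len = "tagLen", tag_fail_prob = "tagFailProb",
    contamination_frac = "contaminationFrac",
    k_assembly = "kAssembly", min_contig_len = "minContigLen",
    min_kmer_count = "minKmerCount",
    host_genome_len = "hostGenomeLen",
    n_sources = "nSources", source_len = "sourceLen",
    vector_len = "vectorLen",
    barcoded_depth_factor = "barcodedDepthFactor", k_barcoded = "kBarcoded")

#' Read a pool configuration file
#'
#' Flat YAML key-value file with snake_case keys mirroring the
#' [PoolConfig-class] fields (`n_clones`, `insert_len_mean`, ...), plus
#' optional `overlap_groups` (list of `{size, overlap}`) and
#' `similarity_pairs` (list of `{clone1, clone2, length, identity}`).
#' Unknown keys are a validation error.
#'
#' @param path path to the config file.
#' @return a validated [PoolConfig-class].
#' @export
readPoolConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- c(names(.configKeyMap), "overlap_groups", "similarity_pairs")
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("invalid config keys: ", paste(bad, collapse = ", "))
    args <- list()
    for (key in intersect(names(vals), names(.configKeyMap)))
        args[[.configKeyMap[[key]]]] <- vals[[key]]
    if (!is.null(vals$overlap_groups))
        args$overlapGroups <- vals$overlap_groups
    if (!is.null(vals$similarity_pairs))
        args$similarityPairs <- vals$similarity_pairs
    do.call(PoolConfig, args)
}

#' Write a pool configuration file
#'
#' @param cfg a [PoolConfig-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePoolConfig <- function(cfg, path) {
    stopifnot(is(cfg, "PoolConfig"))
    vals <- list()
    for (key in names(.configKeyMap)) {
        v <- slot(cfg, .configKeyMap[[key]])
        vals[[key]] <- if (is.na(v)) NULL else unname(v)
    }
    vals$overlap_groups <- cfg@overlapGroups
    vals$similarity_pairs <- cfg@similarityPairs
    yaml::write_yaml(vals, path)
    invisible(path)
}
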