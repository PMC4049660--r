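.logStage <- function(stage, ...) {
    kv <- c(...)
    message(stage, " ", paste(names(kv), unname(kv), sep = "=",
                              collapse = " "))
}

#' Run the full pooled-sequencing pipeline
#'
#' Simulate -> screen vector reads -> estimate contamination -> assemble ->
#' retrieve by end-tags -> classify -> evaluate, writing every stage output
#' (FASTA/FASTQ/TSV) plus a JSON run manifest under one directory.
#' Regenerating with the same configuration and seed reproduces
#' byte-identical stage outputs.
#'
#' @param cfg a [PoolConfig-class] (or path to a config file readable by
#'   [readPoolConfig()]).
#' @param outDir output directory (created if missing); `NULL` runs
#'   in-memory only.
#' @param refs optional named `DNAStringSet` of per-clone references used
#'   for evaluation; defaults to the simulator's true insert sequences.
#' @return invisibly, the run manifest: a list with the config echo, seed,
#'   per-stage summary statistics, the evaluation tables, and output paths.
#' @export
runAll <- function(cfg, outDir = NULL, refs = NULL) {
    if (is.character(cfg)) cfg <- readPoolConfig(cfg)
    stopifnot(is(cfg, "PoolConfig"))
    paths <- list()
    emit <- function(name, writer) {
        if (!is.null(outDir)) {
            p <- file.path(outDir, name)
            writer(p)
            paths[[name]] <<- p
        }
    }
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)

    ## --- simulate ----------------------------------------------------------
    sources <- generateSources(cfg@nSources, cfg@sourceLen,
                               seed = .stageSeed(cfg@seed, 1L))
    backbone <- simulateVector(cfg@vectorLen, seed = .stageSeed(cfg@seed, 2L))
    host <- generateSources(1L, cfg@hostGenomeLen,
                            seed = .stageSeed(cfg@seed, 6L))
    names(host) <- "host"
    clones <- generateClonePool(sources, backbone, cfg)
    tags <- simulateEndTags(clones, backbone, cfg)
    reads <- simulateReads(clones, host, cfg, vector = backbone)
    .logStage("simulate", c(clones = length(inserts(clones)),
                            pairs = length(reads),
                            okTags = sum(tagStatus(tags) == "ok")))
    emit("vector.fasta", function(p)
        writeFasta(setNames(DNAStringSet(as.character(backboneSeq(backbone))),
                            "vector"), p))
    emit("host.fasta", function(p) writeFasta(host, p))
    emit("clones.fasta", function(p) writeFasta(inserts(clones), p))
    emit("cosmids.fasta", function(p) writeFasta(cosmids(clones), p))
    emit("endtags.fasta", function(p)
        writeFasta(tagSequences(tags)[tagStatus(tags) == "ok"], p))
    emit("reads_1.fastq", function(p) p) # reserved below
    emit("reads_2.fastq", function(p) p)
    if (!is.null(outDir))
        writeFastqPairs(reads, paths[["reads_1.fastq"]],
                        paths[["reads_2.fastq"]])
    emit("truth.tsv", function(p)
        writeTable(data.frame(readId = names(mate1(reads)),
                              origin = truthOrigin(reads)), p))

    ## --- subtract ----------------------------------------------------------
    scr <- screenVector(reads, backbone, host = host)
    hostFraction <- scr$report@hostFraction
    .logStage("subtract", c(total = scr$report@totalPairs,
                            vector = scr$report@vectorPairs,
                            hostFraction = signif(hostFraction, 4)))
    emit("screen_report.tsv", function(p)
        writeTable(data.frame(totalPairs = scr$report@totalPairs,
                              vectorPairs = scr$report@vectorPairs,
                              hostPairs = scr$report@hostPairs,
                              keptPairs = scr$report@keptPairs,
                              hostFraction = hostFraction), p))

    ## --- assemble ----------------------------------------------------------
    contigs <- assemblePool(scr$kept, cfg, vector = backbone)
    stats <- assemblyStats(contigs)
    .logStage("assemble", c(contigs = stats$nContigs,
                            meanLen = round(stats$meanLen)))
    emit("contigs.fasta", function(p) writeFasta(contigs, p))
    emit("assembly_stats.tsv", function(p) writeTable(stats, p))

    ## --- retrieve ----------------------------------------------------------
    classification <- classifyClones(tags, contigs)
    typeCounts <- table(factor(classification$types$cloneType,
                               levels = c("A", "B", "C", "D",
                                          "unretrieved", "excluded")))
    .logStage("retrieve", setNames(as.integer(typeCounts),
                                   names(typeCounts)))
    emit("hit_table.tsv", function(p) writeTable(classification$hits, p))
    emit("clone_types.tsv", function(p) writeTable(classification$types, p))

    ## --- evaluate ----------------------------------------------------------
    if (is.null(refs)) refs <- inserts(clones)
    report <- coverageReport(refs, contigs, classification)
    simMat <- pairwiseSimilarity(refs)
    depths <- lapply(names(refs), function(id)
        depthProfile(scr$kept, refs[[id]], seedLen = cfg@kAssembly))
    names(depths) <- names(refs)
    meanDepths <- vapply(depths, function(d) d$meanDepth, numeric(1))
    .logStage("evaluate",
              c(meanRetrieved = round(mean(report$retrievedCoverage), 2),
                meanActual = round(mean(report$actualCoverage), 2)))
    emit("coverage_report.tsv", function(p) writeTable(report, p))
    emit("similarity.tsv", function(p)
        writeTable(data.frame(cloneId = rownames(simMat),
                              as.data.frame(simMat)), p))
    emit("depth_mean.tsv", function(p)
        writeTable(data.frame(cloneId = names(meanDepths),
                              meanDepth = unname(meanDepths)), p))
    emit("coverage_hist_retrieved.tsv", function(p)
        writeTable(binCoverage(report$retrievedCoverage), p))
    emit("coverage_hist_actual.tsv", function(p)
        writeTable(binCoverage(report$actualCoverage), p))

    cfgEcho <- setNames(
        lapply(names(.configKeyMap),
               function(k) unname(slot(cfg, .configKeyMap[[k]]))),
        names(.configKeyMap))
    manifest <- list(
        config = cfgEcho,
        seed = cfg@seed,
        summary = list(
            nClones = length(inserts(clones)),
            nPairs = length(reads),
            nVectorPairs = scr$report@vectorPairs,
            hostFraction = hostFraction,
            nContigs = stats$nContigs,
            meanContigLen = stats$meanLen,
            typeCounts = as.list(setNames(as.integer(typeCounts),
                                          names(typeCounts))),
            meanRetrievedCoverage = mean(report$retrievedCoverage),
            meanActualCoverage = mean(report$actualCoverage),
            meanIdentity = mean(report$identity, na.rm = TRUE)),
        coverage = report,
        types = classification$types,
        hits = classification$hits,
        similarity = simMat,
        meanDepths = meanDepths,
        depths = depths,
        contigs = contigs,
        clones = clones,
        tags = tags,
        reads = reads,
        screen = scr$report,
        paths = paths)
    if (!is.null(outDir)) {
        mf <- manifest[c("seed", "summary")]
        mf$config <- manifest$config
        mf$paths <- lapply(paths, basename)
        jsonlite::write_json(mf, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(manifest)
}

#' Run the barcoded (reference) arm
#'
#' Simulates and assembles each clone separately at
#' `barcodedDepthFactor` times the pooled depth with the barcoded-arm
#' k-mer size, after vector screening — the per-clone analogue of
#' individually indexed sequencing. Clones whose assembly yields several
#' contigs above the length floor are concatenated (largest first) into one
#' reference, mirroring how fragmented reference assemblies are handled.
#'
#' @param cfg a [PoolConfig-class].
#' @param clones optionally a pre-built [ClonePool-class] (so the barcoded
#'   arm references the same clones as a pooled run under the same seed);
#'   built from `cfg` when `NULL`.
#' @param outDir optional output directory for per-clone reference FASTA.
#' @return a named `DNAStringSet`, one reference per clone (zero-width when
#'   a clone failed to assemble).
#' @export
runBarcodedArm <- function(cfg, clones = NULL, outDir = NULL) {
    stopifnot(is(cfg, "PoolConfig"))
    if (is.null(clones)) {
        sources <- generateSources(cfg@nSources, cfg@sourceLen,
                                   seed = .stageSeed(cfg@seed, 1L))
        backbone <- simulateVector(cfg@vectorLen,
                                   seed = .stageSeed(cfg@seed, 2L))
        clones <- generateClonePool(sources, backbone, cfg)
    } else {
        backbone <- simulateVector(cfg@vectorLen,
                                   seed = .stageSeed(cfg@seed, 2L))
    }
    n <- length(inserts(clones))
    refs <- character(n)
    for (i in seq_len(n)) {
        sub <- new("ClonePool",
                   inserts = inserts(clones)[i], cosmids = cosmids(clones)[i],
                   info = cloneInfo(clones)[i, , drop = FALSE],
                   similarity = similarityInfo(clones)[0, , drop = FALSE])
        cfgClone <- cfg
        cfgClone@seed <- .stageSeed(cfg@seed, 1000L + i)
        cfgClone@depth <- cfg@depth * cfg@barcodedDepthFactor
        cfgClone@contaminationFrac <- 0
        cfgClone@kAssembly <- cfg@kBarcoded
        reads <- simulateReads(sub, NULL, cfgClone, vector = backbone)
        scr <- screenVector(reads, backbone)
        contigs <- assemblePool(scr$kept, cfgClone, vector = backbone)
        refs[i] <- paste(as.character(contigs), collapse = "")
        .logStage("barcoded", c(clone = names(inserts(clones))[i],
                                contigs = length(contigs)))
    }
    out <- DNAStringSet(refs)
    names(out) <- names(inserts(clones))
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        writeFasta(out[width(out) > 0], file.path(outDir, "barcoded_refs.fasta"))
    }
    out
}
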