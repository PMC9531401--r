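#' @include AllClasses.R graph.R kmerIndex.R countModel.R helperVariants.R
NULL

# subset a panel to a set of variant columns (e.g. after the graph drops
# overlapping variants)
.subsetPanel <- function(panel, cols) {
    GenotypePanel(haplotypeMatrix(panel)[, cols, drop = FALSE],
        phased = panel@phased)
}

#' Build the complete genotyping index for a reference population
#'
#' Runs the whole indexing stage: graph construction, window enumeration,
#' population k-mer frequency modelling, minimum-maximum-frequency k-mer
#' selection, k-mer index construction, duplicate-count histograms and
#' helper-variant tables. Built once per (reference, panel); genotyping a
#' new sample then only needs \code{\link{countReads}} +
#' \code{\link{genotypeSample}}.
#'
#' @param reference named character vector of contig sequences.
#' @param variants variant data.frame (\code{contig}, \code{pos},
#'   \code{ref}, \code{alt}, optional \code{af}).
#' @param panel a \linkS4class{GenotypePanel} with one column per variant
#'   row.
#' @param k k-mer length, default 31 (odd, at most 31).
#' @param lambda0 expected read k-mer count per genome copy; computed from
#'   \code{coverage} and \code{readLength} when NULL.
#' @param coverage,readLength used to derive \code{lambda0} via
#'   \code{\link{estimateLambda0}} when \code{lambda0} is NULL.
#' @param epsilon error-term rate, default 0.01.
#' @param dMax duplicate-count overflow bin, default 15.
#' @param helperWindow helper candidates per side, default 100.
#' @param verbose log a one-line summary to stderr.
#' @return A \linkS4class{GenotypeIndex}.
#' @export
buildGenotypeIndex <- function(reference, variants, panel, k = 31L,
                               lambda0 = NULL, coverage = 15,
                               readLength = 150L, epsilon = 0.01,
                               dMax = 15L, helperWindow = 100L,
                               verbose = FALSE) {
    k <- as.integer(k)
    if (k < 3L || k > 31L) stop("k must be in 3..31")
    if (k %% 2L == 0L) stop("k must be odd")
    if (is.null(lambda0))
        lambda0 <- estimateLambda0(coverage, readLength, k)
    graph <- buildVariantGraph(reference, variants)
    v <- graph@variants
    kept <- attr(v, "kept")
    if (length(kept) != nVariants(panel))
        panel <- .subsetPanel(panel, kept)

    altWinExt <- lapply(seq_len(nrow(v)), function(j)
        enumerateAlleleWindows(graph, v$variant[j], "alt", k,
            offsets = .catalogOffsets(k, nchar(v$alt[j]))))
    freqModel <- buildFrequencyModel(graph, panel, k,
        altWindows = altWinExt)

    selRows <- vector("list", nrow(v))
    for (j in seq_len(nrow(v))) {
        winRef <- enumerateAlleleWindows(graph, v$variant[j], "ref", k)
        offA <- vapply(altWinExt[[j]], `[[`, 0L, "offset")
        winAlt <- altWinExt[[j]][offA <= 0L]
        sel <- selectVariantKmers(winRef, winAlt, freqModel, k)
        if (is.null(sel))
            sel <- list(offset = NA_integer_, refKmers = character(0),
                altKmers = character(0), score = NA_real_,
                lowConfidence = TRUE)
        selRows[[j]] <- sel
    }
    selected <- data.frame(
        variant = v$variant,
        offset = vapply(selRows, `[[`, 0L, "offset"),
        score = vapply(selRows, `[[`, 0, "score"),
        lowConfidence = vapply(selRows, `[[`, TRUE, "lowConfidence")
    )
    selected$refKmers <- lapply(selRows, `[[`, "refKmers")
    selected$altKmers <- lapply(selRows, `[[`, "altKmers")

    kmerIndex <- buildKmerIndex(selected, graph, k)
    countModel <- buildCountModel(freqModel, panel, selected, lambda0,
        epsilon = epsilon, dMax = dMax)
    helperTable <- buildHelperTable(panel, v, window = helperWindow)
    if (verbose)
        message(sprintf(
            "indexed %d variants (%d low-confidence), mean kmer score %.2f",
            nrow(v), sum(selected$lowConfidence),
            mean(selected$score, na.rm = TRUE)))
    new("GenotypeIndex", version = .ARCHIVE_VERSION, k = k, graph = graph,
        kmerIndex = kmerIndex, selected = selected,
        countModel = countModel, helperTable = helperTable)
}

#' Save / load a genotyping index archive
#'
#' Single-file serialized archive with an explicit format-version tag;
#' loading verifies the tag so stale archives fail loudly rather than
#' silently drifting.
#'
#' @param archive a \linkS4class{GenotypeIndex}.
#' @param path archive file path.
#' @return \code{saveGenotypeIndex}: the path, invisibly;
#'   \code{loadGenotypeIndex}: the \linkS4class{GenotypeIndex}.
#' @export
saveGenotypeIndex <- function(archive, path) {
    stopifnot(is(archive, "GenotypeIndex"))
    saveRDS(archive, path)
    invisible(path)
}

#' @rdname saveGenotypeIndex
#' @export
loadGenotypeIndex <- function(path) {
    archive <- readRDS(path)
    if (!is(archive, "GenotypeIndex"))
        stop("not a genotyping index archive: ", path)
    if (!identical(archive@version, .ARCHIVE_VERSION))
        stop("archive version '", archive@version,
            "' does not match this package's format '", .ARCHIVE_VERSION,
            "'")
    archive
}
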