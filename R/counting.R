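#' @include AllClasses.R kmerIndex.R io.R
NULL

#' Count read k-mer support per graph allele node
#'
#' Streams the reads, canonicalizes every k-length window (windows
#' containing non-ACGT bases are skipped), looks the k-mer up in the index
#' and increments every allele node it maps to, once per occurrence. The
#' result is deterministic and independent of read order, so any
#' partitioning of the read set sums to the same counts.
#'
#' @param reads character vector of read sequences, or path(s) to
#'   FASTA/FASTQ(.gz) files.
#' @param index a \linkS4class{KmerIndex}.
#' @return A \linkS4class{NodeCounts}.
#' @export
countReads <- function(reads, index) {
    if (length(reads) && all(file.exists(reads)))
        reads <- unlist(lapply(reads, readReads), use.names = FALSE)
    kms <- ls(index@lookup)
    if (length(kms)) {
        nodeLists <- mget(kms, envir = index@lookup)
        nodeIds <- as.integer(unlist(nodeLists, use.names = FALSE))
        nodeStarts <- c(0L, cumsum(lengths(nodeLists)))
    } else {
        nodeIds <- integer(0)
        nodeStarts <- 0L
    }
    res <- .cppCountReads(as.character(reads), kms, nodeIds, nodeStarts,
        index@k, index@nNodes)
    new("NodeCounts", counts = res$counts, totalReads = res$totalReads,
        totalKmers = res$totalKmers)
}

#' Combine node counts from separately counted read batches
#'
#' @param ... \linkS4class{NodeCounts} objects over the same index.
#' @return their element-wise sum as a \linkS4class{NodeCounts}.
#' @export
combineNodeCounts <- function(...) {
    xs <- list(...)
    stopifnot(length(xs) >= 1L)
    counts <- Reduce(`+`, lapply(xs, nodeCounts))
    new("NodeCounts", counts = counts,
        totalReads = sum(vapply(xs, slot, 0, "totalReads")),
        totalKmers = sum(vapply(xs, slot, 0, "totalKmers")))
}

#' Observed k-mer counts on a variant's two alleles
#'
#' @param counts a \linkS4class{NodeCounts}.
#' @param graph the \linkS4class{VariantGraph} the index was built over.
#' @param variantId a variant id, or NULL for all variants.
#' @return for one variant, \code{c(ref = K_ref, alt = K_alt)}; for all,
#'   a variants x 2 matrix.
#' @export
variantCounts <- function(counts, graph, variantId = NULL) {
    vn <- graph@variantNodes
    cnt <- nodeCounts(counts)
    if (is.null(variantId)) {
        m <- cbind(ref = cnt[vn$refNode], alt = cnt[vn$altNode])
        rownames(m) <- vn$variant
        return(m)
    }
    row <- match(variantId, vn$variant)
    if (is.na(row)) stop("unknown variant id: ", variantId)
    c(ref = cnt[vn$refNode[row]], alt = cnt[vn$altNode[row]])
}

#' Write / read a node-count dump
#'
#' Tab-separated \code{node_id <TAB> count} files, the intermediate of the
#' two-stage count-then-genotype command-line path.
#'
#' @param counts a \linkS4class{NodeCounts}.
#' @param path output (input) path.
#' @return \code{writeNodeCounts}: the path, invisibly;
#'   \code{readNodeCounts}: a \linkS4class{NodeCounts}.
#' @export
writeNodeCounts <- function(counts, path) {
    df <- data.frame(node_id = seq_along(counts@counts),
        count = counts@counts)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' @rdname writeNodeCounts
#' @export
readNodeCounts <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    new("NodeCounts", counts = as.numeric(df$count),
        totalReads = NA_real_, totalKmers = NA_real_)
}
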