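#' @include AllClasses.R
NULL

#' Accessors for kmertyper containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{kmerLength} returns the k-mer length an object was built with,
#' \code{variantTable} the variant metadata data.frame, \code{nVariants}
#' and \code{nIndividuals} the obvious sizes, \code{genotypeMatrix} and
#' \code{haplotypeMatrix} the panel matrices, and \code{nodeCounts} the
#' per-node count vector of a \linkS4class{NodeCounts} object.
#'
#' @param x one of the package's S4 containers.
#' @return See the individual descriptions above.
#' @examples
#' panel <- GenotypePanel(haplotypes = matrix(c(0L, 1L, 1L, 1L), 2, 2))
#' nIndividuals(panel)
#' genotypeMatrix(panel)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname accessors
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname accessors
#' @export
setGeneric("haplotypeMatrix", function(x) standardGeneric("haplotypeMatrix"))

#' @rdname accessors
#' @export
setGeneric("nodeCounts", function(x) standardGeneric("nodeCounts"))

#' @rdname accessors
#' @export
setMethod("kmerLength", "KmerIndex", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("kmerLength", "KmerFrequencyModel", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("kmerLength", "GenotypeIndex", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("variantTable", "VariantGraph", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("variantTable", "GenotypeIndex", function(x) x@graph@variants)

#' @rdname accessors
#' @export
setMethod("nVariants", "VariantGraph", function(x) nrow(x@variants))

#' @rdname accessors
#' @export
setMethod("nVariants", "GenotypePanel", function(x) ncol(x@genotypes))

#' @rdname accessors
#' @export
setMethod("nVariants", "GenotypeIndex", function(x) nrow(x@graph@variants))

#' @rdname accessors
#' @export
setMethod("nIndividuals", "GenotypePanel", function(x) nrow(x@genotypes))

#' @rdname accessors
#' @export
setMethod("genotypeMatrix", "GenotypePanel", function(x) x@genotypes)

#' @rdname accessors
#' @export
setMethod("haplotypeMatrix", "GenotypePanel", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setMethod("nodeCounts", "NodeCounts", function(x) x@counts)

#' Construct a GenotypePanel from a phased haplotype matrix
#'
#' @param haplotypes integer matrix of 0/1 alleles with two consecutive
#'   rows per individual (haplotype 1 then haplotype 2) and one column per
#'   variant.
#' @param phased logical, whether the haplotype split is meaningful.
#' @return A \linkS4class{GenotypePanel}.
#' @examples
#' GenotypePanel(matrix(c(0L, 1L, 1L, 1L), nrow = 2))
#' @export
GenotypePanel <- function(haplotypes, phased = TRUE) {
    storage.mode(haplotypes) <- "integer"
    if (nrow(haplotypes) %% 2L != 0L)
        stop("haplotype matrix needs an even number of rows")
    g <- haplotypes[seq(1, nrow(haplotypes), by = 2), , drop = FALSE] +
        haplotypes[seq(2, nrow(haplotypes), by = 2), , drop = FALSE]
    new("GenotypePanel", genotypes = g, haplotypes = haplotypes,
        phased = phased)
}

setMethod("show", "VariantGraph", function(object) {
    cat(sprintf(
        "VariantGraph: %d contig(s), %d variant(s), %d nodes, %d edges\n",
        length(object@contigs), nrow(object@variants),
        nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "GenotypePanel", function(object) {
    cat(sprintf("GenotypePanel: %d individuals x %d variants (%s)\n",
        nrow(object@genotypes), ncol(object@genotypes),
        if (object@phased) "phased" else "unphased"))
})

setMethod("show", "KmerIndex", function(object) {
    cat(sprintf("KmerIndex: k = %d, %d canonical kmers over %d nodes\n",
        object@k, length(ls(object@lookup)), object@nNodes))
})

setMethod("show", "KmerFrequencyModel", function(object) {
    cat(sprintf(
        "KmerFrequencyModel: k = %d, %d graph kmers, panel n = %d\n",
        object@k, length(ls(object@freq)), object@nIndividuals))
})

setMethod("show", "CountModel", function(object) {
    cat(sprintf(
        "CountModel: %d variants, lambda0 = %.3f, epsilon = %.3g, dMax = %d\n",
        dim(object@histRef)[1], object@lambda0, object@epsilon, object@dMax))
})

setMethod("show", "HelperTable", function(object) {
    cat(sprintf("HelperTable: %d variants, %d with a helper\n",
        length(object@helper), sum(!is.na(object@helper))))
})

setMethod("show", "NodeCounts", function(object) {
    cat(sprintf(
        "NodeCounts: %d nodes, %.0f reads, %.0f kmers scanned, %.0f hits\n",
        length(object@counts), object@totalReads, object@totalKmers,
        sum(object@counts)))
})

setMethod("show", "GenotypeIndex", function(object) {
    cat(sprintf("GenotypeIndex (%s): k = %d, %d variants\n",
        object@version, object@k, nrow(object@graph@variants)))
})
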