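# Central S4 data containers. Genotypes are coded 0 = hom-ref (0/0),
# 1 = het (0/1, unordered), 2 = hom-alt (1/1) throughout.

.GT_LABELS <- c("0/0", "0/1", "1/1")

#' VariantGraph: acyclic pangenome graph over reference and variant alleles
#'
#' One reference-segment node chain per contig, interrupted at every
#' biallelic variant by a pair of allele nodes (reference allele and
#' alternative allele) that share predecessors and successors. Deletion
#' alleles are empty-sequence nodes, so alternative paths skip the deleted
#' bases. Node ids increase along the genome, which makes acyclicity a
#' construction invariant.
#'
#' @slot nodes data.frame with columns \code{node} (integer id),
#'   \code{contig}, \code{seq} (possibly empty string) and \code{role}
#'   (\code{"reference-segment"}, \code{"ref-allele"} or \code{"alt-allele"}).
#' @slot edges data.frame with integer columns \code{from}, \code{to}.
#' @slot variantNodes data.frame with columns \code{variant},
#'   \code{refNode}, \code{altNode}.
#' @slot refPath named list (per contig) of node ids whose concatenated
#'   sequences spell the contig.
#' @slot variants data.frame with columns \code{variant} (integer id),
#'   \code{contig}, \code{pos} (0-based, first affected base), \code{ref},
#'   \code{alt} (left-trimmed alleles; at most one may be empty) and
#'   \code{af} (population alternative-allele frequency).
#' @slot contigs named character vector of uppercase contig sequences.
#'
#' @exportClass VariantGraph
setClass("VariantGraph",
    representation(
        nodes = "data.frame",
        edges = "data.frame",
        variantNodes = "data.frame",
        refPath = "list",
        variants = "data.frame",
        contigs = "character"
    )
)

setValidity("VariantGraph", function(object) {
    msg <- character()
    if (is.null(names(object@contigs)) || anyDuplicated(names(object@contigs)))
        msg <- c(msg, "contig names must be unique and non-empty")
    if (nrow(object@edges) && !all(object@edges$from < object@edges$to))
        msg <- c(msg, "edges must point forward (acyclicity)")
    for (ct in names(object@contigs)) {
        path <- object@refPath[[ct]]
        spelled <- paste(object@nodes$seq[match(path, object@nodes$node)],
            collapse = "")
        if (!identical(spelled, unname(object@contigs[[ct]])))
            msg <- c(msg, sprintf(
                "reference path of contig '%s' does not spell the contig", ct))
    }
    if (nrow(object@variantNodes) != nrow(object@variants))
        msg <- c(msg, "one (ref, alt) node pair required per variant")
    if (length(msg)) msg else TRUE
})

#' GenotypePanel: genotypes (and phased haplotypes) of a reference panel
#'
#' @slot genotypes integer matrix, individuals x variants, coded 0/1/2.
#' @slot haplotypes integer matrix, 2 x individuals rows (haplotype 1 of
#'   individual 1, haplotype 2 of individual 1, ...), variants as columns,
#'   coded 0 (ref) / 1 (alt). When the input was unphased the haplotype
#'   split of heterozygotes is arbitrary.
#' @slot phased logical, TRUE when all input genotypes were phased.
#'
#' @exportClass GenotypePanel
setClass("GenotypePanel",
    representation(
        genotypes = "matrix",
        haplotypes = "matrix",
        phased = "logical"
    )
)

setValidity("GenotypePanel", function(object) {
    msg <- character()
    if (!all(object@genotypes %in% 0:2))
        msg <- c(msg, "genotypes must be coded 0, 1, 2")
    if (nrow(object@haplotypes) != 2L * nrow(object@genotypes))
        msg <- c(msg, "need exactly two haplotype rows per individual")
    if (!all(object@haplotypes %in% 0:1))
        msg <- c(msg, "haplotype alleles must be 0 or 1")
    gsum <- object@haplotypes[seq(1, nrow(object@haplotypes), by = 2), ,
        drop = FALSE] +
        object@haplotypes[seq(2, nrow(object@haplotypes), by = 2), ,
            drop = FALSE]
    if (!identical(unname(gsum), unname(object@genotypes)))
        msg <- c(msg, "haplotypes must sum to the genotype dosage")
    if (length(msg)) msg else TRUE
})

#' KmerFrequencyModel: expected diploid copies of every graph-window k-mer
#'
#' Maps canonical k-mers to the expected number of copies in a random panel
#' individual's diploid genome. Built from the graph windows only: all
#' reference windows plus every alternative-path window, each weighted by
#' the mean number of panel haplotypes per individual consistent with the
#' window's local allele combination. Also carries the occurrence catalogue
#' used to compute per-individual duplicate counts.
#'
#' @slot k integer k-mer length.
#' @slot freq environment mapping canonical k-mer to frequency.
#' @slot occVar environment mapping canonical k-mer to a list of
#'   alternative-path occurrences, each a list with integer vectors
#'   \code{vars} and \code{alleles} (0 = ref, 1 = alt constraints).
#' @slot refCanon list per contig of canonical reference-window k-mers
#'   (index = window start + 1; NA where the window contains a non-ACGT
#'   base).
#' @slot refStarts list per contig: environment mapping a canonical k-mer
#'   to the 0-based reference window starts where it occurs.
#' @slot refOverlap list per contig: list with \code{starts} (0-based
#'   window starts that intersect at least one variant) and \code{sets}
#'   (list of integer vectors of the intersected variant ids).
#' @slot nIndividuals integer panel size used for normalisation.
#'
#' @exportClass KmerFrequencyModel
setClass("KmerFrequencyModel",
    representation(
        k = "integer",
        freq = "environment",
        occVar = "environment",
        refCanon = "list",
        refStarts = "list",
        refOverlap = "list",
        nIndividuals = "integer"
    )
)

#' KmerIndex: lookup from canonical k-mer to graph allele nodes
#'
#' @slot k integer k-mer length.
#' @slot lookup environment mapping canonical k-mer string to an integer
#'   vector of allele-node ids.
#' @slot nNodes integer, total number of graph nodes (for count vectors).
#'
#' @exportClass KmerIndex
setClass("KmerIndex",
    representation(k = "integer", lookup = "environment", nNodes = "integer")
)

#' CountModel: per-genotype histograms of k-mer duplicate counts
#'
#' For every variant, allele and genotype class the histogram over panel
#' individuals of d, the total number of times the allele's selected k-mers
#' occur in that individual's diploid genome (own-site copies plus
#' duplicate copies elsewhere). Together with the read-depth rate lambda0
#' and the error rate epsilon this defines the mixture-of-Poissons
#' likelihood of an observed allele k-mer count.
#'
#' @slot lambda0 expected read k-mer count per single genome copy.
#' @slot epsilon error-term rate added to every duplicate count.
#' @slot dMax largest stored duplicate count; larger values clamp here.
#' @slot histRef,histAlt numeric arrays variants x 3 genotypes x
#'   (dMax + 1) duplicate-count bins; each (variant, genotype) slice sums
#'   to the number of panel individuals in that class (after
#'   pseudo-individual fill of empty classes).
#'
#' @exportClass CountModel
setClass("CountModel",
    representation(
        lambda0 = "numeric",
        epsilon = "numeric",
        dMax = "integer",
        histRef = "array",
        histAlt = "array"
    )
)

setValidity("CountModel", function(object) {
    msg <- character()
    if (object@lambda0 <= 0) msg <- c(msg, "lambda0 must be > 0")
    if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
    if (any(object@histRef < 0) || any(object@histAlt < 0))
        msg <- c(msg, "histogram counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' HelperTable: helper-variant choice and panel prior tables per variant
#'
#' @slot helper integer vector: for each variant the id of its helper
#'   variant (NA when no helper exists, e.g. a single-variant contig).
#' @slot pi numeric array variants x 3 x 3 of smoothed joint genotype
#'   frequencies pi(G_i, G_h); rows index the variant's own genotype,
#'   columns the helper genotype. All-NA slice when helper is NA.
#' @slot popPrior numeric matrix variants x 3 of smoothed marginal
#'   genotype frequencies, used when no helper is available and in
#'   likelihoods-only mode.
#'
#' @exportClass HelperTable
setClass("HelperTable",
    representation(helper = "integer", pi = "array", popPrior = "matrix")
)

#' NodeCounts: observed k-mer support per graph allele node
#'
#' @slot counts numeric vector indexed by node id.
#' @slot totalReads number of reads processed.
#' @slot totalKmers number of valid k-mer windows scanned.
#'
#' @exportClass NodeCounts
setClass("NodeCounts",
    representation(
        counts = "numeric",
        totalReads = "numeric",
        totalKmers = "numeric"
    )
)

#' GenotypeIndex: the combined, serialisable genotyping index
#'
#' Self-describing archive of everything needed to genotype new samples
#' against a fixed reference population: graph, k-mer index, selected
#' k-mers, count model and helper table. Built once by
#' \code{\link{buildGenotypeIndex}}; save/load with
#' \code{\link{saveGenotypeIndex}} / \code{\link{loadGenotypeIndex}}.
#'
#' @slot version archive format version string.
#' @slot k integer k-mer length the index was built with.
#' @slot graph \linkS4class{VariantGraph}.
#' @slot kmerIndex \linkS4class{KmerIndex}.
#' @slot selected data.frame of selected k-mers per variant (columns
#'   \code{variant}, \code{offset}, \code{score}, \code{lowConfidence} and
#'   list columns \code{refKmers}, \code{altKmers}).
#' @slot countModel \linkS4class{CountModel}.
#' @slot helperTable \linkS4class{HelperTable}.
#'
#' @exportClass GenotypeIndex
setClass("GenotypeIndex",
    representation(
        version = "character",
        k = "integer",
        graph = "VariantGraph",
        kmerIndex = "KmerIndex",
        selected = "data.frame",
        countModel = "CountModel",
        helperTable = "HelperTable"
    )
)

.ARCHIVE_VERSION <- "kmertyper-index-1"
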