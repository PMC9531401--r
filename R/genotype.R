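#' @include AllClasses.R countModel.R helperVariants.R counting.R
NULL

# log-likelihood matrix (variants x 3 genotypes) for observed counts
.logLikMatrix <- function(K, countModel) {
    nv <- nrow(K)
    out <- matrix(0, nv, 3L)
    for (r in seq_len(nv)) {
        for (g in 0:2) {
            out[r, g + 1L] <-
                .alleleLogLik(K[r, 1L], countModel@histRef[r, g + 1L, ],
                    countModel@lambda0, countModel@epsilon) +
                .alleleLogLik(K[r, 2L], countModel@histAlt[r, g + 1L, ],
                    countModel@lambda0, countModel@epsilon)
        }
    }
    out
}

#' Genotype likelihoods from observed allele k-mer counts
#'
#' \code{L(g) = P(K_ref | g) * P(K_alt | g)}: the two allele counts are
#' modelled as conditionally independent given the genotype, each under
#' its mixture-of-Poissons model (\code{\link{alleleLikelihood}}).
#'
#' @param kRef,kAlt observed k-mer counts on the two alleles.
#' @param countModel a \linkS4class{CountModel}.
#' @param variant variant row index into the model.
#' @param log return log likelihoods.
#' @return 3-vector of (possibly log) likelihoods for genotypes 0/0, 0/1,
#'   1/1.
#' @export
genotypeLikelihood <- function(kRef, kAlt, countModel, variant,
                               log = FALSE) {
    ll <- .logLikMatrix(matrix(c(kRef, kAlt), 1L), .sliceModel(countModel,
        variant))
    if (log) ll[1L, ] else exp(ll[1L, ])
}

# single-variant view of a count model (keeps genotypeLikelihood simple)
.sliceModel <- function(countModel, variant) {
    new("CountModel", lambda0 = countModel@lambda0,
        epsilon = countModel@epsilon, dMax = countModel@dMax,
        histRef = countModel@histRef[variant, , , drop = FALSE],
        histAlt = countModel@histAlt[variant, , , drop = FALSE])
}

#' Posterior genotype probabilities with a helper-variant prior
#'
#' Combines the variant's own genotype likelihoods with the haplotype-panel
#' prior carried by its helper variant: for each genotype \code{a},
#' \code{posterior(a)} is proportional to \code{L_i(a) * sum_b pi(a, b) *
#' L_h(b)}, which equals the marginal over the 9 genotype combinations of
#' \code{L_i(a) * P(G_h = b) * P(G_i = a | G_h = b) * L_h(b)}, normalized
#' over \code{a}.
#'
#' @param likI 3-vector of likelihoods at the variant of interest.
#' @param likH 3-vector of likelihoods at its helper variant.
#' @param pi 3x3 smoothed joint genotype frequency matrix (rows = variant
#'   of interest, columns = helper).
#' @param popPrior fallback 3-vector prior used (with a warning) when the
#'   unnormalized posterior is all-zero.
#' @return posterior 3-vector summing to 1.
#' @export
posteriorWithHelper <- function(likI, likH, pi, popPrior = rep(1 / 3, 3)) {
    priorH <- colSums(pi)            # P(G_h)
    trans <- sweep(pi, 2L, priorH, "/") # P(G_i | G_h), columns sum to 1
    prior <- as.numeric(trans %*% (priorH * likH))
    unnorm <- likI * prior
    s <- sum(unnorm)
    if (!is.finite(s) || s <= 0) {
        warning("all-zero posterior; falling back to the population prior")
        unnorm <- popPrior
        s <- sum(unnorm)
    }
    unnorm / s
}

#' Call a genotype from posterior probabilities
#'
#' Argmax with ties broken in the order 0/0 > 0/1 > 1/1; the quality is
#' the phred-scaled probability of miscall,
#' \code{-10 * log10(1 - max posterior)}, capped at 99.
#'
#' @param posterior 3-vector of posterior probabilities.
#' @return list with \code{genotype} (0, 1 or 2) and \code{quality}.
#' @examples
#' callGenotype(c(0.01, 0.04, 0.95)) # 1/1, quality 13
#' @export
callGenotype <- function(posterior) {
    g <- which.max(posterior) - 1L
    pmax <- posterior[g + 1L]
    q <- if (pmax >= 1) 99 else min(99, round(-10 * log10(1 - pmax)))
    list(genotype = g, quality = as.numeric(q))
}

# naive (unique-kmer) ablation of a count model: duplicate counts replaced
# by the idealized own-site copies, class sizes preserved
.naiveModel <- function(countModel) {
    dims <- dim(countModel@histRef)
    hr <- array(0, dims)
    ha <- array(0, dims)
    ownRef <- .ownCopies("ref")
    ownAlt <- .ownCopies("alt")
    for (g in 0:2) {
        hr[, g + 1L, ownRef[g + 1L] + 1L] <-
            rowSums(countModel@histRef[, g + 1L, , drop = FALSE], dims = 1L)
        ha[, g + 1L, ownAlt[g + 1L] + 1L] <-
            rowSums(countModel@histAlt[, g + 1L, , drop = FALSE], dims = 1L)
    }
    new("CountModel", lambda0 = countModel@lambda0,
        epsilon = countModel@epsilon, dMax = countModel@dMax,
        histRef = hr, histAlt = ha)
}

#' Genotype a sample from reads (or precomputed node counts)
#'
#' Runs the counting and genotyping stages against a prebuilt
#' \linkS4class{GenotypeIndex}: observed allele k-mer counts are scored
#' under the population count model, and, in \code{"full"} mode, combined
#' with each variant's helper prior
#' (\code{\link{posteriorWithHelper}}). In \code{"likelihoods-only"} mode
#' the helper term is skipped and the posterior is the normalized product
#' of the k-mer likelihood and the population genotype prior — the output
#' meant for downstream imputation tools. Variants without a helper fall
#' back to the same formula.
#'
#' @param archive a \linkS4class{GenotypeIndex}.
#' @param reads read sequences or FASTA/FASTQ path(s) (ignored when
#'   \code{counts} is given).
#' @param counts optional precomputed \linkS4class{NodeCounts}.
#' @param mode \code{"full"} or \code{"likelihoods-only"}.
#' @param naive use the unique-k-mer ablation count model.
#' @param lambda0,epsilon optional overrides of the archived rates (e.g.
#'   to recalibrate \code{lambda0} to a sample's actual coverage).
#' @return data.frame with one row per variant: \code{variant},
#'   \code{genotype} (0/1/2), \code{gq}, posterior \code{p0,p1,p2},
#'   normalized k-mer-only likelihoods \code{l0,l1,l2} and the observed
#'   counts \code{kRef,kAlt}.
#' @export
genotypeSample <- function(archive, reads = NULL, counts = NULL,
                           mode = c("full", "likelihoods-only"),
                           naive = FALSE, lambda0 = NULL, epsilon = NULL) {
    mode <- match.arg(mode)
    stopifnot(is(archive, "GenotypeIndex"))
    if (is.null(counts)) {
        if (is.null(reads)) stop("provide reads or counts")
        counts <- countReads(reads, archive@kmerIndex)
    }
    if (length(nodeCounts(counts)) != archive@kmerIndex@nNodes)
        stop("node-count vector does not match the index (",
            length(nodeCounts(counts)), " vs ",
            archive@kmerIndex@nNodes, " nodes)")
    model <- archive@countModel
    if (!is.null(lambda0)) model@lambda0 <- lambda0
    if (!is.null(epsilon)) model@epsilon <- epsilon
    if (naive) model <- .naiveModel(model)

    K <- variantCounts(counts, archive@graph)
    logL <- .logLikMatrix(K, model)
    ht <- archive@helperTable
    nv <- nrow(K)
    post <- matrix(0, nv, 3L)
    lik <- matrix(0, nv, 3L)
    nFallback <- 0L
    for (r in seq_len(nv)) {
        li <- exp(logL[r, ] - max(logL[r, ]))
        lik[r, ] <- li / sum(li)
        h <- ht@helper[r]
        if (mode == "full" && !is.na(h)) {
            lh <- exp(logL[h, ] - max(logL[h, ]))
            post[r, ] <- withCallingHandlers(
                posteriorWithHelper(li, lh, ht@pi[r, , ],
                    popPrior = ht@popPrior[r, ]),
                warning = function(w) {
                    nFallback <<- nFallback + 1L
                    invokeRestart("muffleWarning")
                })
        } else {
            unnorm <- li * ht@popPrior[r, ]
            s <- sum(unnorm)
            if (!is.finite(s) || s <= 0) {
                nFallback <- nFallback + 1L
                unnorm <- ht@popPrior[r, ]
                s <- sum(unnorm)
            }
            post[r, ] <- unnorm / s
        }
    }
    if (nFallback > 0L)
        warning(nFallback,
            " variant(s) fell back to the population prior")
    calls <- lapply(seq_len(nv), function(r) callGenotype(post[r, ]))
    data.frame(
        variant = archive@graph@variants$variant,
        genotype = vapply(calls, `[[`, 0L, "genotype"),
        gq = vapply(calls, `[[`, 0, "quality"),
        p0 = post[, 1L], p1 = post[, 2L], p2 = post[, 3L],
        l0 = lik[, 1L], l1 = lik[, 2L], l2 = lik[, 3L],
        kRef = K[, 1L], kAlt = K[, 2L]
    )
}
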