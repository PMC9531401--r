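#' @include AllClasses.R kmerIndex.R
NULL

#' Expected read k-mer count per genome copy
#'
#' A sequence present once per haploid genome is covered by
#' \code{coverage/2} haploid depth, and a k-mer is seen by a read only when
#' the read window fully contains it, i.e. in \code{(L - k + 1)} of the
#' \code{L} read start positions covering the base. Hence
#' \code{lambda0 = (coverage / 2) * (readLength - k + 1) / readLength}.
#'
#' @param coverage mean diploid sequencing depth (> 0).
#' @param readLength read length in bases (>= k).
#' @param k k-mer length.
#' @return the Poisson rate per single genome copy.
#' @examples
#' estimateLambda0(15, 150, 31) # 6
#' @export
estimateLambda0 <- function(coverage, readLength, k) {
    if (coverage <= 0) stop("coverage must be > 0")
    if (readLength < k) stop("readLength must be >= k")
    (coverage / 2) * (readLength - k + 1) / readLength
}

# duplicate counts d for one allele's kmer set, vectorized over panel
# individuals: total occurrences of the set across both haplotype paths
.duplicateCounts <- function(freqModel, panel, kmers) {
    hap <- haplotypeMatrix(panel)
    acc <- numeric(nrow(hap))
    for (km in unique(kmers))
        acc <- acc + .kmerHaplotypeHits(freqModel, hap, km)
    acc[seq(1, nrow(hap), by = 2)] + acc[seq(2, nrow(hap), by = 2)]
}

#' Duplicate count of an allele's selected k-mers in one individual
#'
#' Counts how many times the allele's selected k-mers occur, in total,
#' across both haplotype paths of panel individual \code{t} through the
#' graph: the own-site copies plus any duplicate copies elsewhere (the
#' quantity the Poisson rate is proportional to).
#'
#' @param freqModel the \linkS4class{KmerFrequencyModel} (carries the
#'   occurrence catalogue).
#' @param panel the \linkS4class{GenotypePanel}.
#' @param kmers the allele's selected canonical k-mers.
#' @param individual index of the panel individual.
#' @return a non-negative integer.
#' @export
individualDuplicateCount <- function(freqModel, panel, kmers, individual) {
    stopifnot(individual >= 1L, individual <= nIndividuals(panel))
    .duplicateCounts(freqModel, panel, kmers)[individual]
}

# idealized own-site copy number of an allele under each genotype
.ownCopies <- function(allele) {
    if (allele == "ref") c(2L, 1L, 0L) else c(0L, 1L, 2L)
}

#' Build the per-genotype duplicate-count histograms
#'
#' For every (variant, allele, genotype) class, tallies how many panel
#' individuals with that genotype carry the allele's selected k-mers
#' d = 0, 1, 2, ... times in their diploid genome. Genotype classes with
#' no panel individual are filled with one pseudo-individual at the
#' idealized duplicate count (estimated off-site copies plus 0/1/2
#' own-site copies), so every mixture is defined. With
#' \code{naive = TRUE} duplicate counts are replaced by the idealized
#' own-site copies only (0/1/2 by genotype), reproducing the
#' every-k-mer-is-unique baseline model as a testable ablation.
#'
#' @param freqModel a \linkS4class{KmerFrequencyModel}.
#' @param panel the \linkS4class{GenotypePanel}.
#' @param selected per-variant selection data.frame (see
#'   \code{\link{buildGenotypeIndex}}).
#' @param lambda0 expected read k-mer count per genome copy (see
#'   \code{\link{estimateLambda0}}).
#' @param epsilon error-term rate, default 0.01.
#' @param dMax histogram overflow bin, default 15.
#' @param naive build the unique-k-mer ablation model instead.
#' @return A \linkS4class{CountModel}.
#' @export
buildCountModel <- function(freqModel, panel, selected, lambda0,
                            epsilon = 0.01, dMax = 15L, naive = FALSE) {
    nv <- nrow(selected)
    n <- nIndividuals(panel)
    G <- genotypeMatrix(panel)
    histRef <- array(0, dim = c(nv, 3L, dMax + 1L))
    histAlt <- array(0, dim = c(nv, 3L, dMax + 1L))
    for (r in seq_len(nv)) {
        vid <- selected$variant[r]
        g <- G[, vid]
        for (allele in c("ref", "alt")) {
            kmers <- selected[[paste0(allele, "Kmers")]][[r]]
            own <- .ownCopies(allele)
            if (naive || length(kmers) == 0L) {
                d <- own[g + 1L]
                dupExtra <- 0L
            } else {
                d <- .duplicateCounts(freqModel, panel, kmers)
                dupExtra <- max(0, round(mean(d) - mean(own[g + 1L])))
            }
            d <- pmin(d, dMax)
            h <- matrix(0, 3L, dMax + 1L)
            for (gt in 0:2) {
                idx <- which(g == gt)
                if (length(idx)) {
                    tab <- tabulate(d[idx] + 1L, nbins = dMax + 1L)
                    h[gt + 1L, ] <- tab
                } else {
                    dPseudo <- min(dupExtra + own[gt + 1L], dMax)
                    h[gt + 1L, dPseudo + 1L] <- 1
                }
            }
            if (allele == "ref") histRef[r, , ] <- h else histAlt[r, , ] <- h
        }
    }
    new("CountModel", lambda0 = lambda0, epsilon = epsilon,
        dMax = as.integer(dMax), histRef = histRef, histAlt = histAlt)
}

# log of the mixture-of-Poissons likelihood, via log-sum-exp
.alleleLogLik <- function(K, cvec, lambda0, epsilon) {
    d <- which(cvec > 0) - 1L
    w <- cvec[d + 1L]
    w <- w / sum(w)
    rates <- lambda0 * (d + epsilon)
    terms <- log(w) + dpois(K, rates, log = TRUE)
    m <- max(terms)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(terms - m)))
}

#' Mixture-of-Poissons likelihood of an observed allele k-mer count
#'
#' Evaluates \code{sum_d (c[d] / sum(c)) * Pois(K; lambda0 * (d +
#' epsilon))}: one Poisson component per duplicate-count bin of the panel
#' histogram, i.e. one per individual with the conditioning genotype. A
#' rate of exactly zero is the point mass at zero.
#'
#' @param K observed k-mer count(s), non-negative integer(s).
#' @param histogram numeric vector of panel counts over d = 0, 1, ...
#'   (a \code{(variant, allele, genotype)} slice of a
#'   \linkS4class{CountModel}); must have positive total mass.
#' @param lambda0 rate per genome copy.
#' @param epsilon error-term rate.
#' @return numeric vector of likelihoods, same length as \code{K}.
#' @examples
#' alleleLikelihood(2, c(0, 0, 1), lambda0 = 1, epsilon = 0) # dpois(2, 2)
#' @export
alleleLikelihood <- function(K, histogram, lambda0, epsilon) {
    if (any(K < 0)) stop("observed count K must be non-negative")
    if (sum(histogram) < 1) stop("histogram must have mass >= 1")
    vapply(K, function(x)
        exp(.alleleLogLik(x, histogram, lambda0, epsilon)), 0)
}
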