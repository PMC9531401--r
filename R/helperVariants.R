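#' @include AllClasses.R
NULL

#' Joint genotype co-occurrence matrix of a variant pair
#'
#' Estimates the smoothed 3x3 joint genotype frequency table pi(G_i, G_v)
#' from the panel: \code{pi[a, b] = (count(g_i = a, g_v = b) + s) /
#' (n + 9 s)}. Rows index the genotype at variant \code{i}, columns at
#' variant \code{v}. The default pseudo-count \code{s = 1/n} keeps every
#' cell positive so the log-diagonal helper score is finite.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param i,v distinct variant indices.
#' @param smoothing pseudo-count added to each of the 9 cells; default
#'   \code{1/nIndividuals(panel)}.
#' @return 3x3 numeric matrix summing to 1.
#' @export
genotypeCooccurrence <- function(panel, i, v,
                                 smoothing = 1 / nIndividuals(panel)) {
    if (i == v) stop("a variant cannot be its own helper (i == v)")
    G <- genotypeMatrix(panel)
    n <- nrow(G)
    counts <- matrix(tabulate(G[, i] * 3L + G[, v] + 1L, nbins = 9L),
        nrow = 3L, byrow = TRUE)
    (counts + smoothing) / (n + 9 * smoothing)
}

#' Helper-variant score of a co-occurrence matrix
#'
#' The sum over genotypes of the log joint probability of the two variants
#' agreeing: \code{log pi(0/0,0/0) + log pi(0/1,0/1) + log pi(1/1,1/1)}
#' (natural log). Higher is better; a zero diagonal entry (possible with
#' smoothing 0) gives -Inf, a valid ordering value.
#'
#' @param pi 3x3 joint genotype frequency matrix.
#' @return the score (may be -Inf).
#' @examples
#' helperScore(diag(c(0.5, 0.3, 0.2))) # log(.5) + log(.3) + log(.2)
#' @export
helperScore <- function(pi) {
    sum(log(diag(pi)))
}

#' Select the helper variant for one variant
#'
#' Scores the up-to-200 nearest variants by sorted rank on the same contig
#' (100 each side, clipped at contig ends) with
#' \code{\link{helperScore}} and returns the best one. Ties are broken by
#' smaller rank distance, then lower variant index.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param i variant index of interest.
#' @param contig optional character vector assigning each variant to a
#'   contig (candidates are restricted to \code{contig[i]}); NULL = one
#'   contig.
#' @param window candidates per side, default 100.
#' @param smoothing pseudo-count, see \code{\link{genotypeCooccurrence}}.
#' @return the helper variant index, or NA when no candidate exists.
#' @export
selectHelper <- function(panel, i, contig = NULL, window = 100L,
                         smoothing = 1 / nIndividuals(panel)) {
    G <- genotypeMatrix(panel)
    nv <- ncol(G)
    if (is.null(contig)) contig <- rep("contig", nv)
    same <- which(contig == contig[i])
    rankI <- match(i, same)
    lo <- max(1L, rankI - window)
    hi <- min(length(same), rankI + window)
    cand <- same[lo:hi]
    cand <- cand[cand != i]
    if (!length(cand)) return(NA_integer_)
    n <- nrow(G)
    gi <- G[, i]
    score <- numeric(length(cand))
    for (a in 0:2) {
        cnt <- colSums((gi == a) & (G[, cand, drop = FALSE] == a))
        score <- score + log((cnt + smoothing) / (n + 9 * smoothing))
    }
    rankDist <- abs(match(cand, same) - rankI)
    best <- order(-score, rankDist, cand)[1]
    cand[best]
}

#' Build the helper table for all variants
#'
#' Runs \code{\link{selectHelper}} for every variant and stores the chosen
#' helper's smoothed co-occurrence matrix, plus the smoothed marginal
#' genotype frequencies used as the population prior (for helper-less
#' variants and likelihoods-only mode).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param variants variant data.frame (for the contig assignment).
#' @param window candidates per side, default 100.
#' @param smoothing pseudo-count, default \code{1/nIndividuals(panel)}.
#' @return A \linkS4class{HelperTable}.
#' @export
buildHelperTable <- function(panel, variants, window = 100L,
                             smoothing = 1 / nIndividuals(panel)) {
    G <- genotypeMatrix(panel)
    nv <- ncol(G)
    n <- nrow(G)
    helper <- rep(NA_integer_, nv)
    piArr <- array(NA_real_, dim = c(nv, 3L, 3L))
    popPrior <- matrix(0, nv, 3L)
    for (i in seq_len(nv)) {
        cnt <- tabulate(G[, i] + 1L, nbins = 3L)
        popPrior[i, ] <- (cnt + smoothing) / (n + 3 * smoothing)
        h <- selectHelper(panel, i, contig = variants$contig,
            window = window, smoothing = smoothing)
        helper[i] <- h
        if (!is.na(h))
            piArr[i, , ] <- genotypeCooccurrence(panel, i, h,
                smoothing = smoothing)
    }
    new("HelperTable", helper = helper, pi = piArr, popPrior = popPrior)
}

#' Prior and transition tables derived from a helper table
#'
#' For variant \code{i}: \code{prior} is P(G_h) (the column marginal of
#' pi) and \code{transition} the column-normalized pi, i.e.
#' P(G_i | G_h) with helper genotypes as columns.
#'
#' @param helperTable a \linkS4class{HelperTable}.
#' @param i variant index.
#' @return list with \code{helper}, \code{prior} (3-vector) and
#'   \code{transition} (3x3 matrix, columns sum to 1), or NULL when the
#'   variant has no helper.
#' @export
helperPriors <- function(helperTable, i) {
    h <- helperTable@helper[i]
    if (is.na(h)) return(NULL)
    pi <- helperTable@pi[i, , ]
    priorH <- colSums(pi)
    list(helper = h, prior = priorH,
        transition = sweep(pi, 2L, priorH, "/"))
}
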