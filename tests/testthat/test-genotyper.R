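randPi <- function() {
    m <- matrix(runif(9, 0.01, 1), 3, 3)
    m / sum(m)
}

test_that("posterior matches the 9-combination enumeration oracle", {
    set.seed(77)
    for (i in 1:1000) {
        li <- runif(3)
        lh <- runif(3)
        pi <- randPi()
        got <- posteriorWithHelper(li, lh, pi)
        want <- oPosterior9(li, lh, pi)
        expect_lt(max(abs(got - want) / pmax(want, 1e-300)), 1e-12)
    }
})

test_that("an uninformative helper reduces to the population-prior posterior", {
    set.seed(78)
    for (i in 1:200) {
        pa <- runif(3); pa <- pa / sum(pa)
        pb <- runif(3); pb <- pb / sum(pb)
        li <- runif(3)
        lh <- runif(3)
        got <- posteriorWithHelper(li, lh, outer(pa, pb))
        want <- li * pa / sum(li * pa)
        expect_lt(max(abs(got - want)), 1e-12)
    }
})

test_that("uniform inputs give the uniform posterior", {
    got <- posteriorWithHelper(rep(1, 3) / 3, rep(1, 3) / 3,
        matrix(1 / 9, 3, 3))
    expect_equal(got, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("the worked helper example matches brute-force enumeration", {
    # pi from the 4-individual panel: pairs (0/0,0/0),(0/1,0/1),
    # (1/1,1/1),(0/1,0/0), unsmoothed
    pi <- matrix(0, 3, 3)
    pi[1, 1] <- 0.25; pi[2, 2] <- 0.25; pi[3, 3] <- 0.25; pi[2, 1] <- 0.25
    li <- c(0.1, 0.5, 0.2)
    lh <- c(0.6, 0.3, 0.1)
    want <- oPosterior9(li, lh, pi)
    got <- posteriorWithHelper(li, lh, pi)
    expect_equal(got, want, tolerance = 1e-12)
})

test_that("an all-zero posterior falls back to the population prior", {
    expect_warning(
        got <- posteriorWithHelper(c(0, 0, 0), c(1, 1, 1), randPi(),
            popPrior = c(0.5, 0.3, 0.2)),
        "population prior")
    expect_identical(got, c(0.5, 0.3, 0.2))
})

test_that("calls take the argmax with hom-ref-first tie-break and phred GQ", {
    call <- callGenotype(c(0.01, 0.04, 0.95))
    expect_identical(call$genotype, 2L)
    expect_identical(call$quality, 13) # -10*log10(0.05)
    tie <- callGenotype(rep(1 / 3, 3))
    expect_identical(tie$genotype, 0L)
    expect_identical(tie$quality, 2) # -10*log10(2/3) rounds to 2
    expect_identical(callGenotype(c(1, 0, 0))$quality, 99)
    expect_identical(callGenotype(c(0, 0.5, 0.5))$genotype, 1L)
})

idealModel <- function(lambda0, epsilon = 0) {
    histRef <- array(0, c(1, 3, 3))
    histAlt <- array(0, c(1, 3, 3))
    for (g in 0:2) {
        histRef[1, g + 1, (2 - g) + 1] <- 1
        histAlt[1, g + 1, g + 1] <- 1
    }
    new("CountModel", lambda0 = lambda0, epsilon = epsilon, dMax = 2L,
        histRef = histRef, histAlt = histAlt)
}

test_that("balanced counts at depth favour the heterozygote", {
    cm <- idealModel(6)
    ll <- genotypeLikelihood(6, 6, cm, 1L, log = TRUE)
    expect_identical(which.max(ll), 2L)
    # strongly skewed counts favour the homozygotes
    expect_identical(which.max(genotypeLikelihood(12, 0, cm, 1L)), 1L)
    expect_identical(which.max(genotypeLikelihood(0, 12, cm, 1L)), 3L)
})

test_that("zero observed counts leave idealized genotypes in a tie", {
    # per-genotype total rate is lambda0*(2 + 2*epsilon) for every
    # genotype, so K = (0,0) cannot separate them; the call tie-breaks
    cm <- idealModel(6, epsilon = 0.01)
    ll <- genotypeLikelihood(0, 0, cm, 1L, log = TRUE)
    expect_lt(diff(range(ll)), 1e-9)
    post <- exp(ll) / sum(exp(ll))
    expect_identical(callGenotype(post)$genotype, 0L)
})

test_that("a degenerate all-zero-rate histogram is a point mass at zero", {
    h <- c(1, 0, 0)
    expect_identical(alleleLikelihood(0, h, 5, 0), 1)
    cm <- new("CountModel", lambda0 = 5, epsilon = 0, dMax = 2L,
        histRef = array(rep(c(1, 0, 0), each = 3), c(1, 3, 3)),
        histAlt = array(rep(c(1, 0, 0), each = 3), c(1, 3, 3)))
    expect_identical(genotypeLikelihood(0, 0, cm, 1L), c(1, 1, 1))
})

test_that("the duplicated-kmer scenario is rescued by the population model", {
    # alt kmer CTA also occurs on the reference path; truth is hom-ref
    # and we observe K = (1, 1). The full model knows hom-ref individuals
    # carry CTA twice; the naive model mistakes the alt evidence.
    ref <- c(c1 = "GGCTACCCCCGACCCC")
    v <- data.frame(contig = "c1", pos = 10L, ref = "G", alt = "T",
        variant = 1L)
    g <- buildVariantGraph(ref, v)
    hap <- matrix(c(rep(0L, 6), 1L, 0L), 8L, 1L) # 3 hom-ref, 1 het
    panel <- GenotypePanel(hap)
    fm <- buildFrequencyModel(g, panel, 3L)
    selected <- data.frame(variant = 1L)
    selected$refKmers <- list("CGA")
    selected$altKmers <- list("CTA")
    full <- buildCountModel(fm, panel, selected, lambda0 = 0.5)
    naive <- buildCountModel(fm, panel, selected, lambda0 = 0.5,
        naive = TRUE)
    pFull <- genotypeLikelihood(1, 1, full, 1L)
    pNaive <- genotypeLikelihood(1, 1, naive, 1L)
    expect_gt(pFull[1] / sum(pFull), pNaive[1] / sum(pNaive))
    # the naive model calls het or worse; the full model calls hom-ref
    expect_identical(which.max(pFull), 1L)
    expect_false(which.max(pNaive) == 1L)
})

test_that("zero reads yield prior-driven calls for every variant", {
    dat <- toyFixture(seed = 41L, nVariants = 8L, nIndividuals = 5L)
    arch <- buildGenotypeIndex(dat$reference, dat$variants, dat$panel,
        k = 7L, coverage = 10, readLength = 50L)
    calls <- genotypeSample(arch, reads = character(0))
    expect_identical(nrow(calls), 8L)
    expect_identical(unique(calls$kRef), 0)
    expect_identical(unique(calls$kAlt), 0)
    expect_true(all(abs(calls$p0 + calls$p1 + calls$p2 - 1) < 1e-9))
})

test_that("error-free deep reads recover the truth on unique variants", {
    dat <- toyFixture(seed = 19L, genomeLength = 3000L, nVariants = 60L,
        nIndividuals = 10L, coverage = 30, substitutionRate = 0,
        insertionRate = 0, deletionRate = 0, indelFraction = 0.1,
        ldBlockLength = 10L)
    arch <- buildGenotypeIndex(dat$reference, dat$variants, dat$panel,
        k = 15L, coverage = 30, readLength = 50L)
    calls <- genotypeSample(arch, reads = dat$reads)
    uniq <- arch@selected$score <= 2 + 1e-9
    expect_gte(sum(uniq), 50L)
    expect_identical(mean(calls$genotype[uniq] == dat$truth[uniq]), 1)
})

test_that("likelihoods-only mode drops the helper term", {
    dat <- toyFixture(seed = 29L, nVariants = 8L, nIndividuals = 5L)
    arch <- buildGenotypeIndex(dat$reference, dat$variants, dat$panel,
        k = 7L, coverage = 10, readLength = 50L)
    counts <- countReads(dat$reads, arch@kmerIndex)
    lik <- genotypeSample(arch, counts = counts,
        mode = "likelihoods-only")
    # posterior must equal normalized likelihood x population prior
    for (r in seq_len(nrow(lik))) {
        li <- unlist(lik[r, c("l0", "l1", "l2")])
        want <- li * arch@helperTable@popPrior[r, ]
        want <- want / sum(want)
        expect_equal(unname(unlist(lik[r, c("p0", "p1", "p2")])),
            unname(want), tolerance = 1e-9)
    }
})
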