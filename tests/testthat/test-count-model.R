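test_that("lambda0 follows coverage and window-count arithmetic", {
    expect_identical(estimateLambda0(15, 150, 31), 6)
    expect_equal(estimateLambda0(2, 31, 31), 1 / 31) # single window
    expect_error(estimateLambda0(0, 150, 31), "coverage")
    expect_error(estimateLambda0(10, 20, 31), "readLength")
})

test_that("duplicate counts match brute-force counting on written-out genomes", {
    for (seed in c(3L, 8L)) {
        dat <- toyFixture(seed = seed, genomeLength = 200L,
            nVariants = 8L, nIndividuals = 5L, indelFraction = 0.25)
        g <- buildVariantGraph(dat$reference, dat$variants)
        fm <- buildFrequencyModel(g, dat$panel, dat$k)
        for (j in seq_len(nrow(dat$variants))) {
            for (allele in c("ref", "alt")) {
                win <- enumerateAlleleWindows(g, j, allele, dat$k)
                kms <- unique(canonicalKmers(win[[1]]$kmers))
                for (t in seq_len(nIndividuals(dat$panel))) {
                    expect_identical(
                        individualDuplicateCount(fm, dat$panel, kms, t),
                        oDuplicateCount(dat$reference, dat$variants,
                            dat$panel, kms, t, dat$k),
                        info = sprintf("seed %d var %d %s ind %d",
                            seed, j, allele, t))
                }
            }
        }
    }
})

test_that("unique alt kmers count own-site copies by genotype", {
    # panel: individuals with genotypes 0/0, 0/1, 1/1 at one isolated SNP
    ref <- c(c1 = "ACGTACGGTTCAGGACTTACG")
    v <- data.frame(contig = "c1", pos = 10L, ref = "C", alt = "A")
    g <- buildVariantGraph(ref, v)
    hap <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 6L, 1L)
    panel <- GenotypePanel(hap)
    fm <- buildFrequencyModel(g, panel, 5L)
    win <- enumerateAlleleWindows(g, 1L, "alt", 5L)
    km <- canonicalKmers(win[[3]]$kmers)
    expect_identical(individualDuplicateCount(fm, panel, km, 1L), 0)
    expect_identical(individualDuplicateCount(fm, panel, km, 2L), 1)
    expect_identical(individualDuplicateCount(fm, panel, km, 3L), 2)
})

test_that("a duplicated alt kmer gives hom-ref individuals d = 2", {
    # alt allele spells CTA, which also occurs on the reference elsewhere:
    # each of a hom-ref individual's two chromosomes carries the elsewhere
    # copy
    ref <- c(c1 = "GGCTACCCCCGACCCC") # CTA once; revcomp TAG absent
    v <- data.frame(contig = "c1", pos = 10L, ref = "G", alt = "T")
    g <- buildVariantGraph(ref, v)
    hap <- matrix(c(0L, 0L, 1L, 1L), 4L, 1L)
    panel <- GenotypePanel(hap)
    fm <- buildFrequencyModel(g, panel, 3L)
    expect_identical(individualDuplicateCount(fm, panel, "CTA", 1L), 2)
    # hom-alt individual: two own copies plus two elsewhere copies
    expect_identical(individualDuplicateCount(fm, panel, "CTA", 2L), 4)
})

test_that("histograms tally individuals per genotype class", {
    ref <- c(c1 = "ACGTACGGTTCAGGACTTACG")
    v <- data.frame(contig = "c1", pos = 10L, ref = "C", alt = "A",
        variant = 1L)
    g <- buildVariantGraph(ref, v)
    hap <- matrix(c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L), 8L, 1L) # 2x 0/0, 2x 0/1
    panel <- GenotypePanel(hap)
    fm <- buildFrequencyModel(g, panel, 5L)
    win <- enumerateAlleleWindows(g, 1L, "alt", 5L)
    selected <- data.frame(variant = 1L)
    selected$refKmers <- list(canonicalKmers(
        enumerateAlleleWindows(g, 1L, "ref", 5L)[[3]]$kmers))
    selected$altKmers <- list(canonicalKmers(win[[3]]$kmers))
    cm <- buildCountModel(fm, panel, selected, lambda0 = 6)
    # alt-allele histograms: hom-ref mass at 0, het at 1
    expect_identical(cm@histAlt[1, 1, ], c(2, rep(0, 15)))
    expect_identical(cm@histAlt[1, 2, ], c(0, 2, rep(0, 14)))
    # empty hom-alt class: one pseudo-individual at idealized d = 2
    expect_identical(cm@histAlt[1, 3, ], c(0, 0, 1, rep(0, 13)))
    # every class sums to its (possibly pseudo-filled) size
    sums <- apply(cm@histAlt[1, , ], 1L, sum)
    expect_identical(unname(sums), c(2, 2, 1))
})

test_that("mixture likelihood reproduces closed-form Poisson values", {
    # single component at d = 2, lambda0 = 1: plain Pois(K; 2)
    h <- c(0, 0, 1)
    expect_equal(alleleLikelihood(2, h, lambda0 = 1, epsilon = 0),
        0.27067, tolerance = 1e-4)
    expect_equal(alleleLikelihood(0:10, h, 1, 0), dpois(0:10, 2))
    # degenerate rate: point mass at zero
    h0 <- c(1, 0, 0)
    expect_identical(alleleLikelihood(0, h0, 1, 0), 1)
    expect_identical(alleleLikelihood(3, h0, 1, 0), 0)
    # two-component mixture by hand: 0.5 * 1 + 0.5 * exp(-2)
    h2 <- c(1, 1)
    expect_equal(alleleLikelihood(0, h2, lambda0 = 2, epsilon = 0),
        0.56767, tolerance = 1e-4)
    expect_error(alleleLikelihood(-1, h, 1, 0), "non-negative")
})

test_that("the mixture normalizes over counts for all stored histograms", {
    dat <- toyFixture(seed = 13L, nVariants = 8L, nIndividuals = 5L)
    arch <- buildGenotypeIndex(dat$reference, dat$variants, dat$panel,
        k = 7L, coverage = 10, readLength = 50L)
    cm <- arch@countModel
    for (r in seq_len(nrow(arch@selected))) {
        for (g in 1:3) {
            for (h in list(cm@histRef[r, g, ], cm@histAlt[r, g, ])) {
                total <- sum(alleleLikelihood(0:200, h, cm@lambda0,
                    cm@epsilon))
                expect_lt(abs(total - 1), 1e-9)
            }
        }
    }
})

test_that("single individual with d = 1 reduces to the plain Poisson pmf", {
    h <- c(0, 1)
    for (l0 in c(0.5, 4, 12)) {
        expect_equal(alleleLikelihood(0:40, h, l0, 0), dpois(0:40, l0))
    }
})

test_that("heterozygous truth wins the likelihood comparison at depth", {
    # unique-kmer variant, idealized histograms; K ~ Pois per allele
    set.seed(101)
    lambda0 <- 4
    histRef <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)) # d = 2,1,0
    histAlt <- histRef[3:1, ]
    wins <- replicate(1000, {
        kr <- rpois(1, lambda0 * 1)
        ka <- rpois(1, lambda0 * 1)
        ll <- vapply(1:3, function(g)
            log(alleleLikelihood(kr, histRef[g, ], lambda0, 0.01)) +
            log(alleleLikelihood(ka, histAlt[g, ], lambda0, 0.01)), 0)
        which.max(ll) == 2L
    })
    expect_gte(mean(wins), 0.9)
})
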