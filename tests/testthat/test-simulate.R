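test_that("fixed seeds give byte-identical fixtures", {
    cfg <- simulationConfig(genomeLength = 2000L, nVariants = 20L,
        nIndividuals = 6L, readLength = 50L, seed = 33L)
    d1 <- simulateDataset(cfg)
    d2 <- simulateDataset(cfg)
    expect_identical(d1$reference, d2$reference)
    expect_identical(d1$variants, d2$variants)
    expect_identical(haplotypeMatrix(d1$panel), haplotypeMatrix(d2$panel))
    expect_identical(d1$truth, d2$truth)
    expect_identical(d1$reads, d2$reads)
    # and written files are byte-identical too
    o1 <- withr::local_tempdir()
    o2 <- withr::local_tempdir()
    simulateDataset(cfg, outDir = o1)
    simulateDataset(cfg, outDir = o2)
    for (f in list.files(o1)) {
        expect_identical(readLines(file.path(o1, f)),
            readLines(file.path(o2, f)), info = f)
    }
})

test_that("an exact duplication makes every source kmer non-unique", {
    set.seed(2)
    ref <- simulateReference(3000L, duplications = list(
        list(sourceStart = 200L, length = 300L, targetStart = 1500L,
            identity = 1.0)))
    k <- 11L
    src <- substr(ref[[1]], 201L, 500L)
    tab <- oKmerCounts(ref, k)
    for (km in oCanonical(oWindows(src, k)))
        expect_gte(tab[[km]], 2L)
    # partial identity shares fewer kmers; no duplication shares ~none
    set.seed(2)
    ref90 <- simulateReference(3000L, duplications = list(
        list(sourceStart = 200L, length = 300L, targetStart = 1500L,
            identity = 0.9)))
    set.seed(2)
    ref0 <- simulateReference(3000L)
    shared <- function(r) {
        s <- substr(r[[1]], 201L, 500L)
        t <- substr(r[[1]], 1501L, 1800L)
        mean(oCanonical(oWindows(s, k)) %in% oCanonical(oWindows(t, k)))
    }
    expect_gt(shared(ref90), shared(ref0))
    expect_lt(shared(ref90), 1)
    expect_identical(shared(ref), 1)
    expect_error(simulateReference(1000L, duplications = list(
        list(sourceStart = 100L, length = 300L, targetStart = 200L,
            identity = 1))), "overlap")
})

test_that("degenerate mosaic settings give founder copies or independence", {
    # one block spanning everything: every haplotype equals a founder
    cfg <- simulationConfig(genomeLength = 3000L, nVariants = 40L,
        nIndividuals = 20L, nFounders = 2L, ldBlockLength = 40L,
        readLength = 50L, seed = 8L)
    set.seed(cfg$seed)
    ref <- simulateReference(cfg$genomeLength)
    pan <- simulatePanel(ref, cfg)
    hap <- haplotypeMatrix(pan$panel)
    for (r in seq_len(nrow(hap))) {
        match <- apply(pan$founders, 1L, function(f)
            identical(unname(hap[r, ]), unname(f)))
        expect_true(any(match))
    }
    # block length 1: near-zero pairwise genotype correlation
    cfg1 <- simulationConfig(genomeLength = 3000L, nVariants = 10L,
        nIndividuals = 500L, ldBlockLength = 1L, readLength = 50L,
        seed = 9L)
    set.seed(cfg1$seed)
    ref1 <- simulateReference(cfg1$genomeLength)
    pan1 <- simulatePanel(ref1, cfg1)
    G <- genotypeMatrix(pan1$panel)
    cors <- cor(G)
    offdiag <- cors[upper.tri(cors)]
    expect_lt(max(abs(offdiag)), 0.1)
})

test_that("panel allele frequencies track the founder mixture", {
    cfg <- simulationConfig(genomeLength = 3000L, nVariants = 30L,
        nIndividuals = 100L, nFounders = 4L, ldBlockLength = 5L,
        readLength = 50L, seed = 10L)
    set.seed(cfg$seed)
    ref <- simulateReference(cfg$genomeLength)
    pan <- simulatePanel(ref, cfg)
    founderAF <- colMeans(pan$founders)
    panelAF <- colMeans(haplotypeMatrix(pan$panel))
    # binomial tolerance: 4 sigma at n = 200 haplotypes
    tol <- 4 * sqrt(founderAF * (1 - founderAF) / 200)
    expect_true(all(abs(panelAF - founderAF) <= tol + 1e-12))
})

test_that("sample haplotypes apply alleles with correct length bookkeeping", {
    dat <- toyFixture(seed = 3L, nVariants = 10L, indelFraction = 0.5)
    hap <- dat$sample$haplotypes
    for (h in 1:2) {
        glen <- nchar(dat$sample$genomes[[h]][[1]])
        delta <- sum((nchar(dat$variants$alt) -
            nchar(dat$variants$ref))[hap[h, ] == 1L])
        expect_identical(glen, nchar(dat$reference[[1]]) + delta)
        # independent right-to-left splice oracle agrees
        expect_identical(dat$sample$genomes[[h]][[1]],
            oApplyHap(dat$reference, dat$variants, hap[h, ])[[1]])
    }
    # applying no alleles is the identity
    expect_identical(
        applyHaplotype(dat$reference, dat$variants,
            rep(0L, nrow(dat$variants)))[[1]],
        dat$reference[[1]])
})

test_that("error-free reads are exact substrings of a haplotype", {
    dat <- toyFixture(seed = 14L, genomeLength = 1000L, nVariants = 10L,
        substitutionRate = 0, insertionRate = 0, deletionRate = 0,
        coverage = 5)
    strings <- c(dat$sample$genomes[[1]][[1]],
        dat$sample$genomes[[2]][[1]])
    strings <- c(strings, oRevcomp(strings))
    for (rd in dat$reads)
        expect_true(any(grepl(rd, strings, fixed = TRUE)))
})

test_that("read count and substitution rate match their settings", {
    cfg <- simulationConfig(genomeLength = 30000L, nVariants = 10L,
        nIndividuals = 4L, coverage = 15, readLength = 150L,
        insertionRate = 0, deletionRate = 0, seed = 44L)
    dat <- simulateDataset(cfg)
    G <- mean(nchar(c(dat$sample$genomes[[1]][[1]],
        dat$sample$genomes[[2]][[1]])))
    expect_lt(abs(length(dat$reads) - 15 * G / 150), 2)
    # align each read back to its source-free mismatch tally: with only
    # substitutions, reads keep their length and mismatch fraction is
    # binomial around 0.001
    strings <- c(dat$sample$genomes[[1]][[1]],
        dat$sample$genomes[[2]][[1]])
    strings <- c(strings, oRevcomp(strings))
    locate <- function(rd) {
        # anchor the read by an error-free 20-mer seed, then compare
        for (off in c(0L, 20L, 40L, 60L)) {
            anchor <- substr(rd, off + 1L, off + 20L)
            for (s in strings) {
                p <- regexpr(anchor, s, fixed = TRUE)
                if (p > 0L) {
                    start <- p - off
                    if (start >= 1L &&
                        start + nchar(rd) - 1L <= nchar(s))
                        return(substr(s, start, start + nchar(rd) - 1L))
                }
            }
        }
        NULL
    }
    nbases <- 0
    nmis <- 0
    for (rd in dat$reads) {
        src <- locate(rd)
        if (is.null(src)) next # unlocatable read (clustered errors)
        nbases <- nbases + nchar(rd)
        nmis <- nmis + sum(strsplit(src, "")[[1]] !=
            strsplit(rd, "")[[1]])
    }
    expect_gt(nbases, 4e5)
    rate <- nmis / nbases
    sigma <- sqrt(0.001 * 0.999 / nbases)
    expect_lt(abs(rate - 0.001), 3 * sigma + 1e-5)
})
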