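#' @include AllClasses.R utils.R io.R
NULL

#' Default simulation configuration
#'
#' The study conditions used throughout the test suite: a 100 kb random
#' genome, 500 biallelic variants (10\% short indels), a phased panel of
#' 50 individuals built by mosaic copying of 4 founder haplotypes in
#' blocks of 50 variants (which yields genotype correlation decaying with
#' rank distance), 15x single-end 150 bp reads, and substitution /
#' insertion / deletion error rates of 0.001 each.
#'
#' @param ... overrides of any default field.
#' @return named list of simulation parameters.
#' @export
simulationConfig <- function(...) {
    cfg <- list(
        genomeLength = 100000L,
        nVariants = 500L,
        nIndividuals = 50L,
        nFounders = 4L,
        ldBlockLength = 50L,
        indelFraction = 0.1,
        maxIndel = 5L,
        coverage = 15,
        readLength = 150L,
        substitutionRate = 0.001,
        insertionRate = 0.001,
        deletionRate = 0.001,
        duplications = list(),
        contig = "chr1",
        seed = 1L
    )
    over <- list(...)
    stopifnot(all(names(over) %in% names(cfg)))
    cfg[names(over)] <- over
    rates <- c(cfg$substitutionRate, cfg$insertionRate, cfg$deletionRate)
    if (any(rates < 0 | rates > 1)) stop("error rates must be in [0, 1]")
    cfg
}

#' Simulate a random reference genome with optional segmental duplications
#'
#' Draws a uniform random A/C/G/T sequence, then copies each configured
#' source interval onto its target position with per-base mutation down to
#' the requested identity — creating shared (non-unique) k-mers between
#' the two copies, the scenario that defeats unique-k-mer genotype models.
#'
#' @param genomeLength genome length in bases.
#' @param duplications list of \code{list(sourceStart, length,
#'   targetStart, identity)} (0-based starts; target must not overlap the
#'   source).
#' @param contig contig name.
#' @return named character vector of length 1. Uses the current RNG
#'   state; call \code{set.seed} first for reproducibility.
#' @export
simulateReference <- function(genomeLength, duplications = list(),
                              contig = "chr1") {
    seq <- paste(sample(.BASES, genomeLength, replace = TRUE),
        collapse = "")
    for (dup in duplications) {
        s0 <- dup$sourceStart
        len <- dup$length
        t0 <- dup$targetStart
        if (max(s0, t0) < min(s0 + len, t0 + len))
            stop("duplication source and target overlap")
        if (t0 < 0 || t0 + len > genomeLength || s0 < 0 ||
            s0 + len > genomeLength)
            stop("duplication interval outside the genome")
        copy <- strsplit(substr(seq, s0 + 1L, s0 + len), "")[[1]]
        mut <- which(runif(len) > dup$identity)
        copy[mut] <- vapply(copy[mut], function(b)
            sample(setdiff(.BASES, b), 1L), "")
        seq <- paste0(substr(seq, 1L, t0), paste(copy, collapse = ""),
            substr(seq, t0 + len + 1L, genomeLength))
    }
    setNames(seq, contig)
}

# sample non-overlapping variant positions: uniform without replacement,
# greedily thinned to the minimum spacing
.samplePositions <- function(genomeLength, n, minGap, margin) {
    lo <- margin
    hi <- genomeLength - margin
    cand <- sort(sample(lo:hi, min(4L * n, hi - lo), replace = FALSE))
    keep <- integer(0)
    last <- -minGap
    for (p in cand) {
        if (p - last >= minGap) {
            keep <- c(keep, p)
            last <- p
        }
    }
    if (length(keep) < n)
        stop("could not place ", n, " variants with spacing ", minGap)
    sort(sample(keep, n))
}

#' Simulate variants and a mosaic-founder haplotype panel
#'
#' Places SNPs (plus a configurable fraction of 1-5 bp indels) uniformly
#' without overlap, draws founder haplotypes with Bernoulli(0.5) alleles
#' (redrawn so every variant is polymorphic among founders), and builds
#' each panel haplotype by copying a random founder in blocks of
#' \code{ldBlockLength} consecutive variants. Nearby variants in one block
#' are inherited together, so genotype correlation decays with rank
#' distance — the linkage the helper-variant prior exploits.
#'
#' @param reference named contig sequences (one contig).
#' @param config a \code{\link{simulationConfig}} list.
#' @return list with \code{variants} (data.frame), \code{panel}
#'   (\linkS4class{GenotypePanel}) and \code{founders} (0/1 matrix). Uses
#'   the current RNG state.
#' @export
simulatePanel <- function(reference, config) {
    ct <- names(reference)[1]
    seq <- reference[[1]]
    L <- nchar(seq)
    n <- config$nVariants
    pos <- .samplePositions(L, n, minGap = config$maxIndel + 2L,
        margin = 10L)
    nIndel <- round(config$indelFraction * n)
    type <- rep("snp", n)
    if (nIndel > 0) {
        idx <- sample(n, nIndel)
        type[idx] <- sample(c("ins", "del"), nIndel, replace = TRUE)
    }
    ref <- alt <- character(n)
    for (j in seq_len(n)) {
        base <- substr(seq, pos[j] + 1L, pos[j] + 1L)
        if (type[j] == "snp") {
            ref[j] <- base
            alt[j] <- sample(setdiff(.BASES, base), 1L)
        } else if (type[j] == "ins") {
            ref[j] <- ""
            alt[j] <- paste(sample(.BASES, sample(config$maxIndel, 1L),
                replace = TRUE), collapse = "")
        } else {
            len <- sample(config$maxIndel, 1L)
            ref[j] <- substr(seq, pos[j] + 1L, pos[j] + len)
            alt[j] <- ""
        }
    }
    variants <- data.frame(variant = seq_len(n), contig = ct, pos = pos,
        ref = ref, alt = alt, af = NA_real_, stringsAsFactors = FALSE)

    founders <- matrix(rbinom(config$nFounders * n, 1L, 0.5),
        config$nFounders, n)
    mono <- which(colSums(founders) %in% c(0L, nrow(founders)))
    for (j in mono) { # force polymorphism among founders
        flip <- sample(config$nFounders, 1L)
        founders[flip, j] <- 1L - founders[flip, j]
    }
    hap <- .mosaicHaplotypes(founders, 2L * config$nIndividuals,
        config$ldBlockLength)
    panel <- GenotypePanel(hap)
    variants$af <- colMeans(hap)
    list(variants = variants, panel = panel, founders = founders)
}

# draw nHap haplotypes by block-wise mosaic copying of the founders
.mosaicHaplotypes <- function(founders, nHap, ldBlockLength) {
    n <- ncol(founders)
    blocks <- split(seq_len(n),
        ceiling(seq_len(n) / max(1L, ldBlockLength)))
    hap <- matrix(0L, nHap, n)
    for (h in seq_len(nHap)) {
        for (b in blocks) {
            f <- sample(nrow(founders), 1L)
            hap[h, b] <- founders[f, b]
        }
    }
    hap
}

#' Simulate a diploid sample related to the panel
#'
#' Draws two haplotypes by the same founder-mosaic process as the panel
#' (so the sample shares the panel's linkage structure without copying any
#' panel individual) and applies them to the reference.
#'
#' @param reference named contig sequences.
#' @param variants variant data.frame from \code{\link{simulatePanel}}.
#' @param founders founder haplotype matrix from the same call.
#' @param config a \code{\link{simulationConfig}} list.
#' @return list with \code{genotypes} (truth vector, 0/1/2),
#'   \code{haplotypes} (2 x variants matrix) and \code{genomes} (list of
#'   two named contig-sequence vectors). Uses the current RNG state.
#' @export
simulateSample <- function(reference, variants, founders, config) {
    hap <- .mosaicHaplotypes(founders, 2L, config$ldBlockLength)
    genomes <- list(
        applyHaplotype(reference, variants, hap[1L, ]),
        applyHaplotype(reference, variants, hap[2L, ])
    )
    list(genotypes = hap[1L, ] + hap[2L, ], haplotypes = hap,
        genomes = genomes)
}

# apply substitution / insertion / deletion errors to one read
.mutateRead <- function(seq, nSub, nIns, nDel) {
    b <- strsplit(seq, "", fixed = TRUE)[[1]]
    L <- length(b)
    if (nSub > 0) {
        idx <- sample(L, nSub)
        b[idx] <- vapply(b[idx], function(x)
            sample(setdiff(.BASES, x), 1L), "")
    }
    if (nDel > 0) b[sample(L, nDel)] <- ""
    if (nIns > 0) {
        idx <- sample(L, nIns)
        b[idx] <- paste0(b[idx], sample(.BASES, nIns, replace = TRUE))
    }
    paste(b, collapse = "")
}

#' Simulate single-end reads from a diploid genome
#'
#' Draws read start positions uniformly from both haplotype strings
#' (expected total bases = coverage x genome length), flips each read to
#' the reverse strand with probability 1/2, and applies per-base
#' substitution, insertion and deletion errors at the configured rates.
#'
#' @param genomes list of two named contig-sequence vectors (a sample's
#'   haplotype genomes).
#' @param config a \code{\link{simulationConfig}} list.
#' @return character vector of read sequences. Uses the current RNG
#'   state.
#' @export
simulateReads <- function(genomes, config) {
    L <- config$readLength
    if (config$coverage <= 0) stop("coverage must be > 0")
    seqs <- unlist(genomes, use.names = FALSE)
    lens <- nchar(seqs)
    if (any(lens < L)) stop("read length exceeds a haplotype length")
    G <- sum(lens) / 2
    nReads <- round(config$coverage * G / L)
    src <- sample(length(seqs), nReads, replace = TRUE,
        prob = lens / sum(lens))
    starts <- floor(runif(nReads) * (lens[src] - L + 1)) + 1L
    reads <- substring(seqs[src], starts, starts + L - 1L)
    rc <- runif(nReads) < 0.5
    if (any(rc)) reads[rc] <- .revcomp(reads[rc])
    nSub <- rbinom(nReads, L, config$substitutionRate)
    nIns <- rbinom(nReads, L, config$insertionRate)
    nDel <- rbinom(nReads, L, config$deletionRate)
    mut <- which(nSub + nIns + nDel > 0L)
    for (i in mut)
        reads[i] <- .mutateRead(reads[i], nSub[i], nIns[i], nDel[i])
    reads
}

#' Generate a complete self-contained fixture set
#'
#' Seeds the RNG and runs \code{\link{simulateReference}},
#' \code{\link{simulatePanel}}, \code{\link{simulateSample}} and
#' \code{\link{simulateReads}}; optionally writes the four fixture files
#' (reference FASTA, phased panel VCF, reads FASTQ, sample truth VCF) plus
#' a config echo. Fixed seed implies byte-identical outputs.
#'
#' @param config a \code{\link{simulationConfig}} list.
#' @param outDir output directory, or NULL to skip writing files.
#' @return list with \code{reference}, \code{variants}, \code{panel},
#'   \code{founders}, \code{truth} (genotype vector), \code{sample},
#'   \code{reads} and, when written, \code{files}.
#' @export
simulateDataset <- function(config = simulationConfig(), outDir = NULL) {
    set.seed(config$seed)
    reference <- simulateReference(config$genomeLength,
        config$duplications, config$contig)
    pan <- simulatePanel(reference, config)
    smp <- simulateSample(reference, pan$variants, pan$founders, config)
    reads <- simulateReads(smp$genomes, config)
    out <- list(reference = reference, variants = pan$variants,
        panel = pan$panel, founders = pan$founders,
        truth = smp$genotypes, sample = smp, reads = reads)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        files <- list(
            reference = file.path(outDir, "reference.fa"),
            panel = file.path(outDir, "panel.vcf"),
            reads = file.path(outDir, "reads.fq"),
            truth = file.path(outDir, "truth.vcf"),
            config = file.path(outDir, "config.yaml")
        )
        Biostrings::writeXStringSet(
            Biostrings::DNAStringSet(reference), files$reference)
        .writePanelVcf(pan$variants, pan$panel, files$panel,
            reference = reference)
        truthPanel <- GenotypePanel(smp$haplotypes)
        .writePanelVcf(pan$variants, truthPanel, files$truth,
            reference = reference, sampleNames = "TRUTH")
        qual <- strrep("I", nchar(reads))
        writeLines(paste0("@read", seq_along(reads), "\n", reads,
            "\n+\n", qual), files$reads)
        scal <- vapply(config, function(x) !is.list(x), TRUE)
        writeLines(c(
            paste0(names(config)[scal], ": ",
                vapply(config[scal], format, "")),
            sprintf("duplications: %d", length(config$duplications))),
            files$config)
        out$files <- files
    }
    out
}
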