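# Independent brute-force oracles. These deliberately avoid the package's
# graph/index machinery: everything is computed on written-out strings.

oRevcomp <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
            collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

oCanonical <- function(x) {
    rc <- oRevcomp(x)
    out <- ifelse(x <= rc, x, rc)
    out[grepl("[^ACGT]", x)] <- NA
    out
}

# all k-windows of a string (NA-free, non-canonical)
oWindows <- function(seq, k) {
    n <- nchar(seq)
    if (n < k) return(character(0))
    substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# splice chosen alt alleles into the reference (independent of
# applyHaplotype): variants have 0-based pos, possibly empty ref/alt
oApplyHap <- function(reference, variants, alleles) {
    out <- reference
    for (ct in names(reference)) {
        idx <- which(variants$contig == ct & alleles == 1L)
        idx <- idx[order(variants$pos[idx], decreasing = TRUE)]
        seq <- reference[[ct]]
        for (v in idx) { # right-to-left so positions stay valid
            p <- variants$pos[v]
            seq <- paste0(substr(seq, 1L, p), variants$alt[v],
                substr(seq, p + nchar(variants$ref[v]) + 1L, nchar(seq)))
        }
        out[[ct]] <- seq
    }
    out
}

# canonical-kmer occurrence counts over a set of sequences
oKmerCounts <- function(seqs, k) {
    kms <- unlist(lapply(seqs, oWindows, k), use.names = FALSE)
    kms <- oCanonical(kms)
    table(kms[!is.na(kms)])
}

# population frequency of every kmer: total occurrences over all written
# out panel haplotype genomes, divided by the number of individuals
oFrequencyTable <- function(reference, variants, panel, k) {
    hap <- haplotypeMatrix(panel)
    n <- nrow(hap) / 2
    seqs <- unlist(lapply(seq_len(nrow(hap)), function(r) {
        oApplyHap(reference, variants, hap[r, ])
    }), use.names = FALSE)
    tab <- oKmerCounts(seqs, k)
    stats::setNames(as.numeric(tab) / n, names(tab))
}

# occurrences of a canonical kmer set in one individual's diploid genome
oDuplicateCount <- function(reference, variants, panel, kmers, t, k) {
    hap <- haplotypeMatrix(panel)
    seqs <- unlist(lapply(c(2L * t - 1L, 2L * t), function(r) {
        oApplyHap(reference, variants, hap[r, ])
    }), use.names = FALSE)
    tab <- oKmerCounts(seqs, k)
    sum(as.numeric(tab[names(tab) %in% kmers]))
}

# quadratic read-vs-index scanner: for every read window, compare against
# every indexed kmer string (both orientations)
oCountReads <- function(reads, kmerNodes, k) {
    counts <- numeric(max(unlist(kmerNodes, use.names = FALSE)))
    idxK <- names(kmerNodes)
    for (rd in reads) {
        for (w in oWindows(rd, k)) {
            cw <- oCanonical(w)
            if (is.na(cw)) next
            for (i in seq_along(idxK)) {
                if (identical(oCanonical(idxK[i]), cw)) {
                    for (nd in kmerNodes[[i]])
                        counts[nd] <- counts[nd] + 1
                }
            }
        }
    }
    counts
}

# 9-combination posterior enumeration (Bayes over the joint genotype grid)
oPosterior9 <- function(likI, likH, pi) {
    joint <- matrix(0, 3, 3)
    for (a in 1:3) {
        for (b in 1:3) {
            joint[a, b] <- likI[a] * likH[b] * pi[a, b]
        }
    }
    rowSums(joint) / sum(joint)
}

# small deterministic toy fixture shared by several suites
toyFixture <- function(seed = 42L, genomeLength = 200L, nVariants = 8L,
                       nIndividuals = 4L, indelFraction = 0,
                       readLength = 50L, k = 5L, ...) {
    cfg <- simulationConfig(genomeLength = genomeLength,
        nVariants = nVariants, nIndividuals = nIndividuals,
        indelFraction = indelFraction, readLength = readLength,
        seed = seed, ...)
    dat <- simulateDataset(cfg)
    dat$cfg <- cfg
    dat$k <- k
    dat
}
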