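#' @include AllClasses.R
NULL

.BASES <- c("A", "C", "G", "T")

# reverse complement of ACGT strings (pure R; the hot paths use C++)
.revcomp <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
            collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

#' Canonicalize k-mers
#'
#' Returns, for each input k-mer, the lexicographically smaller of the
#' k-mer and its reverse complement. Because bases are ordered
#' A < C < G < T, this equals the k-mer with the numerically smaller 2-bit
#' encoding. Reads have unknown strand, so both the index and the read
#' counter operate on canonical k-mers only. Inputs containing non-ACGT
#' characters map to NA.
#'
#' @param kmers character vector of k-mers (1-31 bases each).
#' @return character vector of canonical k-mers.
#' @examples
#' canonicalKmers(c("TTT", "AAA", "ACGN"))
#' @export
canonicalKmers <- function(kmers) {
    .cppCanonicalKmers(as.character(kmers))
}

#' Encode a k-mer as a canonical 2-bit integer code
#'
#' Encodes bases as A=0, C=1, G=2, T=3, two bits each (big-endian), and
#' returns the numerically smaller of the encodings of the k-mer and its
#' reverse complement. The code is returned as a double, exact for
#' k <= 26; the genotyping pipeline itself keys on canonical k-mer strings
#' (an equivalent ordering), so it supports the default k = 31.
#'
#' @param kmer a single k-mer string (A/C/G/T only).
#' @return list with \code{code} (double) and \code{canonical} (TRUE when
#'   the forward orientation won or tied), or NULL (skip signal) for
#'   non-ACGT input.
#' @examples
#' encodeKmer("AAA")$code    # 0
#' encodeKmer("TTT")$code    # same canonical code as AAA
#' @export
encodeKmer <- function(kmer) {
    stopifnot(is.character(kmer), length(kmer) == 1L)
    k <- nchar(kmer)
    if (k < 1L || k > 26L)
        stop("encodeKmer supports k in 1..26 (exact double arithmetic)")
    b <- match(strsplit(kmer, "", fixed = TRUE)[[1]], .BASES) - 1L
    if (anyNA(b)) return(NULL)
    w <- 4^((k - 1):0)
    fwd <- sum(b * w)
    rev <- sum((3 - rev(b)) * w)
    if (fwd <= rev) list(code = fwd, canonical = TRUE)
    else list(code = rev, canonical = FALSE)
}

# genotype integer code (0/1/2) -> VCF label
.gtLabel <- function(g) .GT_LABELS[g + 1L]

# left-trim the shared prefix of a VCF REF/ALT pair; returns the
# normalised (pos, ref, alt) with pos 0-based
.trimAlleles <- function(pos, ref, alt) {
    n <- min(nchar(ref), nchar(alt))
    trim <- 0L
    while (trim < n && substr(ref, trim + 1L, trim + 1L) ==
        substr(alt, trim + 1L, trim + 1L))
        trim <- trim + 1L
    # keep at least one differing base context: trim fully, empty allowed
    list(pos = pos + trim,
        ref = substr(ref, trim + 1L, nchar(ref)),
        alt = substr(alt, trim + 1L, nchar(alt)))
}

#' Apply a haplotype's alternative alleles to the reference
#'
#' Splices the alternative alleles carried by one haplotype into the
#' reference sequences, yielding the haplotype's genome strings. This is
#' the coordinate-shift-aware string edit used by the sample simulator and
#' by the brute-force oracles in the test suite.
#'
#' @param reference named character vector (or list) of contig sequences.
#' @param variants data.frame with columns \code{variant}, \code{contig},
#'   \code{pos} (0-based), \code{ref}, \code{alt}, as in
#'   \code{variantTable}.
#' @param alleles integer vector (0 = ref, 1 = alt), one per variant row.
#' @return named character vector of contig sequences with the alleles
#'   applied.
#' @examples
#' v <- data.frame(variant = 1L, contig = "c", pos = 2L,
#'     ref = "G", alt = "T")
#' applyHaplotype(c(c = "ACGTT"), v, 1L)
#' @export
applyHaplotype <- function(reference, variants, alleles) {
    stopifnot(length(alleles) == nrow(variants))
    out <- vapply(names(reference), function(ct) {
        seq <- reference[[ct]]
        idx <- which(variants$contig == ct & alleles == 1L)
        if (!length(idx)) return(seq)
        idx <- idx[order(variants$pos[idx])]
        pieces <- character(2L * length(idx) + 1L)
        cursor <- 0L # 0-based, next reference base to copy
        for (j in seq_along(idx)) {
            v <- idx[j]
            p <- variants$pos[v]
            pieces[2L * j - 1L] <- substr(seq, cursor + 1L, p)
            pieces[2L * j] <- variants$alt[v]
            cursor <- p + nchar(variants$ref[v])
        }
        pieces[2L * length(idx) + 1L] <- substr(seq, cursor + 1L, nchar(seq))
        paste(pieces, collapse = "")
    }, character(1))
    names(out) <- names(reference)
    out
}
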