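#' @include AllClasses.R utils.R
NULL

#' Read a reference genome from FASTA
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @return named character vector of uppercase contig sequences, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acg", "t"), fa)
#' readReferenceFasta(fa)
#' @export
readReferenceFasta <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    if (!length(seqs)) stop("empty FASTA file: ", path)
    out <- toupper(as.character(seqs))
    # FASTA headers may carry descriptions; the contig name is word one
    names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
    if (anyDuplicated(names(out))) stop("duplicate contig names in ", path)
    if (any(nchar(out) == 0L)) stop("empty sequence record in ", path)
    out
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Yields read sequences only; qualities are ignored. Reads containing N
#' are passed through unchanged (k-mer windows containing non-ACGT bases
#' are skipped downstream). Format is sniffed from the first record so
#' plain and gzip-compressed files of either format work.
#'
#' @param path path to a FASTA or FASTQ file, optionally .gz.
#' @return character vector of read sequences.
#' @export
readReads <- function(path) {
    con <- gzfile(path, "rt")
    first <- readLines(con, n = 1L)
    close(con)
    if (!length(first)) stop("empty read file: ", path)
    fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
    toupper(as.character(Biostrings::readDNAStringSet(path, format = fmt)))
}

# map a vector of VCF GT strings to genotype codes; missing -> NA
.parseGT <- function(gt) {
    gt[is.na(gt)] <- "./." # absent GT == missing
    gt <- sub(":.*", "", gt)
    parts <- strsplit(gt, "[/|]")
    bad <- lengths(parts) != 2L
    if (any(bad))
        stop("non-diploid GT field: ", gt[which(bad)[1]])
    a1 <- vapply(parts, `[`, "", 1L)
    a2 <- vapply(parts, `[`, "", 2L)
    miss <- a1 == "." | a2 == "."
    g <- suppressWarnings(as.integer(a1) + as.integer(a2))
    if (any(!miss & (is.na(g) | g > 2L)))
        stop("GT allele index out of range for a biallelic site")
    g[miss] <- NA_integer_
    list(g = g, a1 = suppressWarnings(as.integer(a1)),
        a2 = suppressWarnings(as.integer(a2)))
}

#' Read biallelic variants and a genotype panel from VCF
#'
#' Multi-allelic records are skipped with a warning (the model is strictly
#' biallelic). Missing genotypes (./.) are counted and treated as hom-ref.
#' Heterozygous genotypes are unordered: 1|0 and 0|1 map to the same
#' class. Alleles are left-trimmed of their shared prefix, so indels are
#' stored with one possibly-empty allele and a 0-based position of the
#' first affected base.
#'
#' @param path path to a VCF 4.x file with GT fields for all samples.
#' @param minAF keep only variants with alternative allele frequency
#'   strictly above this threshold (the INFO AF field when present,
#'   otherwise the panel genotype frequency). Default 0 = no filter.
#' @return list with \code{variants} (data.frame: variant, contig, pos,
#'   ref, alt, af) and \code{panel} (\linkS4class{GenotypePanel}).
#' @export
readPanelVcf <- function(path, minAF = 0) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    if (!nrow(fix)) stop("VCF contains no records: ", path)
    multi <- grepl(",", fix$ALT, fixed = TRUE) | fix$ALT == "." |
        is.na(fix$ALT)
    if (any(multi))
        warning(sum(multi), " multi-allelic or ALT-less record(s) skipped")
    keep <- !multi
    gtmat <- vcfR::extract.gt(vcf, element = "GT", return.alleles = FALSE)
    if (is.null(gtmat) || !ncol(gtmat))
        stop("VCF has no sample GT fields: ", path)
    gtmat <- gtmat[keep, , drop = FALSE]
    fix <- fix[keep, , drop = FALSE]

    nInd <- ncol(gtmat)
    nVar <- nrow(fix)
    G <- matrix(0L, nInd, nVar)
    H1 <- matrix(0L, nInd, nVar)
    H2 <- matrix(0L, nInd, nVar)
    nonmiss <- gtmat[!grepl("^\\.", sub(":.*", "", gtmat))]
    phased <- !any(grepl("/", nonmiss, fixed = TRUE))
    nMissing <- 0L
    for (j in seq_len(nVar)) {
        p <- .parseGT(gtmat[j, ])
        miss <- is.na(p$g)
        nMissing <- nMissing + sum(miss)
        g <- p$g
        g[miss] <- 0L
        G[, j] <- g
        if (phased) {
            a1 <- p$a1; a2 <- p$a2
            a1[miss] <- 0L; a2[miss] <- 0L
        } else { # split heterozygotes deterministically
            a1 <- ifelse(g == 2L, 1L, 0L)
            a2 <- ifelse(g >= 1L, 1L, 0L)
        }
        H1[, j] <- a1
        H2[, j] <- a2
    }
    if (nMissing > 0L)
        message(nMissing, " missing panel genotype(s) treated as hom-ref")

    af <- colMeans(rbind(H1, H2))
    infoAF <- suppressWarnings(as.numeric(sub(
        ".*(^|;)AF=([^;]*).*", "\\2",
        ifelse(grepl("(^|;)AF=", fix$INFO), fix$INFO, NA))))
    af <- ifelse(is.na(infoAF), af, infoAF)

    trimmed <- lapply(seq_len(nVar), function(j) {
        .trimAlleles(as.integer(fix$POS[j]) - 1L, fix$REF[j], fix$ALT[j])
    })
    variants <- data.frame(
        contig = fix$CHROM,
        pos = vapply(trimmed, `[[`, 0L, "pos"),
        ref = vapply(trimmed, `[[`, "", "ref"),
        alt = vapply(trimmed, `[[`, "", "alt"),
        af = af,
        stringsAsFactors = FALSE
    )
    if (any(variants$ref == variants$alt))
        stop("record with identical REF and ALT alleles")

    keepAF <- if (minAF > 0) variants$af > minAF else
        rep(TRUE, nrow(variants))
    if (minAF > 0 && !all(keepAF))
        message(sum(!keepAF), " variant(s) removed by allele-frequency filter")
    ord <- order(variants$contig[keepAF], variants$pos[keepAF])
    idx <- which(keepAF)[ord]
    variants <- variants[idx, , drop = FALSE]
    variants <- cbind(variant = seq_len(nrow(variants)), variants)
    rownames(variants) <- NULL

    hap <- matrix(0L, 2L * nInd, nrow(variants))
    hap[seq(1, 2L * nInd, by = 2L), ] <- H1[, idx, drop = FALSE]
    hap[seq(2, 2L * nInd, by = 2L), ] <- H2[, idx, drop = FALSE]
    list(variants = variants, panel = GenotypePanel(hap, phased = phased))
}

# VCF-facing allele fields: re-anchor empty alleles on the previous
# reference base, 1-based POS
.vcfAlleleFields <- function(variants, reference) {
    pos1 <- variants$pos + 1L
    ref <- variants$ref
    alt <- variants$alt
    needAnchor <- nchar(ref) == 0L | nchar(alt) == 0L
    if (any(needAnchor)) {
        if (is.null(reference))
            stop("reference sequences required to write indel records")
        for (i in which(needAnchor)) {
            base <- substr(reference[[variants$contig[i]]],
                variants$pos[i], variants$pos[i])
            ref[i] <- paste0(base, ref[i])
            alt[i] <- paste0(base, alt[i])
            pos1[i] <- variants$pos[i] # anchor base, 1-based
        }
    }
    data.frame(pos1 = pos1, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

.vcfHeader <- function(reference, sampleNames, extraFormat = TRUE) {
    h <- c("##fileformat=VCFv4.2", "##source=kmertyper")
    if (!is.null(reference))
        h <- c(h, sprintf("##contig=<ID=%s,length=%d>",
            names(reference), nchar(reference)))
    h <- c(h,
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    if (extraFormat)
        h <- c(h,
            paste0("##FORMAT=<ID=GL,Number=G,Type=Float,Description=",
                "\"Log10 genotype likelihoods (0/0,0/1,1/1), ",
                "kmer evidence only\">"),
            paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=",
                "\"Phred-scaled genotype quality\">"))
    c(h, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
        "INFO", "FORMAT", sampleNames), collapse = "\t"))
}

#' Write genotype calls as VCF
#'
#' Emits a VCF 4.2 file with GT, GL and GQ FORMAT fields for one sample.
#' GL holds log10-scaled normalized k-mer-evidence likelihoods (ordered
#' 0/0, 0/1, 1/1), i.e. without the helper prior, which is the input
#' downstream imputation tools expect; GT and GQ come from the calling
#' mode's posterior.
#'
#' @param variants variant data.frame as in \code{variantTable}.
#' @param calls data.frame of calls from \code{\link{genotypeSample}} (one
#'   row per variant: \code{genotype}, \code{gq}, \code{l0,l1,l2}).
#' @param path output path.
#' @param reference named contig sequences (needed to re-anchor indels).
#' @param sampleName sample column name.
#' @return invisibly, the output path.
#' @export
writeGenotypedVcf <- function(variants, calls, path, reference = NULL,
                              sampleName = "SAMPLE") {
    if (nrow(calls) != nrow(variants))
        stop("internal error: ", nrow(calls), " calls for ",
            nrow(variants), " variants")
    av <- .vcfAlleleFields(variants, reference)
    gl <- log10(pmax(cbind(calls$l0, calls$l1, calls$l2), 1e-300))
    body <- paste(
        variants$contig, av$pos1, ".", av$ref, av$alt, ".", "PASS", ".",
        "GT:GL:GQ",
        sprintf("%s:%.4f,%.4f,%.4f:%d", .gtLabel(calls$genotype),
            gl[, 1], gl[, 2], gl[, 3], as.integer(calls$gq)),
        sep = "\t")
    writeLines(c(.vcfHeader(reference, sampleName), body), path)
    invisible(path)
}

# write a panel VCF with (phased) GT fields; used by the simulator and in
# round-trip tests
.writePanelVcf <- function(variants, panel, path, reference = NULL,
                           sampleNames = NULL) {
    n <- nIndividuals(panel)
    if (is.null(sampleNames)) sampleNames <- sprintf("ind%03d", seq_len(n))
    av <- .vcfAlleleFields(variants, reference)
    hap <- haplotypeMatrix(panel)
    sep <- if (panel@phased) "|" else "/"
    gtCols <- vapply(seq_len(n), function(t) {
        paste0(hap[2L * t - 1L, ], sep, hap[2L * t, ])
    }, character(nrow(variants)))
    if (nrow(variants) == 1L) gtCols <- matrix(gtCols, nrow = 1L)
    af <- colMeans(hap)
    body <- paste(variants$contig, av$pos1, ".", av$ref, av$alt, ".",
        "PASS", sprintf("AF=%.6g", af), "GT",
        apply(gtCols, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(.vcfHeader(reference, sampleNames, extraFormat = FALSE),
        body), path)
    invisible(path)
}
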