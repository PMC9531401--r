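#' @include AllClasses.R utils.R graph.R
NULL

# extended offset range that covers every window intersecting the allele
# (windows may start inside a multi-base insertion allele)
.catalogOffsets <- function(k, alleleLen) {
    -(k - 1L):max(0L, alleleLen - 1L)
}

#' Build the k-mer population-frequency model from the graph windows
#'
#' For every k-mer spelled by a graph path window, computes its expected
#' number of copies in a random panel individual's diploid genome: each
#' window occurrence contributes the mean number of haplotypes per
#' individual consistent with the occurrence's local allele combination
#' (a reference window far from any variant contributes 2.0, both
#' chromosomes). Occurrences on alternative paths are catalogued once,
#' anchored at their leftmost alternative allele, and the catalogue is
#' reused to compute per-individual duplicate counts for the count model.
#'
#' @param graph a \linkS4class{VariantGraph}.
#' @param panel the \linkS4class{GenotypePanel} the graph was built from.
#' @param k k-mer length.
#' @param altWindows optional precomputed list (per variant id) of
#'   \code{\link{enumerateAlleleWindows}} results for the alt allele over
#'   the extended catalogue offsets; computed here when NULL.
#' @return A \linkS4class{KmerFrequencyModel}.
#' @export
buildFrequencyModel <- function(graph, panel, k, altWindows = NULL) {
    v <- graph@variants
    hap <- haplotypeMatrix(panel)
    n <- nIndividuals(panel)
    stopifnot(ncol(hap) == nrow(v))
    freq <- new.env(hash = TRUE, parent = emptyenv())
    occVar <- new.env(hash = TRUE, parent = emptyenv())
    refCanon <- list()
    refStarts <- list()
    refOverlap <- list()

    addFreq <- function(km, x) {
        cur <- freq[[km]]
        freq[[km]] <- if (is.null(cur)) x else cur + x
    }

    # fraction of haplotype rows consistent with a constraint set, times 2
    # (mean consistent haplotypes per individual)
    meanHaps <- function(vars, alleles) {
        if (!length(vars)) return(2)
        sub <- hap[, vars, drop = FALSE]
        ok <- rowSums(sub == rep(alleles, each = nrow(sub))) == length(vars)
        2 * sum(ok) / (2 * n)
    }

    # --- reference-path windows ---
    for (ct in names(graph@contigs)) {
        seq <- graph@contigs[[ct]]
        L <- nchar(seq)
        nwin <- L - k + 1L
        canon <- .cppCanonicalWindows(seq, k)
        refCanon[[ct]] <- canon
        if (nwin < 1L) {
            refOverlap[[ct]] <- list(starts = integer(0), sets = list())
            refStarts[[ct]] <- new.env(hash = TRUE, parent = emptyenv())
            next
        }
        ok <- which(!is.na(canon))
        refStarts[[ct]] <- list2env(split(ok - 1L, canon[ok]),
            envir = new.env(hash = TRUE, parent = emptyenv()))
        vct <- which(v$contig == ct)
        pairsStart <- integer(0)
        pairsVar <- integer(0)
        for (j in vct) {
            p <- v$pos[j]
            r <- nchar(v$ref[j])
            s0 <- max(0L, p - k + 1L)
            s1 <- min(nwin - 1L, if (r > 0L) p + r - 1L else p - 1L)
            if (s1 >= s0) {
                ss <- s0:s1
                pairsStart <- c(pairsStart, ss)
                pairsVar <- c(pairsVar, rep(j, length(ss)))
            }
        }
        if (length(pairsStart)) {
            sets <- split(pairsVar, pairsStart)
            starts <- as.integer(names(sets))
            refOverlap[[ct]] <- list(starts = starts, sets = unname(sets))
            # constrained windows, grouped by identical variant set
            groupKey <- vapply(sets, paste, "", collapse = ",")
            for (gk in unique(groupKey)) {
                idx <- which(groupKey == gk)
                vars <- sets[[idx[1]]]
                contrib <- meanHaps(vars, rep(0L, length(vars)))
                for (s in starts[idx]) {
                    km <- canon[s + 1L]
                    if (!is.na(km)) addFreq(km, contrib)
                }
            }
            unconstrained <- setdiff(seq_len(nwin) - 1L, starts)
        } else {
            refOverlap[[ct]] <- list(starts = integer(0), sets = list())
            unconstrained <- seq_len(nwin) - 1L
        }
        kms <- canon[unconstrained + 1L]
        kms <- kms[!is.na(kms)]
        if (length(kms)) {
            tab <- table(kms)
            for (i in seq_along(tab))
                addFreq(names(tab)[i], 2 * unname(tab[i]))
        }
    }

    # --- alternative-path windows, anchored at the leftmost alt allele ---
    for (j in seq_len(nrow(v))) {
        win <- if (!is.null(altWindows)) altWindows[[j]] else
            enumerateAlleleWindows(graph, v$variant[j], "alt", k,
                offsets = .catalogOffsets(k, nchar(v$alt[j])))
        for (ws in win) {
            for (occ in ws$occurrences) {
                isAlt <- occ$alleles == 1L
                if (!any(isAlt)) next
                altPos <- v$pos[occ$vars[isAlt]]
                if (occ$vars[isAlt][which.min(altPos)] != v$variant[j]) next
                km <- canonicalKmers(occ$kmer)
                if (is.na(km)) next
                addFreq(km, meanHaps(occ$vars, occ$alleles))
                cur <- occVar[[km]]
                occVar[[km]] <- c(cur,
                    list(list(vars = occ$vars, alleles = occ$alleles)))
            }
        }
    }

    new("KmerFrequencyModel", k = as.integer(k), freq = freq,
        occVar = occVar, refCanon = refCanon, refStarts = refStarts,
        refOverlap = refOverlap, nIndividuals = as.integer(n))
}

#' Look up expected population frequency of k-mers
#'
#' @param model a \linkS4class{KmerFrequencyModel}.
#' @param kmers character vector of k-mers (canonicalized internally).
#' @return numeric vector of expected diploid copies per panel individual;
#'   0 for k-mers absent from every graph window.
#' @export
kmerFrequency <- function(model, kmers) {
    km <- canonicalKmers(kmers)
    out <- numeric(length(km))
    hit <- !is.na(km)
    if (any(hit))
        out[hit] <- vapply(mget(km[hit], envir = model@freq,
            ifnotfound = list(0)), `[[`, 0, 1L)
    out
}

# per-haplotype-row occurrence counts of one canonical kmer across the
# graph, given the panel haplotypes: the workhorse behind duplicate counts
.kmerHaplotypeHits <- function(freqModel, hap, km) {
    acc <- numeric(nrow(hap))
    occs <- freqModel@occVar[[km]]
    for (occ in occs) {
        sub <- hap[, occ$vars, drop = FALSE]
        ok <- rowSums(sub == rep(occ$alleles, each = nrow(sub))) ==
            length(occ$vars)
        acc <- acc + ok
    }
    for (ct in names(freqModel@refCanon)) {
        starts <- freqModel@refStarts[[ct]][[km]]
        if (is.null(starts)) next
        ov <- freqModel@refOverlap[[ct]]
        for (s in starts) {
            hitIdx <- match(s, ov$starts)
            if (is.na(hitIdx)) {
                acc <- acc + 1
            } else {
                vars <- ov$sets[[hitIdx]]
                ok <- rowSums(hap[, vars, drop = FALSE] == 0L) ==
                    length(vars)
                acc <- acc + ok
            }
        }
    }
    acc
}

#' Select the k-mer window set for each variant
#'
#' Scores every candidate window offset by the maximum expected population
#' frequency over the union of its ref- and alt-allele k-mers, and keeps
#' the offset minimising that maximum (ambiguous, high-frequency k-mers
#' are avoided). Ties prefer the most window-centred offset (nearest
#' \code{-floor((k-1)/2)}), then the lower offset. Degenerate offsets are
#' excluded; when every offset is degenerate the one with fewest k-mers is
#' used and the variant flagged low-confidence.
#'
#' @param windowsRef,windowsAlt \code{\link{enumerateAlleleWindows}}
#'   results for the two alleles (selection offsets \code{-(k-1):0}).
#' @param freqModel a \linkS4class{KmerFrequencyModel}.
#' @param k k-mer length (for the centring tie-break).
#' @return list with \code{offset}, \code{refKmers}, \code{altKmers}
#'   (canonical, unique), \code{score} (the minimised maximum frequency)
#'   and \code{lowConfidence}; or NULL when no window exists at all.
#' @export
selectVariantKmers <- function(windowsRef, windowsAlt, freqModel, k) {
    offR <- vapply(windowsRef, `[[`, 0L, "offset")
    offA <- vapply(windowsAlt, `[[`, 0L, "offset")
    offs <- intersect(offR, offA)
    offs <- offs[offs <= 0L]
    if (!length(offs)) return(NULL)
    cand <- lapply(offs, function(o) {
        wr <- windowsRef[[match(o, offR)]]
        wa <- windowsAlt[[match(o, offA)]]
        refK <- unique(canonicalKmers(wr$kmers))
        altK <- unique(canonicalKmers(wa$kmers))
        refK <- refK[!is.na(refK)]
        altK <- altK[!is.na(altK)]
        list(offset = o, refKmers = refK, altKmers = altK,
            degenerate = wr$degenerate || wa$degenerate,
            nKmers = length(refK) + length(altK))
    })
    cand <- Filter(function(x) length(x$refKmers) > 0L &&
        length(x$altKmers) > 0L, cand)
    if (!length(cand)) return(NULL)
    scores <- vapply(cand, function(x)
        max(kmerFrequency(freqModel, c(x$refKmers, x$altKmers))), 0)
    degen <- vapply(cand, `[[`, TRUE, "degenerate")
    centre <- -((k - 1L) %/% 2L)
    pick <- function(idx, key) {
        o <- vapply(cand[idx], `[[`, 0L, "offset")
        ord <- order(key, abs(o - centre), o)
        idx[ord[1]]
    }
    if (any(!degen)) {
        idx <- which(!degen)
        best <- pick(idx, scores[idx])
        low <- FALSE
    } else {
        best <- pick(seq_along(cand),
            vapply(cand, `[[`, 0L, "nKmers"))
        low <- TRUE
    }
    list(offset = cand[[best]]$offset,
        refKmers = cand[[best]]$refKmers,
        altKmers = cand[[best]]$altKmers,
        score = scores[best],
        lowConfidence = low)
}

#' Build the k-mer-to-allele-node lookup index
#'
#' @param selected data.frame of per-variant selections (columns
#'   \code{variant}, list columns \code{refKmers}, \code{altKmers}), as
#'   assembled by \code{\link{buildGenotypeIndex}}.
#' @param graph the \linkS4class{VariantGraph}.
#' @param k k-mer length.
#' @return A \linkS4class{KmerIndex}: looking up any selected canonical
#'   k-mer returns every allele-node id it was selected for; unselected
#'   k-mers return an empty vector.
#' @export
buildKmerIndex <- function(selected, graph, k) {
    lookup <- new.env(hash = TRUE, parent = emptyenv())
    vn <- graph@variantNodes
    add <- function(kms, node) {
        for (km in kms) {
            cur <- lookup[[km]]
            lookup[[km]] <- if (is.null(cur)) node else
                unique(c(cur, node))
        }
    }
    for (r in seq_len(nrow(selected))) {
        row <- match(selected$variant[r], vn$variant)
        add(selected$refKmers[[r]], vn$refNode[row])
        add(selected$altKmers[[r]], vn$altNode[row])
    }
    new("KmerIndex", k = as.integer(k), lookup = lookup,
        nNodes = nrow(graph@nodes))
}

#' Look up the allele nodes a k-mer maps to
#'
#' @param index a \linkS4class{KmerIndex}.
#' @param kmer a single k-mer (canonicalized internally).
#' @return integer vector of allele-node ids (empty when unindexed).
#' @export
lookupKmer <- function(index, kmer) {
    km <- canonicalKmers(kmer)
    if (is.na(km)) return(integer(0))
    val <- index@lookup[[km]]
    if (is.null(val)) integer(0) else val
}
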