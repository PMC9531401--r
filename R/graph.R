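#' @include AllClasses.R utils.R
NULL

#' Build an acyclic pangenome graph from a reference and biallelic variants
#'
#' Each contig becomes a chain of reference-segment nodes interrupted by a
#' (ref-allele, alt-allele) node pair per variant; both allele nodes share
#' their predecessor and successor segments, so every source-to-sink path
#' spells a haplotype. Deletion alleles get an empty-sequence node, so the
#' alternative path skips the deleted bases. Node ids increase along the
#' genome, making the graph acyclic by construction.
#'
#' Variants must be sorted by (contig, position). Variants whose reference
#' allele disagrees with the reference sequence raise an error naming the
#' variant; variants overlapping an earlier variant's reference interval
#' are skipped with a warning.
#'
#' @param reference named character vector of contig sequences (see
#'   \code{\link{readReferenceFasta}}).
#' @param variants data.frame with columns \code{contig}, \code{pos}
#'   (0-based), \code{ref}, \code{alt} and optionally \code{af}; e.g. the
#'   \code{variants} element of \code{\link{readPanelVcf}}.
#' @return A \linkS4class{VariantGraph}. The returned
#'   \code{variantTable} has ids renumbered 1..n over the retained
#'   variants and a \code{kept} attribute giving the original row indices.
#' @examples
#' g <- buildVariantGraph(c(c1 = "ACTAGA"),
#'     data.frame(contig = "c1", pos = 3L, ref = "G", alt = "T"))
#' g
#' @export
buildVariantGraph <- function(reference, variants) {
    stopifnot(is.character(reference), !is.null(names(reference)))
    if (is.null(variants$af))
        variants$af <- rep(NA_real_, nrow(variants))
    ord <- order(match(variants$contig, names(reference)), variants$pos)
    if (!identical(ord, seq_len(nrow(variants))))
        variants <- variants[ord, , drop = FALSE]

    # drop variants overlapping an earlier kept variant: a variant must
    # start at or after the previous kept variant's reserved end (its ref
    # interval, minimum width 1 so co-located insertions don't collide)
    keep <- rep(TRUE, nrow(variants))
    lastEnd <- -1L
    lastContig <- ""
    for (j in seq_len(nrow(variants))) {
        if (!identical(variants$contig[j], lastContig)) {
            lastEnd <- -1L
            lastContig <- variants$contig[j]
        }
        if (variants$pos[j] < lastEnd) {
            keep[j] <- FALSE
        } else {
            lastEnd <- variants$pos[j] + max(1L, nchar(variants$ref[j]))
        }
    }
    if (!all(keep))
        warning(sum(!keep), " variant(s) overlapping an earlier variant ",
            "were skipped")
    kept <- which(keep)
    variants <- variants[keep, , drop = FALSE]

    # reference-allele consistency
    for (j in seq_len(nrow(variants))) {
        ct <- variants$contig[j]
        if (!ct %in% names(reference))
            stop("variant ", j, " references unknown contig '", ct, "'")
        r <- variants$ref[j]
        if (nchar(r) > 0L) {
            seen <- substr(reference[[ct]], variants$pos[j] + 1L,
                variants$pos[j] + nchar(r))
            if (!identical(seen, r))
                stop(sprintf(
                    "REF mismatch at %s:%d (variant %d): VCF has '%s', reference has '%s'",
                    ct, variants$pos[j] + 1L, j, r, seen))
        }
    }

    nodes <- list()
    edges <- list()
    vnodes <- list()
    refPath <- list()
    nid <- 0L
    addNode <- function(contig, seq, role) {
        nid <<- nid + 1L
        nodes[[length(nodes) + 1L]] <<- data.frame(node = nid,
            contig = contig, seq = seq, role = role,
            stringsAsFactors = FALSE)
        nid
    }
    vrow <- 0L
    for (ct in names(reference)) {
        seq <- reference[[ct]]
        vs <- which(variants$contig == ct)
        path <- integer(0)
        cursor <- 0L
        prevIds <- integer(0) # nodes feeding the next segment
        for (j in vs) {
            vrow <- vrow + 1L
            p <- variants$pos[j]
            segId <- addNode(ct, substr(seq, cursor + 1L, p),
                "reference-segment")
            for (pid in prevIds)
                edges[[length(edges) + 1L]] <- c(pid, segId)
            path <- c(path, segId)
            refId <- addNode(ct, variants$ref[j], "ref-allele")
            altId <- addNode(ct, variants$alt[j], "alt-allele")
            edges[[length(edges) + 1L]] <- c(segId, refId)
            edges[[length(edges) + 1L]] <- c(segId, altId)
            vnodes[[vrow]] <- c(vrow, refId, altId)
            path <- c(path, refId)
            prevIds <- c(refId, altId)
            cursor <- p + nchar(variants$ref[j])
        }
        segId <- addNode(ct, substr(seq, cursor + 1L, nchar(seq)),
            "reference-segment")
        for (pid in prevIds)
            edges[[length(edges) + 1L]] <- c(pid, segId)
        path <- c(path, segId)
        refPath[[ct]] <- path
    }

    variants$variant <- seq_len(nrow(variants))
    variants <- variants[, c("variant", "contig", "pos", "ref", "alt", "af")]
    rownames(variants) <- NULL
    attr(variants, "kept") <- kept
    edgeDf <- if (length(edges)) {
        m <- do.call(rbind, edges)
        data.frame(from = m[, 1], to = m[, 2])
    } else data.frame(from = integer(0), to = integer(0))
    vnodeDf <- if (length(vnodes)) {
        m <- do.call(rbind, vnodes)
        data.frame(variant = m[, 1], refNode = m[, 2], altNode = m[, 3])
    } else data.frame(variant = integer(0), refNode = integer(0),
        altNode = integer(0))
    new("VariantGraph",
        nodes = do.call(rbind, nodes),
        edges = edgeDf,
        variantNodes = vnodeDf,
        refPath = refPath,
        variants = variants,
        contigs = reference)
}

# number of distinct source->sink paths per contig (DP over the DAG)
.countPaths <- function(graph, contig) {
    path <- graph@refPath[[contig]]
    nodeIds <- sort(graph@nodes$node[graph@nodes$contig == contig])
    ways <- setNames(numeric(length(nodeIds)), nodeIds)
    ways[as.character(path[1])] <- 1
    e <- graph@edges[graph@edges$from %in% nodeIds, , drop = FALSE]
    for (id in nodeIds) {
        out <- e$to[e$from == id]
        for (t in out)
            ways[as.character(t)] <- ways[as.character(t)] +
                ways[as.character(id)]
    }
    ways[as.character(path[length(path)])]
}

# splice chosen alleles into a reference region.
# regionSeq covers reference coords [regionStart, regionEnd); vars is a
# data.frame of variants fully inside the region, sorted by pos; chosen is
# 0 (ref) / 1 (alt) per row. Returns the spliced string plus each
# variant's 0-based start and length within it.
.spliceRegion <- function(regionSeq, regionStart, vars, chosen) {
    nv <- nrow(vars)
    pieces <- character(2L * nv + 1L)
    starts <- integer(nv)
    lens <- integer(nv)
    cursor <- 0L # relative to regionStart
    outLen <- 0L
    for (j in seq_len(nv)) {
        rel <- vars$pos[j] - regionStart
        pre <- substr(regionSeq, cursor + 1L, rel)
        allele <- if (chosen[j] == 1L) vars$alt[j] else vars$ref[j]
        pieces[2L * j - 1L] <- pre
        pieces[2L * j] <- allele
        outLen <- outLen + nchar(pre)
        starts[j] <- outLen
        lens[j] <- nchar(allele)
        outLen <- outLen + lens[j]
        cursor <- rel + nchar(vars$ref[j])
    }
    pieces[2L * nv + 1L] <- substr(regionSeq, cursor + 1L, nchar(regionSeq))
    list(seq = paste(pieces, collapse = ""), starts = starts, lens = lens)
}

# does window [w, w+k) intersect an allele piece at [s, s+len)?
# zero-length pieces (deletion alt, insertion ref) use the strict-interior
# junction rule: the window must span the junction to be constrained by it.
.windowHits <- function(w, k, s, len) {
    ifelse(len > 0L, (w < s + len) & (w + k > s), (w < s) & (w + k > s))
}

#' Enumerate the k-length path windows covering a variant allele
#'
#' For every window offset in \code{[-(k-1), 0]} relative to the allele
#' start on its own path (the junction position for empty deletion
#' alleles), enumerates every k-mer spelled by a graph path through the
#' allele node: one spelling per combination of ref/alt choices at the
#' neighbouring variants whose allele nodes intersect the window.
#' Offsets whose window runs off the contig are dropped. A window set
#' with more than \code{maxKmers} spellings (or more than 8 intersecting
#' variants) is flagged degenerate and later excluded from k-mer
#' selection.
#'
#' @param graph a \linkS4class{VariantGraph}.
#' @param variantId integer variant id.
#' @param allele \code{"ref"} or \code{"alt"}.
#' @param k k-mer length.
#' @param offsets window offsets to enumerate (default \code{-(k-1):0}).
#' @param maxKmers degeneracy cap per window set (default 256 = 2^8).
#' @return list with one element per surviving offset: a list with
#'   \code{offset}, \code{kmers} (unique forward spellings),
#'   \code{occurrences} (list of \code{list(kmer, vars, alleles)} local
#'   allele-combination constraints) and \code{degenerate}.
#' @examples
#' g <- buildVariantGraph(c(c1 = "ACTAGAC"),
#'     data.frame(contig = "c1", pos = 3L, ref = "G", alt = "T"))
#' enumerateAlleleWindows(g, 1L, "alt", k = 3L)
#' @export
enumerateAlleleWindows <- function(graph, variantId, allele = c("ref", "alt"),
                                   k, offsets = NULL, maxKmers = 256L) {
    allele <- match.arg(allele)
    v <- graph@variants
    if (!variantId %in% v$variant)
        stop("unknown variant id: ", variantId)
    i <- match(variantId, v$variant)
    stopifnot(k >= 1L)
    ct <- v$contig[i]
    seq <- graph@contigs[[ct]]
    L <- nchar(seq)
    alleleSeq <- if (allele == "alt") v$alt[i] else v$ref[i]
    lenA <- nchar(alleleSeq)
    if (is.null(offsets)) offsets <- -(k - 1L):0L

    slack <- 40L + k
    startR <- max(0L, v$pos[i] - (k - 1L) - slack)
    endR <- min(L, v$pos[i] + nchar(v$ref[i]) + (k - 1L) + slack)
    inRegion <- which(v$contig == ct &
        v$pos >= startR &
        v$pos + nchar(v$ref) <= endR)
    nbr <- setdiff(inRegion, i)
    degenerateAll <- FALSE
    if (length(nbr) > 12L) { # dense region: bound the combination blow-up
        d <- abs(v$pos[nbr] - v$pos[i])
        nbr <- nbr[order(d)][seq_len(8L)]
        degenerateAll <- TRUE
    }
    vars <- rbind(v[nbr, , drop = FALSE], v[i, , drop = FALSE])
    vars <- vars[order(vars$pos), , drop = FALSE]
    anchorRow <- match(variantId, vars$variant)
    regionSeq <- substr(seq, startR + 1L, endR)

    m <- nrow(vars) - 1L
    combos <- if (m > 0L) {
        as.matrix(expand.grid(rep(list(0:1), m)))
    } else matrix(integer(0), nrow = 1L, ncol = 0L)

    res <- lapply(offsets, function(o) list(offset = o, kmers = character(0),
        occKey = character(0), occurrences = list(), nHit = 0L))
    names(res) <- as.character(offsets)

    for (ci in seq_len(nrow(combos))) {
        chosen <- integer(nrow(vars))
        if (m > 0L) chosen[-anchorRow] <- combos[ci, ]
        chosen[anchorRow] <- if (allele == "alt") 1L else 0L
        sp <- .spliceRegion(regionSeq, startR, vars, chosen)
        anchorStart <- sp$starts[anchorRow]
        slen <- nchar(sp$seq)
        W <- anchorStart + offsets
        valid <- W >= 0L & W + k <= slen
        if (!any(valid)) next
        Wv <- W[valid]
        ov <- offsets[valid]
        kmers <- substring(sp$seq, Wv + 1L, Wv + k)
        if (grepl("[^ACGT]", sp$seq)) {
            good <- !grepl("[^ACGT]", kmers)
            Wv <- Wv[good]; ov <- ov[good]; kmers <- kmers[good]
            if (!length(Wv)) next
        }
        npc <- length(sp$starts)
        hitm <- matrix(FALSE, length(Wv), npc)
        for (j in seq_len(npc)) {
            s <- sp$starts[j]
            len <- sp$lens[j]
            hitm[, j] <- if (len > 0L) (Wv < s + len) & (Wv + k > s)
                else (Wv < s) & (Wv + k > s)
        }
        for (wi in seq_along(Wv)) {
            hit <- hitm[wi, ]
            key <- paste(kmers[wi], paste(vars$variant[hit], chosen[hit],
                sep = ":", collapse = ","), sep = "|")
            slot <- as.character(ov[wi])
            if (!key %in% res[[slot]]$occKey) {
                res[[slot]]$occKey <- c(res[[slot]]$occKey, key)
                res[[slot]]$occurrences[[length(res[[slot]]$occurrences) +
                    1L]] <- list(kmer = kmers[wi],
                        vars = vars$variant[hit],
                        alleles = chosen[hit])
            }
            res[[slot]]$nHit <- max(res[[slot]]$nHit, sum(hit))
        }
    }
    res <- lapply(res, function(r) {
        r$kmers <- unique(vapply(r$occurrences, `[[`, "", "kmer"))
        r$degenerate <- degenerateAll || length(r$kmers) > maxKmers ||
            r$nHit > 8L
        r$occKey <- NULL
        r$nHit <- NULL
        r
    })
    unname(res[vapply(res, function(r) length(r$kmers) > 0L, TRUE)])
}
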