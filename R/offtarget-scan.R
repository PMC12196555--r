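## Genome-wide off-target screening: enumerate FokI-compatible composite
## patterns (half-site + degenerate spacer + half-site) and scan both
## strands of a genome with a mismatch budget over the half-site positions.

#' Enumerate composite scan patterns for a ZFN pair
#'
#' Composite patterns are built as `a + N^spacer + b`, where each side is
#' one of the two half-sites in either orientation (the half-site as
#' written, or its reverse complement). The default heterodimeric scheme
#' pairs an oriented copy of the left half-site with an oriented copy of
#' the right half-site, in both orders: 2 orientations x 2 orientations x
#' 2 orders = 8 arrangements, which crossed with spacer lengths 4-10 gives
#' 8 x 7 = 56 distinct patterns for two distinct non-palindromic
#' half-sites. This covers the FokI-cleavable tail-to-tail geometry
#' (`revcomp(left) + spacer + right` and its bottom-strand image) together
#' with every other orientation combination a conservative single-strand
#' text screen would enumerate. `includeHomodimers = TRUE` adds the
#' arrangements pairing a half-site with itself (8 more). Exact duplicate
#' composites (possible for palindromic or identical half-sites) are
#' removed.
#'
#' @param left,right 9-nt half-sites (5' to 3' as bound by their arrays).
#' @param spacerRange Integer vector of spacer lengths (default 4:10).
#' @param includeHomodimers Also enumerate left/left and right/right
#'   pairings (default `FALSE`).
#' @return A [S4Vectors::DataFrame] with columns `pattern_id`, `composite`
#'   (with an N-run spacer), `arrangement` (e.g. `"rcL|R"`), `spacer`,
#'   ordered by arrangement label then spacer.
#' @examples
#' nrow(enumeratePatterns("GCTCTACCC", "AGGACGCTT"))  # 56
#' @export
enumeratePatterns <- function(left, right, spacerRange = 4:10,
                              includeHomodimers = FALSE) {
    for (hs in c(left, right))
        if (!grepl("^[ACGT]{9}$", hs))
            stop("half-sites must be exactly 9 nt over A/C/G/T", call. = FALSE)
    if (length(spacerRange) == 0L)
        stop("spacerRange must be non-empty", call. = FALSE)
    spacerRange <- sort(unique(as.integer(spacerRange)))
    if (any(spacerRange < 0L)) stop("spacer lengths must be >= 0", call. = FALSE)
    oriented <- c(L = left, rcL = reverseComplementSeq(left),
                  R = right, rcR = reverseComplementSeq(right))
    unit <- c(L = "left", rcL = "left", R = "right", rcR = "right")
    pairs <- expand.grid(a = names(oriented), b = names(oriented),
                         stringsAsFactors = FALSE)
    hetero <- unit[pairs$a] != unit[pairs$b]
    pairs <- pairs[if (includeHomodimers) TRUE else hetero, , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(pairs))) {
        arr <- paste0(pairs$a[i], "|", pairs$b[i])
        for (s in spacerRange) {
            rows[[length(rows) + 1L]] <- data.frame(
                pattern_id = sprintf("%s_s%d", gsub("\\|", "_", arr), s),
                composite = paste0(oriented[[pairs$a[i]]], strrep("N", s),
                                   oriented[[pairs$b[i]]]),
                arrangement = arr, spacer = s)
        }
    }
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out$composite), , drop = FALSE]
    out <- out[order(out$arrangement, out$spacer), , drop = FALSE]
    rownames(out) <- NULL
    as(out, "DataFrame")
}

## mismatches of a genome window against a composite, counted only over the
## 18 non-N (half-site) positions; genome N never matches a half-site base
.countHalfSiteMismatches <- function(window, composite) {
    w <- strsplit(window, "")[[1L]]
    p <- strsplit(composite, "")[[1L]]
    informative <- p != "N"
    sum(w[informative] != p[informative])
}

#' Scan a genome for composite pattern matches
#'
#' Matches each composite against both strands of every contig. Spacer Ns
#' match any base; mismatches are counted only over the 18 half-site
#' positions, and an ambiguous genome base (N) never matches a half-site
#' position. All matches with at most `maxMismatches` mismatches are
#' reported, overlapping matches included; minus-strand matches are
#' reported in top-strand coordinates with `strand = "-"`.
#'
#' @param genome A `DNAStringSet` (or named character vector) of contigs.
#' @param patterns Output of [enumeratePatterns()] (or any data frame with
#'   `pattern_id`, `composite`, `spacer` columns).
#' @param maxMismatches Mismatch budget over half-site positions
#'   (default 0).
#' @return A `GRanges` of hits with metadata columns `pattern_id`,
#'   `mismatches` and `variation` (percent of the 18 half-site positions
#'   mismatched), sorted by contig, start, strand, pattern_id.
#' @export
scanGenome <- function(genome, patterns, maxMismatches = 0L) {
    if (is.character(genome)) {
        if (is.null(names(genome)))
            names(genome) <- paste0("contig", seq_along(genome))
        genome <- Biostrings::DNAStringSet(toupper(genome))
    }
    if (length(genome) == 0L) stop("genome is empty", call. = FALSE)
    patterns <- as.data.frame(patterns)
    maxMismatches <- as.integer(maxMismatches)
    rows <- list()
    for (ci in seq_along(genome)) {
        contig <- genome[[ci]]
        contigName <- names(genome)[ci]
        for (pi in seq_len(nrow(patterns))) {
            comp <- patterns$composite[pi]
            if (nchar(comp) > length(contig)) next
            for (str in c("+", "-")) {
                pat <- if (str == "+") comp else reverseComplementSeq(comp)
                ## fixed = FALSE: candidate windows are a superset of the
                ## wanted hits (ambiguity codes match liberally); the exact
                ## half-site mismatch count below does the final filtering,
                ## with genome Ns never matching a half-site base
                m <- Biostrings::matchPattern(
                    Biostrings::DNAString(pat), contig,
                    max.mismatch = maxMismatches, fixed = FALSE)
                if (length(m) == 0L) next
                win <- as.character(m)
                mm <- vapply(win, .countHalfSiteMismatches, integer(1),
                             composite = pat, USE.NAMES = FALSE)
                keep <- mm <= maxMismatches
                if (!any(keep)) next
                rows[[length(rows) + 1L]] <- data.frame(
                    contig = contigName,
                    start = BiocGenerics::start(m)[keep],
                    end = BiocGenerics::end(m)[keep],
                    strand = str,
                    pattern_id = patterns$pattern_id[pi],
                    mismatches = mm[keep])
            }
        }
    }
    if (!length(rows)) {
        out <- GRanges()
        mcols(out) <- DataFrame(pattern_id = character(0),
                                mismatches = integer(0),
                                variation = numeric(0))
        return(out)
    }
    hits <- do.call(rbind, rows)
    hits <- hits[order(hits$contig, hits$start, hits$strand,
                       hits$pattern_id), , drop = FALSE]
    gr <- GRanges(hits$contig, IRanges(hits$start, hits$end),
                  strand = hits$strand)
    mcols(gr) <- DataFrame(pattern_id = hits$pattern_id,
                           mismatches = hits$mismatches,
                           variation = variationPercent(hits$mismatches))
    gr
}

#' Percent variation of a hit from the intended target
#'
#' The fraction of the 18 half-site positions that mismatch, as a
#' percentage: `100 * mismatches / 18`. Two mismatches give 11.1%, eight
#' give 44.4%.
#'
#' @param mismatches Integer vector of mismatch counts in 0..18.
#' @return Numeric percentages in \[0, 100\].
#' @examples
#' variationPercent(c(0, 2, 8))
#' @export
variationPercent <- function(mismatches) {
    if (any(!is.finite(mismatches)) || any(mismatches < 0) ||
        any(mismatches > 18))
        stop("mismatches must lie in 0..18", call. = FALSE)
    100 * mismatches / 18
}

#' Extract flanking context around a scan hit
#'
#' Returns the upstream flank, the matched sequence and the downstream
#' flank, oriented to the strand of the hit (for a minus-strand hit all
#' three pieces are reverse-complemented and upstream is taken from the
#' genomic right). With the default 100-nt flanks a mid-contig hit carries
#' 200 nt of combined context. Flanks clipped at a contig edge set the
#' `truncated` flag.
#'
#' @param genome `DNAStringSet` of contigs (or single named character).
#' @param hit A single-row `GRanges` from [scanGenome()].
#' @param flankUp,flankDown Flank lengths in nt (default 100 each).
#' @return List with `upstream`, `match`, `downstream` (character) and
#'   `truncated` (logical).
#' @export
extractContext <- function(genome, hit, flankUp = 100L, flankDown = 100L) {
    if (is.character(genome)) {
        nm <- names(genome)
        genome <- Biostrings::DNAStringSet(toupper(genome))
        names(genome) <- nm
    }
    if (length(hit) != 1L) stop("hit must be a single range", call. = FALSE)
    if (flankUp < 0L || flankDown < 0L)
        stop("flank lengths must be >= 0", call. = FALSE)
    contigName <- as.character(seqnames(hit))
    if (!contigName %in% names(genome))
        stop("hit contig '", contigName, "' not in genome", call. = FALSE)
    contig <- as.character(genome[[contigName]])
    L <- nchar(contig)
    s <- start(hit); e <- end(hit)
    if (s < 1L || e > L) stop("hit lies outside its contig", call. = FALSE)
    str <- as.character(strand(hit))
    if (str == "-") { gUp <- flankDown; gDown <- flankUp }
    else { gUp <- flankUp; gDown <- flankDown }
    upStart <- max(1L, s - gUp)
    downEnd <- min(L, e + gDown)
    truncated <- (s - upStart < gUp) || (downEnd - e < gDown)
    leftFlank <- if (s > 1L) substr(contig, upStart, s - 1L) else ""
    rightFlank <- if (e < L) substr(contig, e + 1L, downEnd) else ""
    matchSeq <- substr(contig, s, e)
    if (str == "-") {
        list(upstream = reverseComplementSeq(rightFlank),
             match = reverseComplementSeq(matchSeq),
             downstream = reverseComplementSeq(leftFlank),
             truncated = truncated)
    } else {
        list(upstream = leftFlank, match = matchSeq,
             downstream = rightFlank, truncated = truncated)
    }
}

#' Write scan hits to BED6 (and optional context FASTA)
#'
#' BED records are 0-based half-open (conversion handled by
#' [rtracklayer::export()]), with `name` = pattern id and `score` = the
#' mismatch count. When `genome` is supplied a companion FASTA of flanking
#' contexts is written with headers `contig:start-end:strand:pattern_id`
#' (1-based inclusive coordinates in the header) and sequence
#' `upstream + match + downstream`.
#'
#' @param hits `GRanges` from [scanGenome()].
#' @param bedPath Output BED path.
#' @param genome Optional `DNAStringSet` for context extraction.
#' @param fastaPath Output FASTA path (required when `genome` is given).
#' @param flankUp,flankDown Context flank lengths (nt).
#' @return `bedPath`, invisibly.
#' @export
writeHits <- function(hits, bedPath, genome = NULL, fastaPath = NULL,
                      flankUp = 100L, flankDown = 100L) {
    stopifnot(is(hits, "GRanges"))
    gr <- hits
    mcols(gr) <- DataFrame(name = hits$pattern_id, score = hits$mismatches)
    rtracklayer::export(gr, bedPath, format = "BED")
    if (!is.null(genome)) {
        if (is.null(fastaPath))
            stop("fastaPath is required when genome is supplied", call. = FALSE)
        seqs <- character(length(hits))
        hdrs <- character(length(hits))
        for (i in seq_along(hits)) {
            ctx <- extractContext(genome, hits[i], flankUp, flankDown)
            seqs[i] <- paste0(ctx$upstream, ctx$match, ctx$downstream)
            hdrs[i] <- sprintf("%s:%d-%d:%s:%s",
                               as.character(seqnames(hits[i])),
                               start(hits[i]), end(hits[i]),
                               as.character(strand(hits[i])),
                               hits[i]$pattern_id)
        }
        out <- Biostrings::DNAStringSet(seqs)
        names(out) <- hdrs
        Biostrings::writeXStringSet(out, fastaPath)
    }
    invisible(bedPath)
}
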