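## Independent oracles and small fixture builders used across the suite.
## These deliberately re-derive results by brute force, staying independent
## of the package's own code paths.

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## plain character-level reverse complement (independent of Biostrings)
oracleRevComp <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]), collapse = "")
}

## Brute-force all-offsets scan of one contig, both strands. Counts
## mismatches over the non-N pattern positions; a genome N never matches a
## half-site base. Returns a data.frame(start, end, strand, mismatches).
oracleScanContig <- function(contig, composite, maxMismatches) {
    g <- strsplit(contig, "")[[1L]]
    out <- list()
    for (str in c("+", "-")) {
        pat <- if (str == "+") composite else oracleRevComp(composite)
        p <- strsplit(pat, "")[[1L]]
        I <- which(p != "N")
        Lp <- length(p)
        nOff <- length(g) - Lp + 1L
        if (nOff < 1L) next
        idx <- outer(seq_len(nOff) - 1L, I, "+")
        mm <- rowSums(matrix(g[idx] != rep(p[I], each = nOff), nrow = nOff))
        hit <- which(mm <= maxMismatches)
        if (length(hit))
            out[[length(out) + 1L]] <- data.frame(
                start = hit, end = hit + Lp - 1L, strand = str,
                mismatches = mm[hit])
    }
    if (!length(out))
        return(data.frame(start = integer(0), end = integer(0),
                          strand = character(0), mismatches = integer(0)))
    do.call(rbind, out)
}

## Gotoh affine-gap global alignment score (quadratic DP, score only).
## A length-L gap costs gapOpen + L * gapExtend.
oracleAlignScore <- function(ref, alt, match = 2, mismatch = -1,
                             gapOpen = -4, gapExtend = -1) {
    r <- strsplit(ref, "")[[1L]]
    a <- strsplit(alt, "")[[1L]]
    n <- length(r); m <- length(a)
    NEG <- -1e9
    M <- matrix(NEG, n + 1L, m + 1L)
    Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in alt (consumes ref)
    Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in ref (consumes alt)
    M[1L, 1L] <- 0
    for (i in seq_len(n)) Ix[i + 1L, 1L] <- gapOpen + i * gapExtend
    for (j in seq_len(m)) Iy[1L, j + 1L] <- gapOpen + j * gapExtend
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- if (r[i] == a[j]) match else mismatch
            M[i + 1L, j + 1L] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
            Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] + gapOpen + gapExtend,
                                      Ix[i, j + 1L] + gapExtend)
            Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] + gapOpen + gapExtend,
                                      Iy[i + 1L, j] + gapExtend)
        }
    }
    max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

## Exhaustive reverse-translation optimum: best CAI over every synonymous
## codon assignment whose construct (flank5 + core + flank3) is free of
## forbidden-motif occurrences (either strand) overlapping the core.
## Returns -Inf when no assignment is feasible. Proteins must be short.
oracleBestCai <- function(protein, table, forbiddenMotifs,
                          flank5, flank3) {
    w <- relativeAdaptiveness(table)
    gc <- Biostrings::GENETIC_CODE
    aaOf <- gc[names(w)]
    residues <- strsplit(protein, "")[[1L]]
    fams <- lapply(residues, function(a) names(w)[aaOf == a])
    combos <- expand.grid(fams, stringsAsFactors = FALSE)
    motifs <- unique(c(forbiddenMotifs,
                       vapply(forbiddenMotifs, oracleRevComp, character(1))))
    best <- -Inf
    for (i in seq_len(nrow(combos))) {
        core <- paste(unlist(combos[i, ]), collapse = "")
        full <- paste0(flank5, core, flank3)
        coreStart <- nchar(flank5) + 1L
        coreEnd <- coreStart + nchar(core) - 1L
        bad <- FALSE
        for (mo in motifs) {
            p <- gregexpr(paste0("(?=", mo, ")"), full, perl = TRUE)[[1L]]
            if (p[1L] == -1L) next
            if (any(p + nchar(mo) - 1L >= coreStart & p <= coreEnd)) {
                bad <- TRUE; break
            }
        }
        if (bad) next
        best <- max(best, computeCai(core, table))
    }
    best
}

## two-isoform toy gene model on one contig
toyGeneModel <- function() {
    isoA <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(10, 100, 300), end = c(50, 200, 400)))
    isoB <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(100, 300), end = c(200, 400)))
    GeneModel("g1", "+", list(A = isoA, B = isoB),
              paste0("ATG", strrep("GCT", 80)))
}
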