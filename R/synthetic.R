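## Deterministic synthetic-fixture generators: genomes with planted
## (optionally corrupted) composite target sites, coding sequences, and
## mutant clone sets drawn from a configured mutation spectrum. Every
## generator returns a machine-readable truth table alongside the
## sequences, so downstream results can be checked without re-derivation.

## deterministic base corruption: rotate A->C->G->T->A
.corruptBase <- function(b) {
    c(A = "C", C = "G", G = "T", T = "A", N = "A")[[b]]
}

## composite position indices of the 18 half-site positions
.halfSitePositions <- function(composite) {
    which(strsplit(composite, "")[[1L]] != "N")
}

#' Generate a synthetic genome with planted target sites
#'
#' Draws a uniform-composition background (no GC or repeat structure) from
#' a seeded generator and writes composite sites at requested offsets.
#' Spacer Ns in a composite are filled with random bases; requested
#' half-site positions (1-18, numbered over the two half-sites 5' to 3' of
#' the composite) are corrupted deterministically so the planted mismatch
#' count is exact. Minus-strand plants are written as the reverse
#' complement of the realised site.
#'
#' @param length Genome length in nt.
#' @param plants `data.frame` with columns `composite` (pattern string,
#'   N-run spacer allowed), `offset` (1-based start), `strand` (`"+"` or
#'   `"-"`), and optionally `mismatch_positions` (list column of integer
#'   vectors in 1..18). Planted sites must fit without overlapping.
#' @param seed Integer seed; identical inputs and seed give a byte-identical
#'   genome.
#' @param contigName Name for the single contig (default "chr1").
#' @return List with `genome` (length-1 `DNAStringSet`) and `truth`
#'   (`data.frame`: contig, start, end, strand, composite, mismatches).
#' @export
makeSyntheticGenome <- function(length, plants = NULL, seed = 1L,
                                contigName = "chr1") {
    set.seed(as.integer(seed))
    bases <- c("A", "C", "G", "T")
    bg <- sample(bases, length, replace = TRUE)
    truth <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        composite = character(0), mismatches = integer(0))
    if (!is.null(plants) && nrow(plants)) {
        if (is.null(plants$mismatch_positions))
            plants$mismatch_positions <- replicate(nrow(plants), integer(0),
                                                   simplify = FALSE)
        iv <- cbind(plants$offset,
                    plants$offset + nchar(plants$composite) - 1L)
        if (any(iv[, 1] < 1L) || any(iv[, 2] > length))
            stop("planted site out of genome bounds", call. = FALSE)
        o <- order(iv[, 1])
        if (nrow(iv) > 1L && any(iv[o, 1][-1L] <= iv[o, 2][-nrow(iv)]))
            stop("planted sites overlap", call. = FALSE)
        for (i in seq_len(nrow(plants))) {
            comp <- toupper(plants$composite[i])
            chars <- strsplit(comp, "")[[1L]]
            hsPos <- .halfSitePositions(comp)
            if (length(hsPos) != 18L)
                stop("composite must have 18 half-site positions", call. = FALSE)
            chars[chars == "N"] <- sample(bases, sum(chars == "N"),
                                          replace = TRUE)
            mmPos <- plants$mismatch_positions[[i]]
            if (length(mmPos)) {
                if (any(mmPos < 1L) || any(mmPos > 18L))
                    stop("mismatch positions must lie in 1..18", call. = FALSE)
                idx <- hsPos[mmPos]
                chars[idx] <- vapply(chars[idx], .corruptBase, character(1))
            }
            realised <- paste(chars, collapse = "")
            if (plants$strand[i] == "-")
                realised <- reverseComplementSeq(realised)
            s <- plants$offset[i]; e <- s + nchar(comp) - 1L
            bg[s:e] <- strsplit(realised, "")[[1L]]
            truth <- rbind(truth, data.frame(
                contig = contigName, start = s, end = e,
                strand = plants$strand[i], composite = comp,
                mismatches = length(unique(mmPos))))
        }
    }
    genome <- Biostrings::DNAStringSet(paste(bg, collapse = ""))
    names(genome) <- contigName
    list(genome = genome, truth = truth)
}

#' Generate a synthetic coding sequence
#'
#' ATG followed by random sense (non-stop) codons and a terminal TAA,
#' drawn from a seeded generator.
#'
#' @param nCodons Number of codons including the start but not the stop.
#' @param seed Integer seed.
#' @param stopCodon Append a terminal stop codon (default TRUE).
#' @return Nucleotide string of length `3 * nCodons (+ 3)`.
#' @export
makeSyntheticCds <- function(nCodons = 330L, seed = 1L, stopCodon = TRUE) {
    if (nCodons < 1L) stop("nCodons must be >= 1", call. = FALSE)
    set.seed(as.integer(seed))
    body <- sample(setdiff(.SENSE_CODONS, "ATG"), nCodons - 1L,
                   replace = TRUE)
    paste0("ATG", paste(body, collapse = ""), if (stopCodon) "TAA" else "")
}

#' Generate a mutant clone set with a configured mutation spectrum
#'
#' Each clone carries one primary edit: with probability `pSnv` a
#' single-base substitution, with `pIndel` an insertion or deletion (equal
#' odds, length drawn from `indelLengths` with `indelLengthProbs`), with
#' `pComplex` a mixed run (a substitution immediately followed by a
#' deletion). Edit positions are uniform over the supplied CDS windows,
#' emulating a nuclease cut-site window plus a repair hotspot. The defaults
#' (51.5% SNV / 39.4% indel / 9.1% complex, windows 689-713 and 873-935)
#' reproduce the spectrum and hotspot geometry of a ZFN-mutagenised
#' single-copy plant gene; see the package vignette.
#'
#' @param cds Reference coding sequence; must contain all windows with
#'   room for the longest edit.
#' @param n Number of clones.
#' @param pSnv,pIndel,pComplex Category proportions, summing to 1.
#' @param indelLengths,indelLengthProbs Indel length distribution.
#' @param windows List of `c(start, end)` CDS windows for edit positions.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return List with `clones` (named character vector of mutant sequences)
#'   and `truth` (`data.frame`: clone, category, pos, ref, alt, net_indel,
#'   frameshift, class).
#' @export
makeMutantClones <- function(cds, n,
                             pSnv = 0.515, pIndel = 0.394, pComplex = 0.091,
                             indelLengths = c(1L, 2L, 3L),
                             indelLengthProbs = c(0.6, 0.25, 0.15),
                             windows = list(c(689L, 713L), c(873L, 935L)),
                             seed = 1L) {
    .assertScalarString(cds, "cds")
    cds <- toupper(cds)
    if (n < 1L) stop("n must be >= 1", call. = FALSE)
    p <- c(pSnv, pIndel, pComplex)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
        stop("category proportions must be non-negative and sum to 1",
             call. = FALSE)
    maxLen <- max(indelLengths)
    positions <- unlist(lapply(windows, function(w) {
        if (w[1] < 1L || w[2] + maxLen + 1L > nchar(cds))
            stop("window ", w[1], "-", w[2],
                 " (plus indel headroom) outside the cds", call. = FALSE)
        seq.int(w[1], w[2])
    }))
    set.seed(as.integer(seed))
    bases <- c("A", "C", "G", "T")
    clones <- character(n)
    rows <- vector("list", n)
    refProtein <- .translateDna(cds)
    for (i in seq_len(n)) {
        category <- sample(c("SNV", "indel", "complex"), 1L, prob = p)
        pos <- sample(positions, 1L)
        if (category == "SNV") {
            refA <- substr(cds, pos, pos)
            altA <- sample(setdiff(bases, refA), 1L)
            mut <- paste0(substr(cds, 1L, pos - 1L), altA,
                          substr(cds, pos + 1L, nchar(cds)))
            net <- 0L
        } else if (category == "indel") {
            len <- sample(indelLengths, 1L, prob = indelLengthProbs)
            if (stats::runif(1) < 0.5) {  # insertion after pos
                refA <- ""
                altA <- paste(sample(bases, len, replace = TRUE),
                              collapse = "")
                mut <- paste0(substr(cds, 1L, pos), altA,
                              substr(cds, pos + 1L, nchar(cds)))
                net <- len
            } else {                      # deletion of [pos, pos+len-1]
                refA <- substr(cds, pos, pos + len - 1L)
                altA <- ""
                mut <- paste0(substr(cds, 1L, pos - 1L),
                              substr(cds, pos + len, nchar(cds)))
                net <- -len
            }
        } else {
            ## complex: replace 3 reference bases with 1 substituted base
            ## (a substitution fused to a 2-nt deletion). The construction
            ## must not be reducible to a simpler edit, or the mixed run
            ## would legitimately be called as an SNV or pure deletion:
            ## resample the position until the base after the run differs
            ## from the base at pos+1 (no run-splitting realignment), and
            ## pick the substituted base to differ from ref[pos] and
            ## ref[pos+2] (no pure-deletion equivalence).
            while (substr(cds, pos + 1L, pos + 1L) ==
                   substr(cds, pos + 3L, pos + 3L))
                pos <- sample(positions, 1L)
            refA <- substr(cds, pos, pos + 2L)
            altA <- sample(setdiff(bases, c(substr(cds, pos, pos),
                                            substr(cds, pos + 2L, pos + 2L))),
                           1L)
            mut <- paste0(substr(cds, 1L, pos - 1L), altA,
                          substr(cds, pos + 3L, nchar(cds)))
            net <- -2L
        }
        frameshift <- (net %% 3L) != 0L
        mutProtein <- .translateDna(mut)
        mutStop <- regexpr("*", mutProtein, fixed = TRUE)
        lof <- mutStop > 0L && mutStop < nchar(mutProtein)
        class <- if (lof) "loss_of_function"
            else if (frameshift) "frameshift"
            else if (category != "SNV") "in_frame_indel"
            else if (sub("\\*.*$", "", mutProtein) ==
                     sub("\\*.*$", "", refProtein)) "synonymous"
            else "missense"
        clones[i] <- mut
        rows[[i]] <- data.frame(
            clone = sprintf("clone%04d", i), category = category,
            pos = pos, ref = refA, alt = altA, net_indel = net,
            frameshift = frameshift, class = class)
    }
    names(clones) <- sprintf("clone%04d", seq_len(n))
    list(clones = clones, truth = do.call(rbind, rows))
}
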