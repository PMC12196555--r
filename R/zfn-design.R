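## Zinc-finger nuclease pair design: half-site selection on a CDS, assembly
## of three-finger ZFP amino-acid sequences from recognition helices, and
## CAI-driven reverse translation under restriction-site constraints.

## ---------------------------------------------------------------------------
## Recognition-helix table and assembly grammar
## ---------------------------------------------------------------------------

#' Default recognition-helix table
#'
#' The seeded triplet-to-helix assignments covering the two half-sites of
#' the reference design (left 5'-GCTCTACCC-3', right 5'-AGGACGCTT-3'). Each
#' 3-bp triplet maps to the 7-residue recognition helix of one zinc finger.
#' Additional assignments are supplied through a two-column tab-delimited
#' file, see [readHelixTable()].
#'
#' @return Named character vector, `names` = DNA triplets, values = 7-aa
#'   helices.
#' @examples
#' defaultHelixTable()
#' @export
defaultHelixTable <- function() {
    c(GCT = "TSGELVR", CTA = "QNSTLTE", CCC = "SKKHLAE",
      CTT = "TTGALTE", ACG = "RTDTLRD", AGG = "RSDHLTN")
}

#' Read a recognition-helix table
#'
#' Two tab-delimited columns: TRIPLET (3 nt) and HELIX (7 aa). A header line
#' is tolerated when its first field is not a valid triplet.
#'
#' @param path Path to the table.
#' @return Named character vector as in [defaultHelixTable()].
#' @export
readHelixTable <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("triplet", "helix"))
    if (nrow(tab) && !grepl("^[ACGT]{3}$", tab$triplet[1L]))
        tab <- tab[-1L, , drop = FALSE]
    tab$triplet <- toupper(tab$triplet)
    tab$helix <- toupper(tab$helix)
    if (any(!grepl("^[ACGT]{3}$", tab$triplet)))
        stop("invalid triplet(s) in helix table: ",
             paste(tab$triplet[!grepl("^[ACGT]{3}$", tab$triplet)],
                   collapse = ", "), call. = FALSE)
    if (any(nchar(tab$helix) != 7L))
        stop("recognition helices must be exactly 7 residues", call. = FALSE)
    if (anyDuplicated(tab$triplet))
        stop("duplicate triplets in helix table", call. = FALSE)
    stats::setNames(tab$helix, tab$triplet)
}

#' Zinc-finger assembly grammar
#'
#' The constant segments flanking and linking the recognition helices of a
#' three-finger array: an N-terminal cloning sequence, the conserved finger
#' backbone before and after each helix, the canonical inter-finger linker,
#' and a C-terminal cloning sequence. With three 7-residue helices the
#' assembled array is always 7 + 3*(11+7+5) + 2*5 + 6 = 92 residues.
#'
#' @param n_terminus,backbone_n,backbone_c,linker,c_terminus Explicit
#'   overrides for any constant.
#' @return Named list of grammar constants.
#' @export
zfAssemblyGrammar <- function(n_terminus = "LEPGEKP",
                              backbone_n = "YKCPECGKSFS",
                              backbone_c = "HQRTH",
                              linker = "TGEKP",
                              c_terminus = "TGKKTS") {
    list(n_terminus = n_terminus, backbone_n = backbone_n,
         backbone_c = backbone_c, linker = linker, c_terminus = c_terminus)
}

.halfSiteTriplets <- function(halfSite) {
    if (!grepl("^[ACGT]{9}$", halfSite))
        stop("half-site must be exactly 9 nt over A/C/G/T: ", halfSite,
             call. = FALSE)
    substring(halfSite, c(1L, 4L, 7L), c(3L, 6L, 9L))
}

#' Assemble a three-finger zinc-finger protein from a half-site
#'
#' Decomposes a 9-bp half-site into its three triplets, looks up the
#' recognition helix for each, and concatenates grammar constants and
#' helices into the full array:
#' `n_terminus + [backbone_n + helix + backbone_c]` for fingers F1..F3
#' joined by `linker`, closed by `c_terminus`.
#'
#' Finger order is a convention choice: `"five_prime"` assigns F1 the
#' 5'-most triplet of the half-site as written, `"three_prime"` assigns F1
#' the 3'-most triplet (the antiparallel structural convention). Both
#' conventions appear in the literature; see the package vignette.
#'
#' @param halfSite 9-nt half-site sequence (5' to 3' as bound by the array).
#' @param helixTable Named character vector of triplet -> 7-aa helix.
#' @param grammar Assembly constants, see [zfAssemblyGrammar()].
#' @param fingerOrder `"five_prime"` or `"three_prime"`.
#' @return 92-character amino-acid string.
#' @examples
#' assembleZfp("GCTCTACCC", fingerOrder = "five_prime")
#' @export
assembleZfp <- function(halfSite, helixTable = defaultHelixTable(),
                        grammar = zfAssemblyGrammar(),
                        fingerOrder = c("five_prime", "three_prime")) {
    fingerOrder <- match.arg(fingerOrder)
    triplets <- .halfSiteTriplets(halfSite)
    if (fingerOrder == "three_prime") triplets <- rev(triplets)
    missing <- setdiff(triplets, names(helixTable))
    if (length(missing))
        stop("no recognition helix for triplet(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    fingers <- paste0(grammar$backbone_n, helixTable[triplets],
                      grammar$backbone_c)
    paste0(grammar$n_terminus,
           paste(fingers, collapse = grammar$linker),
           grammar$c_terminus)
}

## ---------------------------------------------------------------------------
## Half-site pair selection
## ---------------------------------------------------------------------------

#' Enumerate candidate ZFN half-site pairs on a sequence
#'
#' A candidate paired target site on the top strand reads
#' `revcomp(left half-site) + spacer + right half-site`: the left array
#' binds the bottom strand, the right array the top strand, in the
#' tail-to-tail geometry that lets the two FokI domains dimerise over the
#' spacer. A candidate is reported only when all six triplets of both
#' half-sites have recognition helices in `helixTable`.
#'
#' @param seq Nucleotide string to search (typically a CDS or exon).
#' @param spacerRange Integer vector of admissible spacer lengths (nt).
#' @param helixTable Triplet -> helix map; see [defaultHelixTable()].
#' @return A [S4Vectors::DataFrame] with columns `start` (1-based position
#'   of the site on `seq`), `end`, `spacer`, `left`, `right` (half-sites,
#'   5' to 3' as bound), ordered by ascending `start` then smaller spacer.
#' @examples
#' selectHalfSitePairs(paste0("GGGTAGAGC", "ACGTACG", "AGGACGCTT"),
#'                     spacerRange = 5:7)
#' @export
selectHalfSitePairs <- function(seq, spacerRange = 4:10,
                                helixTable = defaultHelixTable()) {
    .assertScalarString(seq, "seq")
    seq <- toupper(seq)
    .checkDnaAlphabet(seq, allowN = TRUE)
    if (length(spacerRange) == 0L)
        stop("spacerRange must be non-empty", call. = FALSE)
    spacerRange <- sort(unique(as.integer(spacerRange)))
    n <- nchar(seq)
    known <- names(helixTable)
    rows <- list()
    for (i in seq_len(max(0L, n - 18L - min(spacerRange) + 1L))) {
        for (s in spacerRange) {
            e <- i + 17L + s
            if (e > n) next
            bottom9 <- substr(seq, i, i + 8L)
            right <- substr(seq, i + 9L + s, e)
            if (grepl("N", bottom9, fixed = TRUE) ||
                grepl("N", right, fixed = TRUE)) next
            left <- reverseComplementSeq(bottom9)
            trip <- c(.halfSiteTriplets(left), .halfSiteTriplets(right))
            if (!all(trip %in% known)) next
            rows[[length(rows) + 1L]] <-
                data.frame(start = i, end = e, spacer = s,
                           left = left, right = right)
        }
    }
    if (!length(rows))
        return(DataFrame(start = integer(0), end = integer(0),
                         spacer = integer(0), left = character(0),
                         right = character(0)))
    out <- do.call(rbind, rows)
    out <- out[order(out$start, out$spacer), , drop = FALSE]
    rownames(out) <- NULL
    as(out, "DataFrame")
}

## ---------------------------------------------------------------------------
## Codon usage and CAI
## ---------------------------------------------------------------------------

#' Codon usage table with relative adaptiveness
#'
#' Wraps a codon -> usage-frequency map and derives each sense codon's
#' relative adaptiveness `w = frequency / max frequency among synonymous
#' codons` (Sharp & Li). Codons absent from the input (or with zero
#' frequency) receive a pseudo-count of 0.5 before `w` is computed, so
#' `0 < w <= 1` always holds and every amino acid has a codon with `w = 1`.
#' Input frequencies may be counts, fractions or per-thousand values; `w`
#' is invariant to the scale.
#'
#' @slot frequency Named numeric, usage per sense codon (pseudo-counted).
#' @slot w Named numeric, relative adaptiveness per sense codon.
#' @export
setClass("CodonUsageTable",
    representation(frequency = "numeric", w = "numeric"))

setValidity("CodonUsageTable", function(object) {
    msg <- character(0)
    if (!setequal(names(object@w), .SENSE_CODONS))
        msg <- c(msg, "w must cover exactly the 61 sense codons")
    if (any(object@w <= 0) || any(object@w > 1 + 1e-12))
        msg <- c(msg, "w must lie in (0, 1]")
    aa <- .codonToAa(names(object@w))
    top <- tapply(object@w, aa, max)
    if (any(abs(top - 1) > 1e-9))
        msg <- c(msg, "each amino acid needs a codon with w = 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn CodonUsageTable Constructor from a named frequency vector
#'   (names = codons; `U` accepted for `T`; stop codons ignored).
#' @param frequency Named numeric vector of codon usage values.
#' @export
codonUsageTable <- function(frequency) {
    if (is.null(names(frequency)))
        stop("frequency must be named by codon", call. = FALSE)
    codons <- chartr("Uu", "Tt", toupper(names(frequency)))
    if (any(!grepl("^[ACGT]{3}$", codons)))
        stop("invalid codon name(s): ",
             paste(codons[!grepl("^[ACGT]{3}$", codons)], collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(codons)) stop("duplicate codons", call. = FALSE)
    f <- stats::setNames(rep(0, length(.SENSE_CODONS)), .SENSE_CODONS)
    keep <- codons %in% .SENSE_CODONS
    f[codons[keep]] <- as.numeric(frequency[keep])
    if (any(f < 0)) stop("frequencies must be non-negative", call. = FALSE)
    f[f == 0] <- 0.5  # pseudo-count, avoids zero geometric means
    aa <- .codonToAa(names(f))
    w <- f / stats::ave(f, aa, FUN = max)
    new("CodonUsageTable", frequency = f, w = w)
}

#' @describeIn CodonUsageTable Relative-adaptiveness accessor.
#' @param x,object A `CodonUsageTable`.
#' @export
setGeneric("relativeAdaptiveness", function(x)
    standardGeneric("relativeAdaptiveness"))

#' @rdname CodonUsageTable
#' @export
setMethod("relativeAdaptiveness", "CodonUsageTable", function(x) x@w)

#' @describeIn CodonUsageTable Frequency accessor.
#' @export
setGeneric("codonFrequencies", function(x) standardGeneric("codonFrequencies"))

#' @rdname CodonUsageTable
#' @export
setMethod("codonFrequencies", "CodonUsageTable", function(x) x@frequency)

setMethod("show", "CodonUsageTable", function(object) {
    cat("CodonUsageTable over", length(object@w), "sense codons;",
        sum(abs(object@w - 1) < 1e-9), "codons at w = 1\n")
})

#' Read a codon usage table
#'
#' Two tab-delimited columns: CODON and FREQUENCY (counts, fractions or
#' per-thousand; auto-normalised). A header line is tolerated.
#'
#' @param path Path to the table.
#' @return A [CodonUsageTable].
#' @export
readCodonUsage <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("codon", "freq"))
    if (nrow(tab) && !grepl("^[ACGTUacgtu]{3}$", tab$codon[1L]))
        tab <- tab[-1L, , drop = FALSE]
    codonUsageTable(stats::setNames(as.numeric(tab$freq), tab$codon))
}

#' Synthetic codon usage table
#'
#' A deterministic, synthetic usage table for demonstrations and tests when
#' no organism-specific table is supplied: within each synonymous family the
#' alphabetically ordered codons receive geometrically decaying usage
#' (1, 1/2, 1/4, ...), giving a strongly biased but arbitrary profile. It
#' does not represent any real genome.
#'
#' @return A [CodonUsageTable].
#' @export
syntheticCodonUsage <- function() {
    aa <- .codonToAa(.SENSE_CODONS)
    f <- numeric(length(.SENSE_CODONS))
    names(f) <- .SENSE_CODONS
    for (a in unique(aa)) {
        fam <- sort(.SENSE_CODONS[aa == a])
        f[fam] <- 1000 * 0.5^(seq_along(fam) - 1L)
    }
    codonUsageTable(f)
}

#' Codon Adaptation Index of a coding sequence
#'
#' Standard CAI (Sharp & Li): the geometric mean of the relative
#' adaptiveness `w` of each codon, taken over sense codons excluding the
#' single-codon amino acids Met (ATG) and Trp (TGG) and any terminal stop
#' codon. A sequence using each amino acid's most-used codon throughout
#' scores 1.
#'
#' @param cds Nucleotide string, length divisible by 3, no internal stop.
#' @param table A [CodonUsageTable].
#' @return CAI in (0, 1]; 1 when no non-exempt codon remains.
#' @examples
#' computeCai("ATGGCTGCT", syntheticCodonUsage())
#' @export
computeCai <- function(cds, table) {
    stopifnot(is(table, "CodonUsageTable"))
    .assertScalarString(cds, "cds")
    cds <- toupper(cds)
    .checkDnaAlphabet(cds, allowN = FALSE, what = "cds")
    codons <- .splitCodons(cds)
    if (length(codons) && codons[length(codons)] %in% .STOP_CODONS)
        codons <- codons[-length(codons)]
    if (any(codons %in% .STOP_CODONS))
        stop("internal stop codon in cds", call. = FALSE)
    codons <- codons[!codons %in% c("ATG", "TGG")]
    if (!length(codons)) return(1)
    exp(mean(log(table@w[codons])))
}

## ---------------------------------------------------------------------------
## Reverse translation with CAI optimisation and motif avoidance
## ---------------------------------------------------------------------------

## synonymous codons per amino acid, ordered by decreasing w then codon
.codonChoices <- function(table) {
    aa <- .codonToAa(names(table@w))
    lapply(split(names(table@w), aa), function(cod) {
        w <- table@w[cod]
        cod[order(-w, cod)]
    })
}

## all (start, end) spans where any forbidden motif (either strand) occurs
.motifHits <- function(seq, motifs) {
    hits <- list()
    for (m in unique(c(motifs, reverseComplementSeq(motifs)))) {
        p <- gregexpr(paste0("(?=", m, ")"), seq, perl = TRUE)[[1L]]
        if (p[1L] != -1L)
            hits[[length(hits) + 1L]] <-
                cbind(start = as.integer(p), end = as.integer(p) + nchar(m) - 1L)
    }
    if (!length(hits)) return(matrix(integer(0), ncol = 2,
                                     dimnames = list(NULL, c("start", "end"))))
    do.call(rbind, hits)
}

#' Reverse-translate a protein with CAI optimisation under motif constraints
#'
#' Builds a coding sequence for `protein` by a greedy per-codon choice of
#' the highest-`w` synonymous codon, then repairs occurrences of forbidden
#' motifs (checked on both strands, in the context of the flanking cloning
#' sites) by re-choosing codons in a local window around each violation,
#' preferring the highest-CAI motif-free combination; ties break on
#' alphabetical codon order, so the result is deterministic. Motif
#' occurrences lying entirely inside a flank (the cloning sites themselves)
#' are permitted; occurrences overlapping the coding region are not.
#'
#' The default forbidden motifs and flanks are the XbaI (TCTAGA) and BamHI
#' (GGATCC) recognition sites, so the optimised fragment can be subcloned
#' by XbaI/BamHI digestion without internal re-cutting.
#'
#' @param protein Amino-acid string over the 20 standard residues.
#' @param table A [CodonUsageTable].
#' @param forbiddenMotifs Nucleotide motifs that must not occur in the
#'   coding region on either strand.
#' @param flank5,flank3 Sequences prepended/appended to the coding region
#'   in the returned construct (use `""` for none).
#' @param repairBudget Maximum number of repair iterations before giving up.
#' @return List with `coding` (the optimised CDS; translates exactly to
#'   `protein`), `construct` (`flank5 + coding + flank3`) and `cai` (CAI of
#'   `coding` under `table`).
#' @examples
#' reverseTranslateOptimize("MDELV", syntheticCodonUsage())$coding
#' @export
reverseTranslateOptimize <- function(protein, table,
                                     forbiddenMotifs = c("TCTAGA", "GGATCC"),
                                     flank5 = "TCTAGA", flank3 = "GGATCC",
                                     repairBudget = 200L) {
    stopifnot(is(table, "CodonUsageTable"))
    .assertScalarString(protein, "protein")
    protein <- toupper(protein)
    if (nchar(protein) == 0L) stop("protein must be non-empty", call. = FALSE)
    residues <- strsplit(protein, "")[[1L]]
    choices <- .codonChoices(table)
    bad <- setdiff(residues, names(choices))
    if (length(bad))
        stop("unknown amino acid(s): ", paste(unique(bad), collapse = ", "),
             call. = FALSE)
    codons <- vapply(residues, function(a) choices[[a]][1L], character(1))

    coreStart <- nchar(flank5) + 1L
    violations <- function(codons) {
        core <- paste(codons, collapse = "")
        full <- paste0(flank5, core, flank3)
        hit <- .motifHits(full, forbiddenMotifs)
        coreEnd <- coreStart + nchar(core) - 1L
        hit[hit[, "end"] >= coreStart & hit[, "start"] <= coreEnd, ,
            drop = FALSE]
    }

    tries <- 0L
    repeat {
        v <- violations(codons)
        if (nrow(v) == 0L) break
        tries <- tries + 1L
        if (tries > repairBudget)
            stop("motif repair budget exhausted near nucleotides ",
                 v[1L, "start"] - coreStart + 1L, "-",
                 v[1L, "end"] - coreStart + 1L, " of the coding region",
                 call. = FALSE)
        ## codon indices overlapping the first (leftmost) violation
        s <- max(v[1L, "start"], coreStart) - coreStart + 1L
        e <- min(v[1L, "end"], coreStart + 3L * length(codons) - 1L) -
            coreStart + 1L
        win <- unique(((s - 1L) %/% 3L + 1L):((e - 1L) %/% 3L + 1L))
        repaired <- FALSE
        for (widen in 0:1) {
            w2 <- unique(pmax(1L, pmin(length(codons),
                                       c(min(win) - widen, win, max(win) + widen))))
            w2 <- sort(w2)
            combos <- expand.grid(lapply(w2, function(i)
                choices[[residues[i]]]), stringsAsFactors = FALSE)
            score <- apply(combos, 1L, function(row)
                sum(log(table@w[unlist(row)])))
            key <- apply(combos, 1L, paste, collapse = "")
            combos <- combos[order(-score, key), , drop = FALSE]
            for (r in seq_len(nrow(combos))) {
                cand <- codons
                cand[w2] <- as.character(combos[r, ])
                ## accept the first combo that clears this window without
                ## leaving a violation overlapping it
                vv <- violations(cand)
                winSpan <- c(coreStart + 3L * (min(w2) - 1L),
                             coreStart + 3L * max(w2) - 1L)
                still <- nrow(vv) > 0L &&
                    any(vv[, "end"] >= winSpan[1L] & vv[, "start"] <= winSpan[2L])
                if (!still) {
                    codons <- cand
                    repaired <- TRUE
                    break
                }
            }
            if (repaired) break
        }
        if (!repaired)
            stop("no motif-free synonymous assignment found for codons ",
                 min(win), "-", max(win), call. = FALSE)
    }
    core <- paste(codons, collapse = "")
    list(coding = core,
         construct = paste0(flank5, core, flank3),
         cai = computeCai(core, table))
}

## ---------------------------------------------------------------------------
## ZFNDesign
## ---------------------------------------------------------------------------

#' A designed ZFN pair
#'
#' Bundles a paired target site (two 9-bp half-sites separated by a spacer)
#' with the two assembled zinc-finger protein sequences and their optimised
#' coding sequences. Constructed with [designZfnPair()].
#'
#' @slot left,right 9-nt half-site sequences (5' to 3' as bound).
#' @slot spacerLength Spacer length in nt.
#' @slot proteins `AAStringSet` of the two 92-aa arrays (names "left",
#'   "right").
#' @slot cds `DNAStringSet` of the optimised coding sequences.
#' @slot cai Numeric CAI of each coding sequence.
#' @export
setClass("ZFNDesign",
    representation(left = "character", right = "character",
                   spacerLength = "integer", proteins = "ANY",
                   cds = "ANY", cai = "numeric"))

setValidity("ZFNDesign", function(object) {
    msg <- character(0)
    if (nchar(object@left) != 9L || nchar(object@right) != 9L)
        msg <- c(msg, "half-sites must be 9 nt")
    if (any(Biostrings::width(object@proteins) != 92L))
        msg <- c(msg, "three-finger arrays must be 92 aa")
    prot <- vapply(seq_along(object@cds), function(i)
        .translateDna(as.character(object@cds[[i]])), character(1))
    if (!identical(unname(prot), unname(as.character(object@proteins))))
        msg <- c(msg, "coding sequences must translate to the proteins")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ZFNDesign", function(object) {
    cat("ZFNDesign\n",
        "  left  half-site: 5'-", object@left, "-3' (bottom strand)\n",
        "  right half-site: 5'-", object@right, "-3' (top strand)\n",
        "  spacer: ", object@spacerLength, " nt\n",
        "  proteins: 2 x ", Biostrings::width(object@proteins)[1L], " aa;",
        " CAI ", sprintf("%.3f / %.3f", object@cai[1L], object@cai[2L]), "\n",
        sep = "")
})

#' @describeIn ZFNDesign Protein accessor.
#' @param x,object A `ZFNDesign`.
#' @export
setGeneric("zfpProteins", function(x) standardGeneric("zfpProteins"))

#' @rdname ZFNDesign
#' @export
setMethod("zfpProteins", "ZFNDesign", function(x) x@proteins)

#' @describeIn ZFNDesign Optimised coding-sequence accessor.
#' @export
setGeneric("zfpCodingSeqs", function(x) standardGeneric("zfpCodingSeqs"))

#' @rdname ZFNDesign
#' @export
setMethod("zfpCodingSeqs", "ZFNDesign", function(x) x@cds)

#' Design a ZFN pair for two half-sites
#'
#' Assembles the left and right three-finger arrays ([assembleZfp()]) and
#' reverse-translates both with CAI optimisation
#' ([reverseTranslateOptimize()]). By default the left array is assembled
#' with finger F1 on the 5'-most triplet and the right array with F1 on the
#' 3'-most triplet, matching the helix listings this design reproduces; both
#' orders are overridable.
#'
#' @param left,right 9-nt half-sites (5' to 3' as bound by their arrays).
#' @param spacerLength Spacer length between the half-sites (nt).
#' @param helixTable Triplet -> helix map.
#' @param codonTable A [CodonUsageTable] for the host organism.
#' @param leftFingerOrder,rightFingerOrder Finger-order conventions, see
#'   [assembleZfp()].
#' @param ... Passed to [reverseTranslateOptimize()].
#' @return A [ZFNDesign].
#' @examples
#' designZfnPair("GCTCTACCC", "AGGACGCTT", codonTable = syntheticCodonUsage())
#' @export
designZfnPair <- function(left, right, spacerLength = 7L,
                          helixTable = defaultHelixTable(),
                          codonTable = syntheticCodonUsage(),
                          leftFingerOrder = "five_prime",
                          rightFingerOrder = "three_prime", ...) {
    lp <- assembleZfp(left, helixTable, fingerOrder = leftFingerOrder)
    rp <- assembleZfp(right, helixTable, fingerOrder = rightFingerOrder)
    lo <- reverseTranslateOptimize(lp, codonTable, ...)
    ro <- reverseTranslateOptimize(rp, codonTable, ...)
    proteins <- Biostrings::AAStringSet(c(left = lp, right = rp))
    cds <- Biostrings::DNAStringSet(c(left = lo$coding, right = ro$coding))
    new("ZFNDesign", left = left, right = right,
        spacerLength = as.integer(spacerLength), proteins = proteins,
        cds = cds, cai = c(left = lo$cai, right = ro$cai))
}
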