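## Genotyping of nuclease-induced edits from amplicon clone sequences:
## global alignment to the reference CDS, edit calling with VCF-style
## left-normalisation, protein-level consequence classification, percent
## identity and mutation-spectrum summaries.

#' Global pairwise alignment of a clone against its reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed by
#' [Biostrings::pairwiseAlignment()]. Default scores (match 2, mismatch -1,
#' gap open -4, gap extend -1; a length-L gap costs open + L*extend) suit
#' short amplicon/CDS comparisons.
#'
#' @param ref,alt Nucleotide strings over A/C/G/T (reference first).
#' @param match,mismatch,gapOpen,gapExtend Alignment scores (penalties
#'   negative).
#' @return List with `ref` and `alt` (equal-length aligned strings over
#'   A/C/G/T/-) and `score`.
#' @examples
#' globalAlign("ACGT", "AGT")
#' @export
globalAlign <- function(ref, alt, match = 2, mismatch = -1,
                        gapOpen = -4, gapExtend = -1) {
    .assertScalarString(ref, "ref"); .assertScalarString(alt, "alt")
    ref <- toupper(ref); alt <- toupper(alt)
    if (nchar(ref) == 0L || nchar(alt) == 0L)
        stop("sequences must be non-empty", call. = FALSE)
    .checkDnaAlphabet(ref, allowN = FALSE, what = "ref")
    .checkDnaAlphabet(alt, allowN = FALSE, what = "alt")
    sub <- Biostrings::nucleotideSubstitutionMatrix(
        match = match, mismatch = mismatch, baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(ref), Biostrings::DNAString(alt),
        type = "global", substitutionMatrix = sub,
        gapOpening = -gapOpen, gapExtension = -gapExtend)
    list(ref = as.character(Biostrings::alignedPattern(pa)),
         alt = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa))
}

## left-align a pure insertion/deletion within repeat context (VCF-style);
## never shifted past minPos, the rightmost reference position already
## occupied by an earlier call, so calls stay independent and ordered
.leftAlignIndel <- function(kind, pos, allele, ref, minPos = 0L) {
    k <- nchar(allele)
    if (kind == "deletion") {
        ## deletion of ref[pos .. pos+k-1]; shifting one left preserves the
        ## result iff the base entering the deletion window from the left
        ## equals the base leaving it on the right
        while (pos - 1L > minPos &&
               substr(ref, pos - 1L, pos - 1L) ==
               substr(ref, pos + k - 1L, pos + k - 1L)) {
            pos <- pos - 1L
        }
        allele <- substr(ref, pos, pos + k - 1L)
    } else {
        ## insertion after ref position pos; shift left while the anchor
        ## base equals the last inserted base
        while (pos > minPos &&
               substr(ref, pos, pos) == substr(allele, k, k)) {
            allele <- paste0(substr(ref, pos, pos),
                             substr(allele, 1L, k - 1L))
            pos <- pos - 1L
        }
    }
    list(pos = pos, allele = allele)
}

#' Call edits from a pairwise alignment
#'
#' Maximal runs of difference columns become calls: an isolated
#' substitution is an SNV; a pure gap run is an insertion (gap in the
#' reference row) or deletion (gap in the clone row), left-aligned within
#' homopolymer/repeat context; any other run (mixed substitution and gap,
#' or a multi-nucleotide substitution) is complex. Positions are 1-based on
#' the reference; an insertion is anchored at the reference position it
#' follows (0 = before the first base) with an empty reference allele, a
#' deletion has an empty alternate allele.
#'
#' @param aln Alignment list from [globalAlign()] (elements `ref`, `alt`).
#' @return A `data.frame` with columns `kind`
#'   (SNV/insertion/deletion/complex), `pos`, `ref`, `alt`; zero rows for
#'   identical sequences.
#' @export
callEdits <- function(aln) {
    r <- strsplit(aln$ref, "")[[1L]]
    a <- strsplit(aln$alt, "")[[1L]]
    if (length(r) != length(a))
        stop("aligned strings must have equal length", call. = FALSE)
    if (any(r == "-" & a == "-"))
        stop("alignment has a column with gaps in both rows", call. = FALSE)
    diffCol <- r != a
    if (!any(diffCol))
        return(data.frame(kind = character(0), pos = integer(0),
                          ref = character(0), alt = character(0)))
    refPos <- cumsum(r != "-")  # reference coordinate of each column
    runs <- rle(diffCol)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    refSeq <- paste(r[r != "-"], collapse = "")
    out <- list()
    prevEnd <- 0L  # rightmost ref position touched by earlier runs
    for (i in which(runs$values)) {
        cols <- starts[i]:ends[i]
        refRun <- paste(r[cols][r[cols] != "-"], collapse = "")
        altRun <- paste(a[cols][a[cols] != "-"], collapse = "")
        runEnd <- refPos[cols[length(cols)]]
        if (nchar(refRun) == 1L && nchar(altRun) == 1L) {
            kind <- "SNV"; pos <- refPos[cols[1L]]
        } else if (nchar(altRun) == 0L) {
            kind <- "deletion"; pos <- refPos[cols[1L]]
            la <- .leftAlignIndel("deletion", pos, refRun, refSeq, prevEnd)
            pos <- la$pos; refRun <- la$allele
        } else if (nchar(refRun) == 0L) {
            kind <- "insertion"
            pos <- if (cols[1L] == 1L) 0L else refPos[cols[1L] - 1L]
            la <- .leftAlignIndel("insertion", pos, altRun, refSeq, prevEnd)
            pos <- la$pos; altRun <- la$allele
        } else {
            kind <- "complex"; pos <- refPos[cols[1L]]
        }
        prevEnd <- max(prevEnd, runEnd)
        out[[length(out) + 1L]] <- data.frame(
            kind = kind, pos = as.integer(pos), ref = refRun, alt = altRun)
    }
    res <- do.call(rbind, out)
    res[order(res$pos), , drop = FALSE]
}

#' Apply edit calls to a reference sequence
#'
#' Reconstructs the alternate sequence from a reference and a call table
#' (the inverse of [callEdits()]): applying the calls made from an
#' alignment returns the aligned clone exactly.
#'
#' @param ref Reference nucleotide string.
#' @param edits `data.frame` as returned by [callEdits()].
#' @return The edited sequence.
#' @export
applyEdits <- function(ref, edits) {
    if (nrow(edits) == 0L) return(ref)
    edits <- edits[order(-edits$pos), , drop = FALSE]
    for (i in seq_len(nrow(edits))) {
        e <- edits[i, ]
        if (e$kind == "insertion") {
            ref <- paste0(substr(ref, 1L, e$pos), e$alt,
                          substr(ref, e$pos + 1L, nchar(ref)))
        } else {
            if (e$pos < 1L || e$pos + nchar(e$ref) - 1L > nchar(ref))
                stop("edit at position ", e$pos, " outside sequence",
                     call. = FALSE)
            ref <- paste0(substr(ref, 1L, e$pos - 1L), e$alt,
                          substr(ref, e$pos + nchar(e$ref), nchar(ref)))
        }
    }
    ref
}

## net inserted length of a call table (insertions minus deletions, with
## complex runs contributing their length difference)
.netIndel <- function(edits) {
    if (nrow(edits) == 0L) return(0L)
    sum(nchar(edits$alt) - nchar(edits$ref))
}

#' Classify the protein-level consequence of a set of edits
#'
#' Applies the calls to the coding sequence, translates reference and
#' mutant, and classifies: a premature stop before the original terminus is
#' loss-of-function; otherwise a net indel length not divisible by 3 is a
#' frameshift; an in-frame indel, a missense or a synonymous change
#' otherwise. Because the convention for numbering a frameshifted residue
#' is ambiguous, both the last fully intact codon and the first affected
#' codon are reported. For a single-codon missense the change is formatted
#' `<codon><refAA>><altAA>` (e.g. `231A>V`).
#'
#' @param edits Call table from [callEdits()].
#' @param cds Reference coding sequence (starts ATG, no internal stop; a
#'   terminal stop codon is allowed).
#' @return List with `class`, `frameshift` and `lof` flags,
#'   `first_affected_codon`, `last_intact_codon`, `aa_change` (NA unless a
#'   single-codon missense).
#' @export
classifyConsequence <- function(edits, cds) {
    .assertScalarString(cds, "cds")
    cds <- toupper(cds)
    if (nrow(edits)) {
        maxEnd <- max(edits$pos + pmax(nchar(edits$ref) - 1L, 0L))
        if (any(edits$pos < 0L) || maxEnd > nchar(cds))
            stop("edits fall outside the coding sequence", call. = FALSE)
    }
    refProt <- .translateDna(cds)
    refStop <- regexpr("*", refProt, fixed = TRUE)
    if (refStop > 0L && refStop < nchar(refProt))
        stop("reference cds has an internal stop codon", call. = FALSE)

    mut <- applyEdits(cds, edits)
    mutProt <- .translateDna(mut)
    ## premature stop = a stop at any non-terminal codon of the mutant; an
    ## in-frame deletion that merely moves the original terminus closer is
    ## not premature
    mutStop <- regexpr("*", mutProt, fixed = TRUE)
    prematureStop <- mutStop > 0L && mutStop < nchar(mutProt)

    net <- .netIndel(edits)
    frameshift <- nrow(edits) > 0L && (net %% 3L) != 0L
    anyIndel <- nrow(edits) > 0L &&
        any(edits$kind %in% c("insertion", "deletion") |
            (edits$kind == "complex" & nchar(edits$ref) != nchar(edits$alt)))

    refCore <- sub("\\*.*$", "", refProt)
    mutCore <- sub("\\*.*$", "", mutProt)
    class <- if (nrow(edits) == 0L) "synonymous"
        else if (prematureStop) "loss_of_function"
        else if (frameshift) "frameshift"
        else if (anyIndel) "in_frame_indel"
        else if (!identical(refCore, mutCore)) "missense"
        else "synonymous"

    if (nrow(edits)) {
        firstNt <- min(ifelse(edits$kind == "insertion",
                              edits$pos + 1L, edits$pos))
        firstNt <- max(firstNt, 1L)
        firstCodon <- cdsPositionToCodon(firstNt)
        lastIntact <- as.integer((firstNt - 1L) %/% 3L)
    } else {
        firstCodon <- NA_integer_; lastIntact <- NA_integer_
    }

    aaChange <- NA_character_
    if (class == "missense") {
        diffIdx <- which(strsplit(refCore, "")[[1L]][seq_len(min(nchar(refCore), nchar(mutCore)))] !=
                         strsplit(mutCore, "")[[1L]][seq_len(min(nchar(refCore), nchar(mutCore)))])
        if (length(diffIdx) == 1L)
            aaChange <- sprintf("%d%s>%s", diffIdx,
                                substr(refCore, diffIdx, diffIdx),
                                substr(mutCore, diffIdx, diffIdx))
    }
    list(class = class, frameshift = frameshift, lof = prematureStop,
         first_affected_codon = firstCodon, last_intact_codon = lastIntact,
         aa_change = aaChange)
}

#' Percent identity of an alignment
#'
#' `100 * identical columns / alignment columns`; gap columns count in the
#' denominator (set `countGaps = FALSE` to restrict the denominator to
#' gap-free columns).
#'
#' @param aln Alignment list from [globalAlign()].
#' @param countGaps Include gap columns in the denominator (default TRUE).
#' @return Percentage in \[0, 100\].
#' @export
percentIdentity <- function(aln, countGaps = TRUE) {
    r <- strsplit(aln$ref, "")[[1L]]
    a <- strsplit(aln$alt, "")[[1L]]
    if (length(r) == 0L) stop("zero-length alignment", call. = FALSE)
    ident <- sum(r == a & r != "-")
    denom <- if (countGaps) length(r) else sum(r != "-" & a != "-")
    100 * ident / denom
}

#' Genotype a set of clone sequences against a reference CDS
#'
#' Aligns every clone to the reference ([globalAlign()]), calls edits
#' ([callEdits()]), classifies consequences ([classifyConsequence()]) and
#' computes percent identity.
#'
#' @param ref Reference coding sequence (character or `DNAString`).
#' @param clones Named `DNAStringSet` or named character vector of clone
#'   sequences.
#' @param ... Alignment parameters passed to [globalAlign()].
#' @return List with `calls` (per-edit `data.frame`: clone, kind, pos, ref,
#'   alt) and `clones` (per-clone `data.frame`: clone, n_edits, class,
#'   frameshift, lof, first_affected_codon, last_intact_codon, aa_change,
#'   identity).
#' @export
genotypeClones <- function(ref, clones, ...) {
    ref <- toupper(as.character(ref))
    if (!is.character(clones)) clones <- as.character(clones)
    if (is.null(names(clones)))
        names(clones) <- paste0("clone", seq_along(clones))
    callRows <- list(); cloneRows <- list()
    for (nm in names(clones)) {
        aln <- globalAlign(ref, toupper(clones[[nm]]), ...)
        ed <- callEdits(aln)
        cons <- classifyConsequence(ed, ref)
        if (nrow(ed))
            callRows[[nm]] <- cbind(clone = nm, ed)
        cloneRows[[nm]] <- data.frame(
            clone = nm, n_edits = nrow(ed), class = cons$class,
            frameshift = cons$frameshift, lof = cons$lof,
            first_affected_codon = cons$first_affected_codon,
            last_intact_codon = cons$last_intact_codon,
            aa_change = cons$aa_change,
            identity = percentIdentity(aln))
    }
    calls <- if (length(callRows)) do.call(rbind, callRows)
             else data.frame(clone = character(0), kind = character(0),
                             pos = integer(0), ref = character(0),
                             alt = character(0))
    rownames(calls) <- NULL
    clonesTab <- do.call(rbind, cloneRows)
    rownames(clonesTab) <- NULL
    list(calls = calls, clones = clonesTab)
}

## ---------------------------------------------------------------------------
## Mutation spectrum
## ---------------------------------------------------------------------------

#' Mutation-spectrum summary
#'
#' Proportions of SNV / indel / complex calls over a clone set, plus the
#' (overlapping) percentages of frameshift-inducing and loss-of-function
#' clones. Built by [summarizeSpectrum()].
#'
#' @slot nSequences Total clones summarised.
#' @slot nMutated Clones carrying at least one edit.
#' @slot counting `"per_sequence"` or `"per_mutation"`.
#' @slot proportions Named numeric percentages (SNV, indel, complex),
#'   summing to 100 over mutated units.
#' @slot frameshiftPct,lofPct Percent of mutated clones with a frameshift /
#'   a premature stop.
#' @export
setClass("SpectrumSummary",
    representation(nSequences = "integer", nMutated = "integer",
                   counting = "character", proportions = "numeric",
                   frameshiftPct = "numeric", lofPct = "numeric"))

setValidity("SpectrumSummary", function(object) {
    if (length(object@proportions) == 3L && object@nMutated > 0L &&
        abs(sum(object@proportions) - 100) > 1e-6)
        "SNV + indel + complex proportions must sum to 100"
    else TRUE
})

setMethod("show", "SpectrumSummary", function(object) {
    cat("SpectrumSummary (", object@counting, ") over ", object@nMutated,
        " mutated / ", object@nSequences, " sequences\n", sep = "")
    p <- object@proportions
    cat(sprintf("  SNV %.1f%%  indel %.1f%%  complex %.1f%%\n",
                p[["SNV"]], p[["indel"]], p[["complex"]]))
    cat(sprintf("  frameshift-inducing %.1f%%  loss-of-function %.1f%%\n",
                object@frameshiftPct, object@lofPct))
})

#' @describeIn SpectrumSummary Proportion accessor (named percentages).
#' @param x,object A `SpectrumSummary`.
#' @export
setGeneric("spectrumProportions", function(x)
    standardGeneric("spectrumProportions"))

#' @rdname SpectrumSummary
#' @export
setMethod("spectrumProportions", "SpectrumSummary", function(x) x@proportions)

#' Summarise the mutation spectrum of a genotyped clone set
#'
#' With `counting = "per_sequence"` (default) each mutated clone
#' contributes one unit to a primary category with precedence
#' complex > indel > SNV (a clone with any complex call is complex, else
#' indel if it carries any insertion/deletion, else SNV). With
#' `counting = "per_mutation"` every individual call is tallied instead.
#' Frameshift and loss-of-function percentages are always per mutated
#' clone and overlap the category proportions rather than partitioning
#' them.
#'
#' @param genotyped Output of [genotypeClones()].
#' @param counting `"per_sequence"` or `"per_mutation"`.
#' @param allowUnmutated Return a zero-mutation summary instead of an error
#'   when no clone differs from the reference.
#' @return A [SpectrumSummary].
#' @export
summarizeSpectrum <- function(genotyped,
                              counting = c("per_sequence", "per_mutation"),
                              allowUnmutated = FALSE) {
    counting <- match.arg(counting)
    calls <- genotyped$calls
    clones <- genotyped$clones
    if (nrow(clones) == 0L) stop("no clones to summarise", call. = FALSE)
    mutated <- unique(calls$clone)
    if (length(mutated) == 0L) {
        if (!allowUnmutated)
            stop("no clone differs from the reference", call. = FALSE)
        return(new("SpectrumSummary", nSequences = nrow(clones),
                   nMutated = 0L, counting = counting,
                   proportions = c(SNV = NaN, indel = NaN, complex = NaN),
                   frameshiftPct = NaN, lofPct = NaN))
    }
    if (counting == "per_sequence") {
        cat3 <- vapply(mutated, function(cl) {
            k <- calls$kind[calls$clone == cl]
            if (any(k == "complex")) "complex"
            else if (any(k %in% c("insertion", "deletion"))) "indel"
            else "SNV"
        }, character(1))
        tab <- table(factor(cat3, levels = c("SNV", "indel", "complex")))
        prop <- 100 * as.numeric(tab) / length(mutated)
    } else {
        k <- ifelse(calls$kind %in% c("insertion", "deletion"), "indel",
                    calls$kind)
        tab <- table(factor(k, levels = c("SNV", "indel", "complex")))
        prop <- 100 * as.numeric(tab) / nrow(calls)
    }
    names(prop) <- c("SNV", "indel", "complex")
    mutRows <- clones[clones$clone %in% mutated, , drop = FALSE]
    new("SpectrumSummary",
        nSequences = nrow(clones), nMutated = length(mutated),
        counting = counting, proportions = prop,
        frameshiftPct = 100 * mean(mutRows$frameshift),
        lofPct = 100 * mean(mutRows$lof))
}
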