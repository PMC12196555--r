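## ---------------------------------------------------------------------------
## FASTA I/O
## ---------------------------------------------------------------------------

#' Read a FASTA file into a validated string set
#'
#' Thin validation layer over [Biostrings::readBStringSet()]: sequences are
#' uppercased, record identifiers (the first whitespace-delimited token of
#' each header) must be unique, records must be non-empty, and for
#' `type = "dna"` the alphabet is restricted to A, C, G, T, N (soft-masked
#' lowercase bases are uppercased; masking is not tracked).
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` (returns a [Biostrings::DNAStringSet]) or `"aa"`
#'   (returns a [Biostrings::AAStringSet]).
#' @return A `DNAStringSet` or `AAStringSet`, one element per record, in file
#'   order; an empty set for an empty file.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g", "acgt"), tf)
#' readFastaRecords(tf)
#' @export
readFastaRecords <- function(path, type = c("dna", "aa")) {
    type <- match.arg(type)
    if (!file.exists(path))
        stop("no such file: ", path, call. = FALSE)
    if (file.size(path) == 0L)
        return(if (type == "dna") Biostrings::DNAStringSet()
               else Biostrings::AAStringSet())
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("malformed FASTA '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
    ids <- sub("\\s.*$", "", names(set))
    if (any(ids == ""))
        stop("malformed FASTA '", path, "': record ",
             which(ids == "")[1L], " has an empty header", call. = FALSE)
    if (anyDuplicated(ids))
        stop("duplicate record identifiers in '", path, "': ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    if (any(width(set) == 0L))
        stop("empty sequence for record '", ids[width(set) == 0L][1L],
             "' in '", path, "'", call. = FALSE)
    seqs <- toupper(as.character(set))
    if (type == "dna") {
        .checkDnaAlphabet(seqs, allowN = TRUE, what = paste0("FASTA '", path, "'"))
        out <- Biostrings::DNAStringSet(seqs)
    } else {
        out <- Biostrings::AAStringSet(seqs)
    }
    names(out) <- ids
    out
}

#' Write sequences to FASTA
#'
#' @param x A named `XStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(x, path) {
    if (is.character(x)) x <- Biostrings::BStringSet(x)
    if (is.null(names(x)) || anyDuplicated(names(x)))
        stop("records must carry unique names", call. = FALSE)
    Biostrings::writeXStringSet(x, filepath = path)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Elementary sequence arithmetic
## ---------------------------------------------------------------------------

#' Reverse complement of plain nucleotide strings
#'
#' Character-vector front end to [Biostrings::reverseComplement()]; accepts
#' only A, C, G, T, N (N maps to N).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverseComplementSeq("AGGACGCTT")
#' @export
reverseComplementSeq <- function(x) {
    if (!is.character(x)) stop("x must be character", call. = FALSE)
    .checkDnaAlphabet(x, allowN = TRUE)
    vapply(x, function(s) {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, character(1), USE.NAMES = FALSE)
}

#' Map a CDS nucleotide position to its codon index
#'
#' Under the ATG-at-position-1 convention, nucleotide `pos` of a coding
#' sequence lies in codon `ceiling(pos / 3)`; e.g. position 692 lies in
#' codon 231.
#'
#' @param pos Integer vector of 1-based CDS nucleotide positions.
#' @return Integer vector of 1-based codon indices.
#' @examples
#' cdsPositionToCodon(c(692, 524))
#' @export
cdsPositionToCodon <- function(pos) {
    if (!is.numeric(pos) || any(!is.finite(pos)) || any(pos < 1))
        stop("pos must be >= 1", call. = FALSE)
    as.integer(ceiling(pos / 3))
}

#' Position of a CDS coordinate relative to a window
#'
#' Reports whether each position falls upstream of, inside, or downstream of
#' a 1-based inclusive CDS window, and the distance in nucleotides
#' (`window start - pos` upstream, `pos - window end` downstream, 0 inside).
#'
#' @param pos Integer vector of 1-based CDS positions.
#' @param window Length-2 numeric, `c(start, end)` with `start <= end`.
#' @return A `data.frame` with columns `pos`, `relation`
#'   (upstream/inside/downstream) and `distance`.
#' @examples
#' distanceToWindow(c(524, 769, 700), c(689, 713))
#' @export
distanceToWindow <- function(pos, window) {
    if (length(window) != 2L || any(!is.finite(window)) ||
        window[1] < 1 || window[1] > window[2])
        stop("window must be c(start, end) with 1 <= start <= end",
             call. = FALSE)
    if (any(pos < 1)) stop("pos must be >= 1", call. = FALSE)
    relation <- ifelse(pos < window[1], "upstream",
                ifelse(pos > window[2], "downstream", "inside"))
    distance <- ifelse(relation == "upstream", window[1] - pos,
                ifelse(relation == "downstream", pos - window[2], 0))
    data.frame(pos = as.integer(pos), relation = relation,
               distance = as.integer(distance))
}

## ---------------------------------------------------------------------------
## GeneModel
## ---------------------------------------------------------------------------

#' Gene model with isoform exon structure and a CDS sequence
#'
#' Holds a gene's isoforms as a [GenomicRanges::GRangesList] (one element per
#' isoform, exons in genomic order) together with the coding sequence used
#' for all CDS coordinate arithmetic. The CDS must start with ATG and the
#' exons of each isoform must be non-overlapping; genomic intervals follow
#' the usual Bioconductor 1-based inclusive convention.
#'
#' @slot geneId Gene identifier.
#' @slot geneStrand `"+"` or `"-"`.
#' @slot isoforms `GRangesList` of exon intervals, one element per isoform.
#' @slot cds Coding sequence as a [Biostrings::DNAString].
#' @export
setClass("GeneModel",
    representation(geneId = "character", geneStrand = "character",
                   isoforms = "GRangesList", cds = "ANY"))

setValidity("GeneModel", function(object) {
    msg <- character(0)
    if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be length 1")
    if (!object@geneStrand %in% c("+", "-"))
        msg <- c(msg, "geneStrand must be '+' or '-'")
    if (length(object@isoforms) < 1L)
        msg <- c(msg, "at least one isoform is required")
    for (i in seq_along(object@isoforms)) {
        ex <- object@isoforms[[i]]
        if (length(ex) > 1L) {
            o <- order(start(ex))
            if (any(start(ex)[o][-1L] <= end(ex)[o][-length(ex)]))
                msg <- c(msg, paste0("isoform ", i, " has overlapping exons"))
        }
    }
    cds <- as.character(object@cds)
    if (nchar(cds) < 3L) msg <- c(msg, "cds must be at least 3 nt")
    if (substr(cds, 1L, 3L) != "ATG")
        msg <- c(msg, "cds must begin with ATG")
    if (length(msg)) msg else TRUE
})

#' @describeIn GeneModel Constructor.
#' @param geneId Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param isoforms Named `GRangesList` (or list of `GRanges`) of exons.
#' @param cds Coding sequence (character or `DNAString`), beginning ATG.
#' @export
GeneModel <- function(geneId, strand, isoforms, cds) {
    if (is.list(isoforms)) isoforms <- GRangesList(isoforms)
    if (is.character(cds)) {
        cds <- toupper(cds)
        .checkDnaAlphabet(cds, what = "cds")
        cds <- Biostrings::DNAString(cds)
    }
    new("GeneModel", geneId = geneId, geneStrand = strand,
        isoforms = isoforms, cds = cds)
}

#' @describeIn GeneModel Coding sequence accessor (as character).
#' @param x,object A `GeneModel`.
#' @export
setGeneric("cdsSequence", function(x) standardGeneric("cdsSequence"))

#' @rdname GeneModel
#' @export
setMethod("cdsSequence", "GeneModel", function(x) as.character(x@cds))

#' @describeIn GeneModel Isoform exon structure accessor.
#' @export
setGeneric("isoformExons", function(x) standardGeneric("isoformExons"))

#' @rdname GeneModel
#' @export
setMethod("isoformExons", "GeneModel", function(x) x@isoforms)

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel '", object@geneId, "' (", object@geneStrand, ") with ",
        length(object@isoforms), " isoform(s); CDS ",
        length(object@cds), " nt\n", sep = "")
})

#' Exons shared by every isoform of a gene
#'
#' An exon is shared when an interval with identical genomic start and end
#' occurs in every isoform (structural identity, not mere overlap). Shared
#' constitutive exons are the natural place to direct an edit that must hit
#' all predicted transcripts.
#'
#' @param model A [GeneModel].
#' @return A `GRanges` of shared exon intervals in genomic order (empty when
#'   no interval is common to all isoforms).
#' @export
findSharedExons <- function(model) {
    stopifnot(is(model, "GeneModel"))
    iso <- model@isoforms
    if (length(iso) == 0L) stop("gene model has no isoforms", call. = FALSE)
    key <- function(gr) paste0(as.character(seqnames(gr)), ":",
                               start(gr), "-", end(gr))
    shared <- Reduce(intersect, lapply(iso, key))
    first <- iso[[1L]]
    out <- first[key(first) %in% shared]
    out[order(as.character(seqnames(out)), start(out))]
}

## ---------------------------------------------------------------------------
## GFF3 gene models
## ---------------------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Imports a GFF3 annotation via [rtracklayer::import()], groups exon
#' features into transcripts through their `Parent` attribute, and groups
#' transcripts into genes. Coding sequences are supplied separately (one per
#' gene, e.g. from a CDS FASTA) because GFF3 carries structure, not sequence.
#'
#' @param gffPath Path to a GFF3 file with gene/mRNA/exon features.
#' @param cdsSeqs Named character vector or `DNAStringSet` of coding
#'   sequences keyed by gene id.
#' @return A named list of [GeneModel] objects (genes lacking a CDS entry
#'   are dropped with a warning).
#' @export
readGeneModels <- function(gffPath, cdsSeqs) {
    gff <- tryCatch(rtracklayer::import(gffPath, format = "gff3"),
                    error = function(e) stop("cannot parse GFF3 '", gffPath,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
    if (!is.null(names(cdsSeqs)) && !is.character(cdsSeqs))
        cdsSeqs <- as.character(cdsSeqs)
    tx <- gff[gff$type %in% c("mRNA", "transcript")]
    ex <- gff[gff$type == "exon"]
    if (length(tx) == 0L || length(ex) == 0L)
        stop("GFF3 '", gffPath, "' has no mRNA/exon features", call. = FALSE)
    txGene <- vapply(tx$Parent, function(p) as.character(p)[1L], character(1))
    names(txGene) <- tx$ID
    exTx <- vapply(ex$Parent, function(p) as.character(p)[1L], character(1))
    models <- list()
    for (g in unique(txGene)) {
        txIds <- names(txGene)[txGene == g]
        iso <- lapply(txIds, function(t) {
            e <- ex[exTx == t]
            e[order(start(e))]
        })
        names(iso) <- txIds
        if (!g %in% names(cdsSeqs)) {
            warning("no CDS sequence provided for gene '", g, "'; skipped")
            next
        }
        strand <- as.character(strand(tx[tx$ID == txIds[1L]]))[1L]
        if (!strand %in% c("+", "-")) strand <- "+"
        models[[g]] <- GeneModel(g, strand, GRangesList(iso), cdsSeqs[[g]])
    }
    models
}

#' CDS windows covered by shared exons
#'
#' Maps each shared exon (see [findSharedExons()]) to the 1-based CDS
#' interval it occupies, assuming the CDS of the anchor isoform is the
#' concatenation of its exons in transcription order (exons taken 5' to 3';
#' for minus-strand genes genomic order is reversed). Intervals are clipped
#' to the CDS length.
#'
#' @param model A [GeneModel].
#' @param isoform Index or name of the isoform anchoring CDS numbering
#'   (default first).
#' @return A `data.frame` with columns `start`, `end` (1-based CDS
#'   coordinates) in CDS order; zero rows when nothing is shared.
#' @export
cdsWindowsFromSharedExons <- function(model, isoform = 1L) {
    shared <- findSharedExons(model)
    anchor <- model@isoforms[[isoform]]
    anchor <- anchor[order(start(anchor))]
    if (model@geneStrand == "-") anchor <- rev(anchor)
    w <- width(anchor)
    cdsStart <- cumsum(c(1L, w))[seq_along(w)]
    key <- paste0(as.character(seqnames(anchor)), ":", start(anchor), "-",
                  end(anchor))
    sharedKey <- paste0(as.character(seqnames(shared)), ":", start(shared),
                        "-", end(shared))
    idx <- which(key %in% sharedKey)
    n <- length(model@cds)
    out <- data.frame(start = cdsStart[idx],
                      end = cdsStart[idx] + w[idx] - 1L)
    out <- out[out$start <= n, , drop = FALSE]
    out$end <- pmin(out$end, n)
    out[order(out$start), , drop = FALSE]
}
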