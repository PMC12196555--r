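## Workflow drivers tying the modules together. Each driver reads standard
## files, runs the corresponding pipeline and writes tab-delimited / BED /
## FASTA outputs; the inst/cli/zfntools.R script exposes them as shell
## subcommands.

.logmsg <- function(...) message("[ZFNtools] ", ...)

#' Run the ZFN design workflow
#'
#' Reads a coding sequence (and optionally a GFF3 gene model to restrict
#' the search to exons shared by all isoforms), enumerates candidate
#' half-site pairs covered by the recognition-helix table, assembles both
#' zinc-finger arrays for each candidate and reverse-translates them with
#' CAI optimisation.
#'
#' @param cdsFasta FASTA with the reference coding sequence(s); the first
#'   record is used unless `gene` is given.
#' @param gff Optional GFF3 path; with it, candidates are restricted to
#'   CDS windows covered by shared exons.
#' @param gene Optional gene id selecting the record/model.
#' @param helixFile Optional helix-table path (default: seeded table).
#' @param codonFile Optional codon-usage path (default: synthetic table).
#' @param spacerRange Candidate spacer lengths.
#' @param outPrefix Output prefix: writes `<prefix>_design.tsv`,
#'   `<prefix>_proteins.fa`, `<prefix>_cds.fa` (omitted when `NULL`).
#' @return Invisibly, a `data.frame` report (one row per candidate:
#'   half-sites, spacer, site coordinates, CAI of both arrays).
#' @export
runDesign <- function(cdsFasta, gff = NULL, gene = NULL,
                      helixFile = NULL, codonFile = NULL,
                      spacerRange = 4:10, outPrefix = NULL) {
    cdsSet <- readFastaRecords(cdsFasta, type = "dna")
    if (length(cdsSet) == 0L) stop("empty CDS FASTA", call. = FALSE)
    if (is.null(gene)) gene <- names(cdsSet)[1L]
    if (!gene %in% names(cdsSet))
        stop("gene '", gene, "' not in ", cdsFasta, call. = FALSE)
    cds <- as.character(cdsSet[[match(gene, names(cdsSet))]])
    helixTable <- if (is.null(helixFile)) defaultHelixTable()
                  else readHelixTable(helixFile)
    codonTable <- if (is.null(codonFile)) syntheticCodonUsage()
                  else readCodonUsage(codonFile)

    searchWindows <- list(c(1L, nchar(cds)))
    if (!is.null(gff)) {
        models <- readGeneModels(gff, stats::setNames(cds, gene))
        if (!gene %in% names(models))
            stop("gene '", gene, "' not found in ", gff, call. = FALSE)
        sw <- cdsWindowsFromSharedExons(models[[gene]])
        searchWindows <- lapply(seq_len(nrow(sw)),
                                function(i) c(sw$start[i], sw$end[i]))
        .logmsg(length(searchWindows), " shared-exon window(s) searched")
    }

    rows <- list()
    for (w in searchWindows) {
        sub <- substr(cds, w[1], w[2])
        cand <- as.data.frame(selectHalfSitePairs(sub, spacerRange,
                                                  helixTable))
        if (nrow(cand)) {
            cand$start <- cand$start + w[1] - 1L
            cand$end <- cand$end + w[1] - 1L
            rows[[length(rows) + 1L]] <- cand
        }
    }
    if (!length(rows)) {
        warning("no helix-coverable candidate site found")
        report <- data.frame(start = integer(0), end = integer(0),
                             spacer = integer(0), left = character(0),
                             right = character(0), cai_left = numeric(0),
                             cai_right = numeric(0))
    } else {
        report <- do.call(rbind, rows)
        report <- report[order(report$start, report$spacer), , drop = FALSE]
        designs <- lapply(seq_len(nrow(report)), function(i)
            designZfnPair(report$left[i], report$right[i], report$spacer[i],
                          helixTable, codonTable))
        report$cai_left <- vapply(designs, function(d) d@cai[[1L]], numeric(1))
        report$cai_right <- vapply(designs, function(d) d@cai[[2L]], numeric(1))
        if (!is.null(outPrefix)) {
            prot <- do.call(c, lapply(seq_along(designs), function(i) {
                p <- zfpProteins(designs[[i]])
                names(p) <- sprintf("site%d_%s", i, names(p))
                p
            }))
            dna <- do.call(c, lapply(seq_along(designs), function(i) {
                d <- zfpCodingSeqs(designs[[i]])
                names(d) <- sprintf("site%d_%s", i, names(d))
                d
            }))
            writeFastaRecords(prot, paste0(outPrefix, "_proteins.fa"))
            writeFastaRecords(dna, paste0(outPrefix, "_cds.fa"))
        }
    }
    .logmsg(nrow(report), " candidate site(s)")
    if (!is.null(outPrefix))
        utils::write.table(report, paste0(outPrefix, "_design.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(report)
}

#' Run the off-target scan workflow
#'
#' Enumerates composite patterns for a half-site pair, scans every contig
#' of a genome FASTA on both strands, and writes a BED6 of hits plus a
#' FASTA of flanking contexts.
#'
#' @param genomeFasta Genome FASTA path.
#' @param left,right 9-nt half-sites.
#' @param spacerRange Spacer lengths (default 4:10).
#' @param maxMismatches Mismatch budget over half-site positions.
#' @param flank Flank length for context extraction (nt each side).
#' @param outBed BED6 output path.
#' @param outFasta Optional context FASTA output path.
#' @return Invisibly, the `GRanges` of hits.
#' @export
runScan <- function(genomeFasta, left, right, spacerRange = 4:10,
                    maxMismatches = 0L, flank = 100L,
                    outBed = NULL, outFasta = NULL) {
    genome <- readFastaRecords(genomeFasta, type = "dna")
    if (length(genome) == 0L) stop("empty genome FASTA", call. = FALSE)
    patterns <- enumeratePatterns(left, right, spacerRange)
    .logmsg(nrow(patterns), " patterns enumerated")
    hits <- scanGenome(genome, patterns, maxMismatches)
    .logmsg(length(hits), " hit(s)")
    if (!is.null(outBed))
        writeHits(hits, outBed, genome = if (is.null(outFasta)) NULL
                                         else genome,
                  fastaPath = outFasta, flankUp = flank, flankDown = flank)
    invisible(hits)
}

#' Run the genotyping workflow
#'
#' Aligns mutant clone sequences to a reference CDS, calls and classifies
#' edits, and writes a per-clone call table plus a spectrum summary.
#'
#' @param refFasta FASTA with the reference CDS (first record used).
#' @param clonesFasta Multi-FASTA of clone sequences.
#' @param outCalls Optional TSV path for the per-edit call table.
#' @param outClones Optional TSV path for the per-clone consequence table.
#' @param counting Spectrum counting mode, see [summarizeSpectrum()].
#' @return Invisibly, a list with `calls`, `clones` (see
#'   [genotypeClones()]) and `spectrum` (a [SpectrumSummary], or `NULL`
#'   when no clone is mutated).
#' @export
runGenotype <- function(refFasta, clonesFasta, outCalls = NULL,
                        outClones = NULL,
                        counting = c("per_sequence", "per_mutation")) {
    refSet <- readFastaRecords(refFasta, type = "dna")
    if (length(refSet) == 0L) stop("empty reference FASTA", call. = FALSE)
    ref <- as.character(refSet[[1L]])
    if (substr(ref, 1L, 3L) != "ATG")
        warning("reference does not start with ATG; codon numbering ",
                "assumes position 1 is the first base of the start codon")
    clones <- readFastaRecords(clonesFasta, type = "dna")
    if (length(clones) == 0L) stop("no clone sequences", call. = FALSE)
    gt <- genotypeClones(ref, clones)
    spec <- tryCatch(summarizeSpectrum(gt, counting = match.arg(counting)),
                     error = function(e) NULL)
    .logmsg(nrow(gt$calls), " call(s) over ", length(clones), " clone(s)")
    if (!is.null(outCalls))
        utils::write.table(gt$calls, outCalls, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(outClones))
        utils::write.table(gt$clones, outClones, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(list(calls = gt$calls, clones = gt$clones, spectrum = spec))
}

#' Run the fixture-simulation workflow
#'
#' Writes a synthetic genome with planted sites (and its truth table), or a
#' mutant clone set with a configured spectrum (and its truth table).
#'
#' @param what `"genome"` or `"clones"`.
#' @param outPrefix Output prefix: `<prefix>.fa` and `<prefix>_truth.tsv`.
#' @param seed Integer seed.
#' @param ... Passed to [makeSyntheticGenome()] or [makeMutantClones()]
#'   (for `"clones"`, a `cds` is generated with [makeSyntheticCds()] when
#'   not supplied, and written to `<prefix>_ref.fa`).
#' @return Invisibly, the generator's result list.
#' @export
runSimulate <- function(what = c("genome", "clones"), outPrefix, seed = 1L,
                        ...) {
    what <- match.arg(what)
    if (what == "genome") {
        res <- makeSyntheticGenome(seed = seed, ...)
        writeFastaRecords(res$genome, paste0(outPrefix, ".fa"))
        utils::write.table(res$truth, paste0(outPrefix, "_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        args <- list(...)
        if (is.null(args$cds)) args$cds <- makeSyntheticCds(seed = seed)
        if (is.null(args$n)) args$n <- 100L
        args$seed <- seed
        res <- do.call(makeMutantClones, args)
        writeFastaRecords(stats::setNames(args$cds, "reference"),
                          paste0(outPrefix, "_ref.fa"))
        writeFastaRecords(res$clones, paste0(outPrefix, ".fa"))
        utils::write.table(res$truth, paste0(outPrefix, "_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .logmsg("fixture written to ", outPrefix, ".fa")
    invisible(res)
}
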