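## Internal helpers shared across modules.

.assertScalarString <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || is.na(x))
        stop(what, " must be a single character string", call. = FALSE)
    invisible(x)
}

## Nucleotide alphabet check (A/C/G/T plus ambiguous N).
.checkDnaAlphabet <- function(x, allowN = TRUE, what = "sequence") {
    ok <- if (allowN) "^[ACGTN]*$" else "^[ACGT]*$"
    bad <- !grepl(ok, x)
    if (any(bad))
        stop(what, " contains non-nucleotide characters: ",
             paste(unique(unlist(strsplit(gsub(if (allowN) "[ACGTN]" else "[ACGT]",
                                               "", x[bad]), ""))), collapse = ","),
             call. = FALSE)
    invisible(x)
}

.SENSE_CODONS <- local({
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc != "*"]
})

.STOP_CODONS <- local({
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc == "*"]
})

## codon -> amino acid for the standard code, sense codons only
.codonToAa <- function(codons) {
    unname(Biostrings::GENETIC_CODE[codons])
}

.splitCodons <- function(cds) {
    n <- nchar(cds)
    if (n %% 3L != 0L)
        stop("coding sequence length (", n, ") is not a multiple of 3",
             call. = FALSE)
    if (n == 0L) return(character(0))
    substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

.translateDna <- function(x) {
    ## translate the longest complete-codon prefix; stops rendered as '*'
    n <- (nchar(x) %/% 3L) * 3L
    if (n == 0L) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)),
                                       if.fuzzy.codon = "X"))
}
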