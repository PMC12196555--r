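## Small quantification utilities: qPCR relative expression by the
## 2^-ddCt method and the percent-change descriptor for morphometrics.

#' Relative expression fold change by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,sample - Ct_reference,sample) -
#' (Ct_target,calibrator - Ct_reference,calibrator)`; the fold change is
#' `2^-ddCt`. No amplification-efficiency correction is applied. Averaging
#' of technical replicates before the delta is the caller's responsibility
#' (see [foldChangeTable()] for a convenience aggregator).
#'
#' @param ctTargetSample,ctRefSample Ct of target and reference gene in the
#'   sample (cycles).
#' @param ctTargetCalibrator,ctRefCalibrator Ct of target and reference
#'   gene in the calibrator.
#' @return Unitless fold change (vectorised).
#' @examples
#' ddctFoldChange(20, 18, 22, 18)  # 4
#' @export
ddctFoldChange <- function(ctTargetSample, ctRefSample,
                           ctTargetCalibrator, ctRefCalibrator) {
    vals <- c(ctTargetSample, ctRefSample, ctTargetCalibrator,
              ctRefCalibrator)
    if (any(!is.finite(vals)) || any(vals <= 0))
        stop("Ct values must be finite and positive", call. = FALSE)
    ddct <- (ctTargetSample - ctRefSample) -
        (ctTargetCalibrator - ctRefCalibrator)
    2^(-ddct)
}

#' Fold changes from a long-format Ct table
#'
#' Aggregates technical replicates by the mean and computes, for every
#' (sample, gene) pair, the fold change relative to a calibrator sample,
#' normalised to a reference gene, via [ddctFoldChange()].
#'
#' @param ct `data.frame` with columns `sample`, `gene`, `ct`.
#' @param calibrator Name of the calibrator sample (e.g. wild type).
#' @param referenceGene Name of the normalising reference gene.
#' @return `data.frame` with columns `sample`, `gene`, `fold_change`
#'   (calibrator and reference-gene rows excluded).
#' @export
foldChangeTable <- function(ct, calibrator, referenceGene) {
    stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
    if (!calibrator %in% ct$sample)
        stop("calibrator sample '", calibrator, "' not in table", call. = FALSE)
    if (!referenceGene %in% ct$gene)
        stop("reference gene '", referenceGene, "' not in table", call. = FALSE)
    agg <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
    lookup <- function(s, g) {
        v <- agg$ct[agg$sample == s & agg$gene == g]
        if (length(v) != 1L)
            stop("missing Ct for sample '", s, "', gene '", g, "'",
                 call. = FALSE)
        v
    }
    out <- list()
    for (s in setdiff(unique(agg$sample), calibrator)) {
        for (g in setdiff(unique(agg$gene[agg$sample == s]), referenceGene)) {
            out[[length(out) + 1L]] <- data.frame(
                sample = s, gene = g,
                fold_change = ddctFoldChange(
                    lookup(s, g), lookup(s, referenceGene),
                    lookup(calibrator, g), lookup(calibrator, referenceGene)))
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Percent change of a measurement relative to wild type
#'
#' `(m - wt) / wt * 100`, the standard descriptor for mutant-vs-wild-type
#' morphometric comparisons.
#'
#' @param m Mutant measurement(s).
#' @param wt Wild-type measurement(s); must be non-zero.
#' @return Percent change (vectorised).
#' @examples
#' percentChange(16.3, 10)  # 63
#' @export
percentChange <- function(m, wt) {
    if (any(!is.finite(m)) || any(!is.finite(wt)))
        stop("measurements must be finite", call. = FALSE)
    if (any(wt == 0)) stop("wt must be non-zero", call. = FALSE)
    (m - wt) / wt * 100
}
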