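## nRPKM normalization: median-of-ratios size factors, adjusted total
## reads, and RPKM / nRPKM expression matrices.

.geomMean <- function(x) exp(mean(log(x)))

#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample as the median, over
#' reference genes, of the ratio of the sample's count to the gene's
#' geometric mean across samples. Reference genes are those with a nonzero
#' count in every sample (the geometric mean is undefined otherwise). The
#' factors are anchored so that their geometric mean is exactly 1, which
#' makes the single-sample case return 1.
#'
#' @param counts a `CellCountSet` or a nonnegative gene-by-sample matrix.
#' @param totalReads optional per-sample total uniquely aligned reads; when
#'   supplied (or when `counts` is a `CellCountSet`, which carries them),
#'   adjusted totals are calibrated immediately via
#'   [computeAdjustedTotals()].
#' @return a [SizeFactors] object.
#' @examples
#' m <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
#' rownames(m) <- paste0("g", 1:3)
#' sizeFactors(computeSizeFactors(m))   # (1/sqrt(2), sqrt(2))
#' @export
computeSizeFactors <- function(counts, totalReads = NULL) {
    if (is(counts, "CellCountSet")) {
        if (is.null(totalReads)) totalReads <- totalUniqReads(counts)
        counts <- BiocGenerics::counts(counts)
    }
    counts <- as.matrix(counts)
    if (ncol(counts) == 1L) {
        s <- setNames(1, colnames(counts))
    } else {
        ref <- rowSums(counts > 0) == ncol(counts)
        if (!any(ref))
            stop("no gene has a nonzero count in every sample; ",
                 "median-of-ratios size factors are undefined")
        sub <- counts[ref, , drop = FALSE]
        geo <- exp(rowMeans(log(sub)))
        s <- apply(sub / geo, 2, median)
        s <- s / .geomMean(s)
    }
    sf <- new("SizeFactors", factors = s, adjustedTotals = numeric())
    if (!is.null(totalReads)) sf <- computeAdjustedTotals(sf, totalReads)
    sf
}

#' Calibrate adjusted total reads
#'
#' The adjusted total of sample j is proportional to its size factor and
#' rescaled to the level of total uniquely aligned reads:
#' `adjusted_j = s_j * sum(M) / sum(s)`, so that the sum of adjusted totals
#' equals the sum of the observed totals. Any positive calibration constant
#' preserves the proportionality of nRPKM to normalized counts; conserving
#' the project-wide read total keeps nRPKM on a familiar scale.
#'
#' @param sizeFactors a [SizeFactors] object.
#' @param totalReads positive per-sample totals (M), aligned with the
#'   factors.
#' @return the [SizeFactors] object with `adjustedTotals()` filled in.
#' @export
computeAdjustedTotals <- function(sizeFactors, totalReads) {
    stopifnot(is(sizeFactors, "SizeFactors"))
    s <- sizeFactors@factors
    if (length(totalReads) != length(s))
        stop("length mismatch: ", length(s), " size factors but ",
             length(totalReads), " totals")
    if (any(totalReads <= 0)) stop("all totals must be > 0")
    if (!is.null(names(totalReads)) && !is.null(names(s)))
        totalReads <- totalReads[names(s)]
    adj <- s * sum(totalReads) / sum(s)
    new("SizeFactors", factors = s, adjustedTotals = setNames(adj, names(s)))
}

#' RPKM and nRPKM expression matrices
#'
#' RPKM divides each count by gene length in kilobases and by total
#' uniquely aligned reads in millions. nRPKM is identical except that the
#' per-sample "M" term is the adjusted total (size-factor-proportional,
#' rescaled to the read total), so that for any fixed gene the nRPKM values
#' across samples are exactly proportional to count / size factor. A zero
#' count always yields zero expression; no pseudocount is added here.
#'
#' @param counts a `CellCountSet`, or a count matrix (then `geneLength` and
#'   `totalReads` are required).
#' @param sizeFactors optional [SizeFactors]; computed from the counts when
#'   missing and `mode = "nRPKM"`.
#' @param mode `"nRPKM"` (default) or `"RPKM"`.
#' @param geneLength,totalReads required when `counts` is a plain matrix.
#' @return a gene-by-sample matrix with attributes `mode`, `sizeFactors`
#'   and `totals` recording the normalization provenance.
#' @export
computeExpression <- function(counts, sizeFactors = NULL,
                              mode = c("nRPKM", "RPKM"),
                              geneLength = NULL, totalReads = NULL) {
    mode <- match.arg(mode)
    if (is(counts, "CellCountSet")) {
        geneLength <- geneLengths(counts)
        totalReads <- totalUniqReads(counts)
        counts <- BiocGenerics::counts(counts)
    }
    counts <- as.matrix(counts)
    if (is.null(geneLength) || is.null(totalReads))
        stop("'geneLength' and 'totalReads' are required for matrix input")
    if (any(geneLength <= 0)) stop("all gene lengths must be > 0")
    if (any(totalReads <= 0)) stop("all totals must be > 0")
    if (mode == "nRPKM") {
        if (is.null(sizeFactors))
            sizeFactors <- computeSizeFactors(counts, totalReads)
        else if (!length(sizeFactors@adjustedTotals))
            sizeFactors <- computeAdjustedTotals(sizeFactors, totalReads)
        M <- adjustedTotals(sizeFactors)
    } else {
        M <- totalReads
    }
    expr <- counts / (geneLength / 1e3)
    expr <- sweep(expr, 2, M / 1e6, "/")
    attr(expr, "mode") <- mode
    attr(expr, "sizeFactors") <- if (mode == "nRPKM")
        sizeFactors(sizeFactors) else NULL
    attr(expr, "totals") <- M
    expr
}

#' Minimum-count gene pre-filter
#'
#' A gene passes when at least `minSamples` samples (pooled over all
#' conditions) have at least `minCount` reads. The defaults reproduce the
#' "at least ten counts in at least three samples" rule applied upstream of
#' differential expression; genes that fail are reported with p = 1 and
#' log2 fold change 0 and are excluded from multiple-testing correction.
#'
#' @param counts a `CellCountSet` or count matrix.
#' @param minCount,minSamples filter thresholds (defaults 10 and 3).
#' @return named logical vector, `TRUE` for genes that pass.
#' @export
prefilterGenes <- function(counts, minCount = 10, minSamples = 3) {
    if (is(counts, "CellCountSet")) counts <- BiocGenerics::counts(counts)
    counts <- as.matrix(counts)
    stopifnot(minCount >= 0, minSamples >= 1)
    if (minSamples > ncol(counts))
        warning("minSamples (", minSamples, ") exceeds the number of ",
                "samples (", ncol(counts), "); all genes fail the filter")
    setNames(rowSums(counts >= minCount) >= minSamples, rownames(counts))
}
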