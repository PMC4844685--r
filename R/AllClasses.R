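#' @importFrom methods new validObject is setClass setValidity show slot
#' @importFrom stats median rnorm rbinom rnbinom rlnorm runif setNames
#'   quantile sd var pt wilcox.test p.adjust plogis qlogis
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

.CELL_TYPES <- c("microglia", "astrocyte", "neuron", "bulk")

#' Container for sorted-cell / bulk RNA-seq counts
#'
#' `CellCountSet` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds a gene-by-sample matrix of reads overlapping exons of each gene
#' model, together with the two pieces of metadata every downstream step
#' needs: the union-exon length of each gene (`rowData(x)$gene_length_bp`)
#' and, per sample, the total number of uniquely aligned reads
#' (`colData(x)$total_uniq_reads`), the condition, and the cell type
#' (one of `"microglia"`, `"astrocyte"`, `"neuron"` or `"bulk"`).
#'
#' Column totals of the count matrix need not match `total_uniq_reads`:
#' the totals also include intronic and intergenic alignments, which is
#' why they are carried separately rather than recomputed from counts.
#'
#' @rdname CellCountSet
#' @export
setClass("CellCountSet", contains = "SummarizedExperiment")

setValidity("CellCountSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
        if (any(abs(cts - round(cts)) > 1e-8))
            msg <- c(msg, "counts must be integral")
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!"gene_length_bp" %in% colnames(rd))
        msg <- c(msg, "rowData column 'gene_length_bp' is required")
    else if (any(rd$gene_length_bp <= 0))
        msg <- c(msg, "all gene lengths must be > 0")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("condition", "cell_type", "total_uniq_reads"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if ("total_uniq_reads" %in% colnames(cd) &&
        any(cd$total_uniq_reads <= 0))
        msg <- c(msg, "all total_uniq_reads must be > 0")
    if ("cell_type" %in% colnames(cd)) {
        bad <- setdiff(unique(cd$cell_type), .CELL_TYPES)
        if (length(bad))
            msg <- c(msg, sprintf("unknown cell_type value(s): %s",
                                  paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' @param counts integer matrix of reads per gene (rows) and sample
#'   (columns); dimnames are required.
#' @param geneLength positive lengths (bp) of the union of each gene's
#'   exons, in row order or named by gene.
#' @param sampleData `data.frame` with one row per sample and columns
#'   `condition`, `cell_type` and `total_uniq_reads`; a `sample_id` column,
#'   if present, must match the count matrix column names.
#'
#' @return `CellCountSet()` returns a validated `CellCountSet`.
#' @examples
#' cts <- matrix(rpois(12, 50), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cs <- CellCountSet(cts, geneLength = c(1000, 2000, 500),
#'                    sampleData = data.frame(
#'                        condition = rep(c("control", "disease"), 2),
#'                        cell_type = "bulk",
#'                        total_uniq_reads = rep(1e6, 4)))
#' geneLengths(cs)
#' @rdname CellCountSet
#' @export
CellCountSet <- function(counts, geneLength, sampleData) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must have row (gene) and column (sample) names")
    if (!is.null(names(geneLength)))
        geneLength <- geneLength[rownames(counts)]
    if (length(geneLength) != nrow(counts))
        stop("'geneLength' must supply one length per gene")
    if ("sample_id" %in% colnames(sampleData)) {
        if (anyDuplicated(sampleData$sample_id))
            stop("duplicate sample_id in sampleData: ",
                 paste(unique(sampleData$sample_id[
                     duplicated(sampleData$sample_id)]), collapse = ", "))
        rownames(sampleData) <- sampleData$sample_id
        sampleData <- sampleData[colnames(counts), , drop = FALSE]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_length_bp = as.numeric(geneLength)),
        colData = S4Vectors::DataFrame(sampleData))
    new("CellCountSet", se)
}

#' Per-sample size factors with adjusted total reads
#'
#' Holds the median-of-ratios size factor of each sample (anchored so the
#' geometric mean of the factors is 1) and, once calibrated against the
#' samples' total uniquely aligned reads, the "adjusted total reads"
#' statistic used as the M term of nRPKM. Adjusted totals are proportional
#' to the size factors and conserve the project-wide read total.
#'
#' @seealso [computeSizeFactors()], [computeAdjustedTotals()]
#' @rdname SizeFactors
#' @export
setClass("SizeFactors",
         representation(factors = "numeric", adjustedTotals = "numeric"))

setValidity("SizeFactors", function(object) {
    msg <- character()
    if (any(object@factors <= 0) || any(!is.finite(object@factors)))
        msg <- c(msg, "all size factors must be finite and > 0")
    n <- length(object@adjustedTotals)
    if (n && n != length(object@factors))
        msg <- c(msg, "adjustedTotals must match factors in length")
    if (n && any(object@adjustedTotals <= 0))
        msg <- c(msg, "all adjusted totals must be > 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SizeFactors", function(object) {
    cat(sprintf("SizeFactors for %d sample(s)\n", length(object@factors)))
    print(signif(object@factors, 4))
    if (length(object@adjustedTotals)) {
        cat("adjusted total reads:\n")
        print(signif(object@adjustedTotals, 4))
    } else cat("adjusted totals: not yet calibrated\n")
})

#' Mean reference expression of each gene in three sorted cell types
#'
#' A genes-by-3 matrix of mean normalized expression (nRPKM) in the three
#' sorted cell populations. The cell-type order is explicit metadata: the
#' simplex projection maps the first, second and third listed type to the
#' triangle corners (-1, 0), (1, 0) and (0, sqrt(3)) respectively.
#'
#' @rdname CellTypeProfile
#' @export
setClass("CellTypeProfile",
         representation(means = "matrix", cellTypes = "character"))

setValidity("CellTypeProfile", function(object) {
    msg <- character()
    if (length(object@cellTypes) != 3L)
        msg <- c(msg, "exactly three cell types are required")
    if (ncol(object@means) != 3L)
        msg <- c(msg, "'means' must have three columns (one per cell type)")
    if (any(object@means < 0))
        msg <- c(msg, "mean expression must be nonnegative")
    if (is.null(rownames(object@means)))
        msg <- c(msg, "'means' must have gene row names")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CellTypeProfile", function(object) {
    cat(sprintf("CellTypeProfile: %d genes x (%s)\n",
                nrow(object@means), paste(object@cellTypes, collapse = ", ")))
    print(head(signif(object@means, 4), 4))
    if (nrow(object@means) > 4) cat("...\n")
})

#' Genes with strongly cell-type-specific reference expression
#'
#' A marker set records the genes whose reference expression in one cell
#' type exceeds a fold threshold relative to each of the other two types
#' (after adding a pseudocount), along with the threshold and pseudocount
#' used so the selection is reproducible.
#'
#' @rdname MarkerSet
#' @export
setClass("MarkerSet",
         representation(cellType = "character", genes = "character",
                        fold = "numeric", pseudocount = "numeric"))

setValidity("MarkerSet", function(object) {
    msg <- character()
    if (length(object@cellType) != 1L)
        msg <- c(msg, "cellType must be a single string")
    if (object@fold <= 1) msg <- c(msg, "fold threshold must be > 1")
    if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MarkerSet", function(object) {
    cat(sprintf("MarkerSet '%s': %d genes (fold >= %g, pseudocount %g)\n",
                object@cellType, length(object@genes), object@fold,
                object@pseudocount))
})
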