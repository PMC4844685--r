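#' Accessors for triCell classes
#'
#' `geneLengths()` returns the per-gene union-exon length (bp);
#' `totalUniqReads()` the per-sample total uniquely aligned reads;
#' `cellTypes()` the cell-type labels; `adjustedTotals()` the calibrated
#' per-sample adjusted total reads of a [SizeFactors] object;
#' `markerGenes()` the gene identifiers of a [MarkerSet].
#' `sizeFactors()` (the [BiocGenerics::sizeFactors] generic) returns the
#' numeric factors themselves.
#'
#' @param x,object a `CellCountSet`, `SizeFactors`, `CellTypeProfile` or
#'   `MarkerSet` as appropriate.
#' @return a named numeric or character vector (see above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname accessors
#' @export
setMethod("geneLengths", "CellCountSet", function(x)
    setNames(SummarizedExperiment::rowData(x)$gene_length_bp, rownames(x)))

#' @rdname accessors
#' @export
setGeneric("totalUniqReads", function(x) standardGeneric("totalUniqReads"))

#' @rdname accessors
#' @export
setMethod("totalUniqReads", "CellCountSet", function(x)
    setNames(SummarizedExperiment::colData(x)$total_uniq_reads, colnames(x)))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setMethod("cellTypes", "CellCountSet", function(x)
    setNames(as.character(SummarizedExperiment::colData(x)$cell_type),
             colnames(x)))

#' @rdname accessors
#' @export
setMethod("cellTypes", "CellTypeProfile", function(x) x@cellTypes)

#' @importFrom BiocGenerics sizeFactors
#' @rdname accessors
#' @export
setMethod("sizeFactors", "SizeFactors", function(object) object@factors)

#' @rdname accessors
#' @export
setGeneric("adjustedTotals", function(x) standardGeneric("adjustedTotals"))

#' @rdname accessors
#' @export
setMethod("adjustedTotals", "SizeFactors", function(x) {
    if (!length(x@adjustedTotals))
        stop("adjusted totals not calibrated; run computeAdjustedTotals()")
    x@adjustedTotals
})

#' @rdname accessors
#' @export
setGeneric("profileMeans", function(x) standardGeneric("profileMeans"))

#' @rdname accessors
#' @export
setMethod("profileMeans", "CellTypeProfile", function(x) x@means)

#' @rdname accessors
#' @export
setGeneric("markerGenes", function(x) standardGeneric("markerGenes"))

#' @rdname accessors
#' @export
setMethod("markerGenes", "MarkerSet", function(x) x@genes)

#' @importFrom BiocGenerics counts
#' @rdname accessors
#' @export
setMethod("counts", "CellCountSet", function(object)
    SummarizedExperiment::assay(object, "counts"))
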