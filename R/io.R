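## TSV readers/writers for all table formats, and gene-length derivation
## from a GTF gene model. All files are UTF-8 TSV with a header row;
## undefined values are written as NA; numeric output keeps full
## precision so write -> read round-trips are identities.

#' Union-exon gene lengths from a GTF gene model
#'
#' Imports the exon features of a GTF (1-based inclusive coordinates),
#' merges overlapping exons per gene (strand ignored for length) and
#' sums the merged widths. Genes without exon features are absent from
#' the result.
#'
#' @param gtf path to a GTF file whose exon records carry a `gene_id`
#'   attribute.
#' @return named numeric vector of union-exon lengths (bp).
#' @examples
#' \dontrun{len <- computeGeneLengths("genes.gtf")}
#' @export
computeGeneLengths <- function(gtf) {
    gr <- rtracklayer::import(gtf, format = "gtf")
    ex <- gr[gr$type == "exon"]
    if (!length(ex)) stop("no exon features found in ", gtf)
    if (is.null(ex$gene_id)) stop("exon features lack gene_id attributes")
    noExon <- setdiff(unique(gr$gene_id), unique(ex$gene_id))
    if (length(noExon))
        warning("gene(s) without exon features omitted: ",
                paste(noExon, collapse = ", "))
    GenomicRanges::strand(ex) <- "*"
    byGene <- GenomicRanges::split(ex, ex$gene_id)
    len <- sum(GenomicRanges::width(GenomicRanges::reduce(byGene)))
    setNames(as.numeric(len), names(len))
}

.readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write any table as TSV
#'
#' Tab-separated, UTF-8, header row, `NA` for undefined values, full
#' numeric precision (15 significant digits).
#'
#' @param x `data.frame` (or matrix with a leading id taken from row
#'   names via `rowLabel`).
#' @param path output path.
#' @param rowLabel when `x` is a matrix, the header of the row-name
#'   column (e.g. `"gene_id"`); `NULL` for data.frames.
#' @export
writeTsv <- function(x, path, rowLabel = NULL) {
    if (!is.null(rowLabel)) {
        ids <- rownames(x)
        body <- x
        rownames(body) <- NULL          # ids may repeat; keep them as data
        x <- data.frame(setNames(list(ids), rowLabel),
                        as.data.frame(body), check.names = FALSE,
                        stringsAsFactors = FALSE)
    }
    old <- options(digits = 15); on.exit(options(old))
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
}

#' Read a gene-by-sample count matrix
#'
#' Expects a header row, first column `gene_id`, and integer cells.
#' Duplicate gene ids, negative or non-integer counts are errors that
#' name the offending line.
#'
#' @param path TSV path.
#' @return integer matrix with gene row names.
#' @export
readCounts <- function(path) {
    d <- .readTsv(path)
    if (colnames(d)[1] != "gene_id")
        stop("first column of a count matrix must be 'gene_id'")
    dup <- duplicated(d$gene_id)
    if (any(dup))
        stop("duplicate gene_id '", d$gene_id[which(dup)[1]], "' at line ",
             which(dup)[1] + 1L)
    m <- as.matrix(d[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("count cells must be numeric")
    bad <- which(m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
    if (nrow(bad))
        stop("non-integer or negative count for gene '",
             d$gene_id[bad[1, 1]], "' at line ", bad[1, 1] + 1L)
    storage.mode(m) <- "integer"
    rownames(m) <- d$gene_id
    m
}

#' Read a sample sheet
#'
#' Columns `sample_id`, `condition`, `cell_type`, `total_uniq_reads`;
#' `cell_type` must be one of microglia, astrocyte, neuron or bulk.
#' Duplicate sample ids and non-positive totals are errors naming the
#' line.
#'
#' @param path TSV path.
#' @return validated `data.frame`.
#' @export
readSampleSheet <- function(path) {
    d <- .readTsv(path)
    need <- c("sample_id", "condition", "cell_type", "total_uniq_reads")
    miss <- setdiff(need, colnames(d))
    if (length(miss))
        stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
    dup <- duplicated(d$sample_id)
    if (any(dup))
        stop("duplicate sample_id '", d$sample_id[which(dup)[1]],
             "' at line ", which(dup)[1] + 1L)
    bad <- !d$cell_type %in% .CELL_TYPES
    if (any(bad))
        stop("unknown cell_type '", d$cell_type[which(bad)[1]],
             "' at line ", which(bad)[1] + 1L)
    if (any(d$total_uniq_reads <= 0))
        stop("total_uniq_reads must be positive (line ",
             which(d$total_uniq_reads <= 0)[1] + 1L, ")")
    d
}

#' Read a gene-length table
#'
#' Columns `gene_id` and `length_bp` (positive).
#'
#' @param path TSV path.
#' @return named numeric vector of lengths.
#' @export
readGeneLengths <- function(path) {
    d <- .readTsv(path)
    if (!all(c("gene_id", "length_bp") %in% colnames(d)))
        stop("gene length table needs columns gene_id and length_bp")
    if (any(d$length_bp <= 0))
        stop("gene lengths must be positive (line ",
             which(d$length_bp <= 0)[1] + 1L, ")")
    setNames(as.numeric(d$length_bp), d$gene_id)
}

#' Read a differential-expression table
#'
#' Accepts externally computed differential results (e.g. from an NB GLM
#' engine) in the package's DE layout: `gene_id`, `log2_fc`, `p_value`,
#' `adj_p`, `prefilter_pass`, and optionally `mean_ctrl`, `mean_trt`.
#' An empty `adj_p` field (NA) marks genes excluded from multiple
#' testing.
#'
#' @param path TSV path.
#' @return `data.frame` usable wherever [assembleDeTable()] output is.
#' @export
readDeTable <- function(path) {
    d <- .readTsv(path)
    need <- c("gene_id", "log2_fc", "p_value", "adj_p", "prefilter_pass")
    miss <- setdiff(need, colnames(d))
    if (length(miss))
        stop("DE table lacks column(s): ", paste(miss, collapse = ", "))
    d$prefilter_pass <- as.logical(d$prefilter_pass)
    d
}

#' Read a splicing event table
#'
#' Long format: `event_id`, `variant_id`, `role`, `retained_intron`,
#' `same_features`, `sample_id`, `count5p`, `count3p`.
#'
#' @param path TSV path.
#' @return validated `data.frame` for [summarizeVariantCounts()].
#' @export
readEventTable <- function(path) {
    d <- .readTsv(path)
    .checkEventTable(d)
    d$retained_intron <- as.logical(d$retained_intron)
    d$same_features <- as.logical(d$same_features)
    d
}

#' Read a qPCR plate table
#'
#' Long format: `sample_id`, `cell_type`, `condition`, `assay_id`,
#' `assay_role`, `replicate_idx`, `ct`, `pass`.
#'
#' @param path TSV path.
#' @return validated `data.frame` for [summarizeCt()].
#' @export
readQpcrPlate <- function(path) {
    d <- .readTsv(path)
    d$pass <- as.logical(d$pass)
    .checkPlate(d)
    d
}

#' Write marker sets as TSV
#'
#' One row per marker gene: `cell_type`, `gene_id`, `fold_min`.
#'
#' @param markers named list of [MarkerSet] from [selectMarkers()].
#' @param path output path.
#' @export
writeMarkerSets <- function(markers, path) {
    rows <- lapply(markers, function(ms)
        if (length(markerGenes(ms)))
            data.frame(cell_type = ms@cellType, gene_id = markerGenes(ms),
                       fold_min = ms@fold, stringsAsFactors = FALSE)
        else NULL)
    writeTsv(do.call(rbind, c(rows, list(make.row.names = FALSE))), path)
}
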