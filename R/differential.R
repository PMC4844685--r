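## Two-group differential expression with the pre-filter bookkeeping the
## attribution pipeline expects. The test itself is a Welch t on
## log2(size-factor-normalized counts + 1); any externally produced table
## in the same layout (e.g. from an NB GLM engine) can be substituted via
## readDeTable().

.rowWelch <- function(x, g1, g2) {
    n1 <- length(g1); n2 <- length(g2)
    m1 <- rowMeans(x[, g1, drop = FALSE])
    m2 <- rowMeans(x[, g2, drop = FALSE])
    v1 <- rowSums((x[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
    v2 <- rowSums((x[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tstat), df)
    ## degenerate rows: both groups constant
    zero <- se2 == 0
    p[zero] <- ifelse(m2[zero] == m1[zero], 1, 0)
    list(diff = m2 - m1, p = p)
}

#' Two-group differential test on normalized expression
#'
#' Computes, per gene, the difference of group means of
#' `log2(normalized + 1)` (treatment minus control) and a Welch two-sample
#' t p-value on the same transformed values. With large expression values
#' the mean difference approaches the log2 fold change; the pseudocount of
#' 1 bounds fold changes for weakly expressed genes.
#'
#' @param x gene-by-sample matrix of size-factor-normalized values (counts
#'   divided by their size factor, or an nRPKM matrix), or raw counts
#'   together with `sizeFactors`.
#' @param groups per-sample group labels (two levels).
#' @param control label of the reference group; defaults to the first
#'   factor level of `groups`.
#' @param sizeFactors optional [SizeFactors] used to normalize raw counts
#'   before transformation.
#' @return `data.frame` with columns `gene_id`, `log2_fc`, `p_value`,
#'   `mean_ctrl`, `mean_trt` (group means on the normalized linear scale).
#' @seealso [assembleDeTable()] to add BH correction with pre-filter
#'   conventions.
#' @export
testTwoGroups <- function(x, groups, control = NULL, sizeFactors = NULL) {
    if (is(x, "CellCountSet")) x <- BiocGenerics::counts(x)
    x <- as.matrix(x)
    if (!is.null(sizeFactors))
        x <- sweep(x, 2, sizeFactors(sizeFactors), "/")
    groups <- as.factor(groups)
    if (nlevels(droplevels(groups)) != 2L)
        stop("'groups' must have exactly two levels")
    groups <- droplevels(groups)
    if (is.null(control)) control <- levels(groups)[1]
    if (!control %in% levels(groups))
        stop("control level '", control, "' not found in groups")
    trt <- setdiff(levels(groups), control)
    g1 <- which(groups == control)
    g2 <- which(groups == trt)
    for (gg in list(c(control, length(g1)), c(trt, length(g2))))
        if (as.integer(gg[2]) < 2L)
            stop("group '", gg[1], "' has fewer than 2 samples")
    res <- .rowWelch(log2(x + 1), g1, g2)
    data.frame(gene_id = rownames(x),
               log2_fc = unname(res$diff),
               p_value = unname(res$p),
               mean_ctrl = unname(rowMeans(x[, g1, drop = FALSE])),
               mean_trt = unname(rowMeans(x[, g2, drop = FALSE])),
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, capped at 1. Missing or NaN p-values are an error rather
#' than silently dropped, because the family size defines the correction.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjustBH <- function(p) {
    if (any(is.na(p))) stop("NA/NaN p-values are not allowed in adjustBH()")
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Assemble a differential-expression table with pre-filter conventions
#'
#' Genes failing the pre-filter get `p_value = 1`, `log2_fc = 0` and an
#' undefined (`NA`) adjusted p, and are excluded from the BH family: the
#' correction denominator is the number of passing genes only.
#'
#' @param stats output of [testTwoGroups()] (or an equivalent table with
#'   `gene_id`, `log2_fc`, `p_value` and optionally group means).
#' @param prefilterPass named logical from [prefilterGenes()], covering the
#'   same gene universe.
#' @return `data.frame` with columns `gene_id`, `log2_fc`, `p_value`,
#'   `adj_p`, `prefilter_pass`, `mean_ctrl`, `mean_trt`.
#' @export
assembleDeTable <- function(stats, prefilterPass) {
    if (is.null(names(prefilterPass)))
        stop("'prefilterPass' must be named by gene")
    if (!setequal(stats$gene_id, names(prefilterPass)))
        stop("gene universes of 'stats' and 'prefilterPass' differ")
    pass <- unname(prefilterPass[stats$gene_id])
    out <- data.frame(gene_id = stats$gene_id,
                      log2_fc = stats$log2_fc,
                      p_value = stats$p_value,
                      adj_p = NA_real_,
                      prefilter_pass = pass,
                      mean_ctrl = if ("mean_ctrl" %in% names(stats))
                          stats$mean_ctrl else NA_real_,
                      mean_trt = if ("mean_trt" %in% names(stats))
                          stats$mean_trt else NA_real_,
                      stringsAsFactors = FALSE)
    out$log2_fc[!pass] <- 0
    out$p_value[!pass] <- 1
    if (any(pass)) out$adj_p[pass] <- adjustBH(out$p_value[pass])
    out
}
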