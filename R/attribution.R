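## Core attribution machinery: reference profiles from sorted cells,
## ternary-simplex projection, marker selection, attribution of bulk
## differential genes to cell types, composition-vs-regulation
## classification, and the distribution-shift diagnostic, plus the
## heat-map / variable-gene / probe-collapse utilities that support them.

.SIMPLEX_PROJ <- rbind(c(-1, 1, 0), c(0, 0, sqrt(3)))

#' Build mean reference profiles from sorted-cell expression
#'
#' Averages normalized expression (nRPKM) within each of exactly three
#' sorted cell types. The resulting per-gene three-vector is the reference
#' used for marker selection, simplex projection and attribution.
#'
#' @param expr gene-by-sample nRPKM matrix, or a `CellCountSet` (then
#'   nRPKM is computed internally).
#' @param cellType per-sample cell-type labels; taken from `colData` when
#'   `expr` is a `CellCountSet`.
#' @param cellTypeOrder the three cell types, in the order that fixes the
#'   triangle corners (default `c("microglia", "astrocyte", "neuron")`).
#' @return a [CellTypeProfile].
#' @export
buildReferenceProfiles <- function(expr, cellType = NULL,
                                   cellTypeOrder = c("microglia",
                                                     "astrocyte",
                                                     "neuron")) {
    if (length(cellTypeOrder) != 3L)
        stop("exactly three cell types are required")
    if (is(expr, "CellCountSet")) {
        if (is.null(cellType)) cellType <- cellTypes(expr)
        expr <- computeExpression(expr, mode = "nRPKM")
    }
    expr <- as.matrix(expr)
    cellType <- as.character(cellType)
    missing <- setdiff(cellTypeOrder, unique(cellType))
    if (length(missing))
        stop("no samples for cell type(s): ", paste(missing, collapse = ", "))
    means <- vapply(cellTypeOrder, function(ct)
        rowMeans(expr[, cellType == ct, drop = FALSE]),
        numeric(nrow(expr)))
    if (nrow(expr) == 1L) {        # vapply drops to vector for 1 gene
        means <- matrix(means, nrow = 1,
                        dimnames = list(rownames(expr), cellTypeOrder))
    }
    colnames(means) <- cellTypeOrder
    new("CellTypeProfile", means = means, cellTypes = cellTypeOrder)
}

#' Project three-cell-type profiles onto the ternary simplex
#'
#' Each gene's three-type mean expression vector is normalized to sum 1,
#' placing it on the plane x + y + z = 1, and mapped to the plane of the
#' page by the matrix `[[-1, 1, 0], [0, 0, sqrt(3)]]`. Pure expression in
#' the first, second or third listed cell type lands exactly on the
#' corners (-1, 0), (1, 0) and (0, sqrt(3)) of an equilateral triangle of
#' side 2; proximity to a corner measures preferential expression in that
#' type. Genes with zero expression in all three types cannot be placed
#' and are excluded (recorded in the `"excluded"` attribute).
#'
#' @param profile a [CellTypeProfile] or a nonnegative genes-by-3 matrix
#'   with row names.
#' @return `data.frame` with columns `gene_id`, `f1`, `f2`, `f3`
#'   (composition fractions summing to 1), `x`, `y`; excluded genes are
#'   listed in `attr(, "excluded")` with a reason.
#' @examples
#' projectToSimplex(matrix(c(5, 0, 0), 1, 3,
#'                  dimnames = list("pure1", NULL)))  # x = -1, y = 0
#' @export
projectToSimplex <- function(profile) {
    m <- if (is(profile, "CellTypeProfile")) profileMeans(profile)
         else as.matrix(profile)
    if (ncol(m) != 3L) stop("a genes-by-3 matrix is required")
    if (any(m < 0)) stop("expression must be nonnegative")
    tot <- rowSums(m)
    keep <- tot > 0
    excluded <- data.frame(gene_id = rownames(m)[!keep],
                           reason = rep("zero expression in all three cell types",
                                        sum(!keep)),
                           stringsAsFactors = FALSE)
    f <- m[keep, , drop = FALSE] / tot[keep]
    xy <- f %*% t(.SIMPLEX_PROJ)
    out <- data.frame(gene_id = rownames(m)[keep],
                      f1 = unname(f[, 1]), f2 = unname(f[, 2]),
                      f3 = unname(f[, 3]),
                      x = unname(xy[, 1]), y = unname(xy[, 2]),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    out
}

#' Select cell-type-specific marker genes
#'
#' A gene is a marker of a cell type when its pseudocounted reference
#' expression is at least `fold` times that of each of the other two
#' types. The default 20-fold threshold selects genes specific enough
#' that their bulk-tissue abundance tracks their cell type's tissue
#' fraction; the pseudocount keeps ratios finite for genes undetected in
#' the other types. Marker sets are disjoint across types for `fold > 1`.
#'
#' @param profile a [CellTypeProfile].
#' @param fold enrichment threshold (> 1; default 20).
#' @param pseudocount added to every expression value before forming
#'   ratios (default 0.1 nRPKM).
#' @return named list of three [MarkerSet] objects, one per cell type.
#' @export
selectMarkers <- function(profile, fold = 20, pseudocount = 0.1) {
    stopifnot(is(profile, "CellTypeProfile"))
    if (fold <= 1) stop("'fold' must be > 1")
    m <- profileMeans(profile) + pseudocount
    sets <- lapply(seq_len(3), function(i) {
        others <- setdiff(seq_len(3), i)
        hit <- m[, i] >= fold * m[, others[1]] &
               m[, i] >= fold * m[, others[2]]
        new("MarkerSet", cellType = cellTypes(profile)[i],
            genes = rownames(m)[hit], fold = fold,
            pseudocount = pseudocount)
    })
    setNames(sets, cellTypes(profile))
}

#' Attribute significant bulk changes to cell types
#'
#' For each bulk gene passing the significance cutoffs
#' (`|log2_fc| >= log2(fcCut)` and `adj_p <= pCut`), the gene's reference
#' composition fractions become its contribution shares, and the gene is
#' assigned to the cell type with the largest share when that share
#' reaches `shareCut`; otherwise the call is `"mixed"`. A share tie is
#' broken towards the type with higher absolute reference expression
#' (which, for normalized shares, is the same ordering) and then by
#' cell-type order. Genes absent from the profile, or expressed in none of
#' the three types, are `"unassigned"`.
#'
#' @param bulkDe a differential table from [assembleDeTable()] for the
#'   bulk-tissue contrast.
#' @param profile the sorted-cell [CellTypeProfile] (reference condition).
#' @param fcCut,pCut significance cutoffs on the bulk contrast (defaults
#'   2-fold, adjusted p 0.05).
#' @param shareCut minimum winning share for a single-type assignment
#'   (default 0.5).
#' @return `data.frame` with one row per significant bulk gene: `gene_id`,
#'   `log2_fc_bulk`, `adj_p_bulk`, `share_t1`..`share_t3` (profile order),
#'   `assigned` (a cell type, `"mixed"` or `"unassigned"`) and
#'   `change_mode` (filled by [classifyChangeMode()], initialised to
#'   `"unassigned"`); the profile's cell-type order is kept in
#'   `attr(, "cellTypes")`.
#' @export
attributeBulkChanges <- function(bulkDe, profile, fcCut = 2, pCut = 0.05,
                                 shareCut = 0.5) {
    stopifnot(is(profile, "CellTypeProfile"))
    sig <- !is.na(bulkDe$adj_p) & bulkDe$adj_p <= pCut &
        abs(bulkDe$log2_fc) >= log2(fcCut)
    de <- bulkDe[sig, , drop = FALSE]
    m <- profileMeans(profile)
    out <- data.frame(gene_id = de$gene_id,
                      log2_fc_bulk = de$log2_fc,
                      adj_p_bulk = de$adj_p,
                      share_t1 = rep(NA_real_, nrow(de)),
                      share_t2 = rep(NA_real_, nrow(de)),
                      share_t3 = rep(NA_real_, nrow(de)),
                      assigned = rep("unassigned", nrow(de)),
                      change_mode = rep("unassigned", nrow(de)),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(out))) {
        g <- out$gene_id[i]
        if (!g %in% rownames(m)) next
        v <- m[g, ]
        if (sum(v) <= 0) next
        f <- v / sum(v)
        out[i, c("share_t1", "share_t2", "share_t3")] <- f
        top <- max(f)
        if (top >= shareCut) {
            winners <- which(f == top)
            if (length(winners) > 1L)     # tie: higher absolute expression,
                winners <- winners[which.max(v[winners])] # then type order
            out$assigned[i] <- cellTypes(profile)[winners[1]]
        } else out$assigned[i] <- "mixed"
    }
    attr(out, "cellTypes") <- cellTypes(profile)
    out
}

#' Classify attributed changes as composition- or regulation-driven
#'
#' A bulk change assigned to a cell type is *regulation* when that type's
#' sorted-cell contrast shows a significant change in the same direction
#' and the type has no composition prior; *both* when the sorted change is
#' significant in the same direction and the type's tissue fraction is
#' known (or simulated) to differ between conditions; *composition* when
#' the bulk change is significant but the assigned type's sorted contrast
#' is not and the type carries a composition prior. Anything else —
#' including a sorted change significant in the opposite direction, or an
#' unchanged type with no composition prior — stays `"unassigned"`.
#'
#' @param calls output of [attributeBulkChanges()].
#' @param sortedDe named list of differential tables
#'   ([assembleDeTable()]), one per cell type, for the sorted-cell
#'   contrasts.
#' @param fcCut,pCut significance cutoffs applied to the sorted contrasts.
#' @param compositionTypes cell types whose tissue fraction differs
#'   between conditions (from external knowledge — e.g. histology — or
#'   simulation truth).
#' @return `calls` with `change_mode` filled in.
#' @export
classifyChangeMode <- function(calls, sortedDe, fcCut = 2, pCut = 0.05,
                               compositionTypes = character()) {
    cellTypes <- attr(calls, "cellTypes")
    warned <- character()
    for (i in seq_len(nrow(calls))) {
        ct <- calls$assigned[i]
        if (!ct %in% cellTypes) next          # mixed / unassigned
        if (is.null(sortedDe[[ct]])) {
            if (!ct %in% warned) {
                warning("no sorted-cell differential table for '", ct,
                        "'; its genes stay unassigned")
                warned <- c(warned, ct)
            }
            next
        }
        tab <- sortedDe[[ct]]
        j <- match(calls$gene_id[i], tab$gene_id)
        if (is.na(j)) {
            warning("gene ", calls$gene_id[i],
                    " missing from sorted table for '", ct, "'")
            next
        }
        sigSameDir <- !is.na(tab$adj_p[j]) && tab$adj_p[j] <= pCut &&
            abs(tab$log2_fc[j]) >= log2(fcCut) &&
            sign(tab$log2_fc[j]) == sign(calls$log2_fc_bulk[i])
        sigAnyDir <- !is.na(tab$adj_p[j]) && tab$adj_p[j] <= pCut &&
            abs(tab$log2_fc[j]) >= log2(fcCut)
        hasPrior <- ct %in% compositionTypes
        calls$change_mode[i] <-
            if (sigSameDir && hasPrior) "both"
            else if (sigSameDir) "regulation"
            else if (!sigAnyDir && hasPrior) "composition"
            else "unassigned"
    }
    calls
}

#' Marker fold-change distribution-shift diagnostic
#'
#' Compares the bulk-contrast log2 fold-change distribution of each cell
#' type's markers against all non-marker genes. A rightward marker shift
#' is consistent with a higher content of that cell type in the affected
#' tissue; for a pure marker the expected shift equals the log2 ratio of
#' the type's tissue fractions. Only genes passing the bulk pre-filter
#' contribute (filtered genes carry the sentinel fold change 0). The
#' location shift is tested with a two-sided Wilcoxon rank-sum test.
#'
#' @param markers named list of [MarkerSet] objects from
#'   [selectMarkers()].
#' @param bulkDe bulk differential table ([assembleDeTable()]).
#' @return `data.frame` with one row per cell type: `cell_type`,
#'   `n_markers`, `median_lfc_markers`, `median_lfc_background`, `shift`
#'   (difference of the medians) and `p_value`.
#' @export
markerShiftDiagnostic <- function(markers, bulkDe) {
    de <- bulkDe[bulkDe$prefilter_pass, , drop = FALSE]
    rows <- lapply(markers, function(ms) {
        inSet <- de$gene_id %in% markerGenes(ms)
        n <- sum(inSet)
        if (n == 0L) {
            warning("no markers for '", ms@cellType,
                    "' in the differential table; skipped")
            return(data.frame(cell_type = ms@cellType, n_markers = 0L,
                              median_lfc_markers = NA_real_,
                              median_lfc_background = NA_real_,
                              shift = NA_real_, p_value = NA_real_,
                              stringsAsFactors = FALSE))
        }
        if (n < 5L)
            warning("only ", n, " markers for '", ms@cellType,
                    "'; the shift estimate is unstable")
        mk <- de$log2_fc[inSet]
        bg <- de$log2_fc[!inSet]
        p <- suppressWarnings(
            wilcox.test(mk, bg, alternative = "two.sided",
                        exact = FALSE)$p.value)
        data.frame(cell_type = ms@cellType, n_markers = n,
                   median_lfc_markers = median(mk),
                   median_lfc_background = median(bg),
                   shift = median(mk) - median(bg), p_value = p,
                   stringsAsFactors = FALSE)
    })
    .rbindRows(rows)
}

#' Floored, dataset-wise Z-scored log2 matrix for heat maps
#'
#' Values are log2-transformed, floored at `floor` (any log2 value below
#' it, including log2(0) = -Inf, is set to the floor), then Z-scored per
#' gene separately within each dataset label, and finally Z-scores above
#' `cap` are set to `cap`. A gene row with zero variance within a dataset
#' gets Z = 0 there.
#'
#' @param expr nonnegative gene-by-sample matrix (nRPKM).
#' @param datasetLabels per-sample dataset labels defining the Z-scoring
#'   groups (a single label Z-scores across all samples).
#' @param floor,cap floor on log2 values and cap on Z-scores
#'   (defaults -4 and 4; `floor < cap` required).
#' @return matrix of capped Z-scores, same dimensions as `expr`.
#' @export
heatmapZscoreMatrix <- function(expr, datasetLabels = rep("all", ncol(expr)),
                                floor = -4, cap = 4) {
    expr <- as.matrix(expr)
    if (floor >= cap) stop("'floor' must be less than 'cap'")
    if (any(expr < 0)) stop("expression must be nonnegative")
    if (length(datasetLabels) != ncol(expr))
        stop("one dataset label per sample is required")
    L <- log2(expr)
    L[L < floor] <- floor
    Z <- L
    for (lab in unique(datasetLabels)) {
        j <- which(datasetLabels == lab)
        sub <- L[, j, drop = FALSE]
        mu <- rowMeans(sub)
        sdv <- apply(sub, 1, sd)
        z <- (sub - mu) / sdv
        z[sdv == 0, ] <- 0
        Z[, j] <- z
    }
    Z[Z > cap] <- cap
    Z
}

#' Select the most variable genes
#'
#' Returns the top `ceiling(fraction * nrow)` genes by per-gene standard
#' deviation across all samples, without regard to sample metadata. Ties
#' at the cutoff are broken by lexicographic gene identifier so the
#' selection is deterministic.
#'
#' @param expr matrix of transformed expression values (e.g.
#'   `log2(nRPKM + 1)`) with gene row names.
#' @param fraction fraction of genes to keep (default 0.025, i.e. the
#'   2.5% most variable).
#' @return character vector of gene identifiers, in decreasing order of
#'   standard deviation.
#' @export
selectVariableGenes <- function(expr, fraction = 0.025) {
    expr <- as.matrix(expr)
    if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
    sdv <- apply(expr, 1, sd)
    n <- ceiling(fraction * nrow(expr))
    ord <- order(-sdv, rownames(expr))
    rownames(expr)[ord[seq_len(n)]]
}

#' Collapse microarray probes to genes by highest IQR
#'
#' For each gene, the probe with the highest interquartile range across
#' all samples (without regard to sample metadata) is selected as the
#' gene's official row. IQR uses linear-interpolation quantiles; an IQR
#' tie is broken by the lexicographically smallest probe identifier.
#' Genes with no probes are absent from the output.
#'
#' @param probeMatrix probe-by-sample matrix with probe row names.
#' @param probeToGene `data.frame` with columns `probe_id` and `gene_id`
#'   (each probe mapping to at most one gene), or a named character vector
#'   `probe_id -> gene_id`.
#' @return gene-by-sample matrix; the chosen probe of each gene is
#'   recorded in `attr(, "probe_selected")`.
#' @export
collapseProbesByIQR <- function(probeMatrix, probeToGene) {
    probeMatrix <- as.matrix(probeMatrix)
    if (is.data.frame(probeToGene)) {
        map <- setNames(as.character(probeToGene$gene_id),
                        probeToGene$probe_id)
    } else map <- probeToGene
    if (anyDuplicated(names(map)))
        stop("a probe may map to at most one gene")
    map <- map[names(map) %in% rownames(probeMatrix)]
    iqr <- apply(probeMatrix[names(map), , drop = FALSE], 1,
                 function(x) unname(diff(quantile(x, c(0.25, 0.75)))))
    genes <- sort(unique(map))
    chosen <- vapply(genes, function(g) {
        probes <- sort(names(map)[map == g])   # lexicographic tie-break
        probes[which.max(iqr[probes])]
    }, character(1))
    out <- probeMatrix[chosen, , drop = FALSE]
    rownames(out) <- genes
    attr(out, "probe_selected") <- setNames(chosen, genes)
    out
}

#' Pair two differential contrasts for a four-way plot
#'
#' Pairs the fold changes of a shared gene universe across two contrasts
#' (e.g. the treatment response of two cell types). Genes below the
#' expression threshold in both conditions of a contrast are plotted as
#' unchanged (FC = 1, log2 fold change 0) for that contrast, and each gene
#' is categorised as significant in `a` only, `b` only, `both` or `none`
#' at the supplied cutoffs.
#'
#' @param deA,deB differential tables ([assembleDeTable()]) sharing a gene
#'   universe; their `mean_ctrl` / `mean_trt` columns supply the
#'   expression levels.
#' @param exprThreshold mean normalized expression below which (in both
#'   conditions) a gene is considered unexpressed in a contrast
#'   (default 1 nRPKM).
#' @param fcCut,pCut significance cutoffs for the categories.
#' @return `data.frame` with `gene_id`, `log2_fc_a`, `log2_fc_b`,
#'   `category` (`"a-only"`, `"b-only"`, `"both"`, `"none"`).
#' @export
prepareFourway <- function(deA, deB, exprThreshold = 1, fcCut = 2,
                           pCut = 0.05) {
    genes <- intersect(deA$gene_id, deB$gene_id)
    a <- deA[match(genes, deA$gene_id), ]
    b <- deB[match(genes, deB$gene_id), ]
    flat <- function(d) d$mean_ctrl < exprThreshold &
        d$mean_trt < exprThreshold
    fa <- flat(a); fb <- flat(b)
    lfcA <- ifelse(fa, 0, a$log2_fc)
    lfcB <- ifelse(fb, 0, b$log2_fc)
    sig <- function(d, isFlat) !isFlat & !is.na(d$adj_p) & d$adj_p <= pCut &
        abs(d$log2_fc) >= log2(fcCut)
    sa <- sig(a, fa); sb <- sig(b, fb)
    category <- ifelse(sa & sb, "both",
                ifelse(sa, "a-only", ifelse(sb, "b-only", "none")))
    data.frame(gene_id = genes, log2_fc_a = lfcA, log2_fc_b = lfcB,
               category = category, stringsAsFactors = FALSE)
}
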