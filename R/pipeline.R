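## End-to-end wrapper: from sorted-cell and bulk count sets to
## attribution calls, change-mode classification and marker-shift
## diagnostics.

#' Run the full bulk-attribution pipeline
#'
#' Normalizes the sorted and bulk count sets (nRPKM), builds reference
#' profiles from the sorted control samples, selects markers, tests the
#' bulk contrast and each sorted cell type's contrast, attributes
#' significant bulk changes to cell types, classifies each attributed
#' change as composition- or regulation-driven, and computes the
#' marker-shift diagnostic on the bulk contrast.
#'
#' @param sorted [CellCountSet] of sorted-cell samples (three cell
#'   types, both conditions).
#' @param bulk [CellCountSet] of bulk samples (both conditions).
#' @param control,treated the condition labels.
#' @param cellTypeOrder the three cell types, profile order.
#' @param markerFold,markerPseudocount marker selection parameters.
#' @param fcCut,pCut significance cutoffs used throughout.
#' @param shareCut minimum winning share for attribution.
#' @param compositionTypes cell types with a composition prior (tissue
#'   fraction known to differ between conditions).
#' @param minCount,minSamples gene pre-filter parameters.
#' @return list with `profile`, `markers`, `bulkDe`, `sortedDe` (named
#'   list per cell type), `calls` (attribution with change modes) and
#'   `shift` (marker-shift diagnostic table).
#' @export
attributionPipeline <- function(sorted, bulk, control, treated,
                                cellTypeOrder = c("microglia", "astrocyte",
                                                  "neuron"),
                                markerFold = 20, markerPseudocount = 0.1,
                                fcCut = 2, pCut = 0.05, shareCut = 0.5,
                                compositionTypes = character(),
                                minCount = 10, minSamples = 3) {
    ct <- cellTypes(sorted)
    cond <- SummarizedExperiment::colData(sorted)$condition
    ## reference profiles from control sorted samples
    ctrlIdx <- cond == control
    exprSorted <- computeExpression(sorted, mode = "nRPKM")
    profile <- buildReferenceProfiles(exprSorted[, ctrlIdx, drop = FALSE],
                                      ct[ctrlIdx], cellTypeOrder)
    markers <- selectMarkers(profile, fold = markerFold,
                             pseudocount = markerPseudocount)
    ## bulk contrast
    bulkDe <- deFromCounts(bulk, control = control, minCount = minCount,
                           minSamples = minSamples)
    ## sorted contrasts per cell type
    sortedDe <- setNames(lapply(cellTypeOrder, function(tt) {
        sub <- sorted[, ct == tt]
        deFromCounts(sub, control = control, minCount = minCount,
                     minSamples = minSamples)
    }), cellTypeOrder)
    calls <- attributeBulkChanges(bulkDe, profile, fcCut = fcCut,
                                  pCut = pCut, shareCut = shareCut)
    calls <- classifyChangeMode(calls, sortedDe, fcCut = fcCut,
                                pCut = pCut,
                                compositionTypes = compositionTypes)
    shift <- markerShiftDiagnostic(markers, bulkDe)
    list(profile = profile, markers = markers, bulkDe = bulkDe,
         sortedDe = sortedDe, calls = calls, shift = shift)
}

#' Differential table straight from a count set
#'
#' Convenience: size factors, pre-filter, two-group test on normalized
#' counts, and assembly with BH over passing genes.
#'
#' @param counts a [CellCountSet] whose `condition` column has two
#'   levels.
#' @param control reference condition.
#' @param minCount,minSamples pre-filter parameters.
#' @return a differential table ([assembleDeTable()]).
#' @export
deFromCounts <- function(counts, control, minCount = 10, minSamples = 3) {
    stopifnot(is(counts, "CellCountSet"))
    sf <- computeSizeFactors(counts)
    stats <- testTwoGroups(BiocGenerics::counts(counts),
                           SummarizedExperiment::colData(counts)$condition,
                           control = control, sizeFactors = sf)
    pass <- suppressWarnings(prefilterGenes(counts, minCount, minSamples))
    assembleDeTable(stats, pass)
}
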