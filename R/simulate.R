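## Negative-binomial simulator of a sorted-cell + bulk tissue study.
## Bulk samples are proportion-weighted mixtures of three cell-type
## expression profiles; condition effects act through composition shifts
## (cell-type proportions differ between conditions) and/or within-cell-
## type regulation (fold changes applied to a gene set in one cell type).
## Every generator is deterministic given its seed and returns ground
## truth so each analysis stage can be validated end to end.

#' Simulation configuration
#'
#' Bundles all simulator parameters with validity checks. Defaults mirror
#' a sorted-cell CNS study: three cell types sorted from 5 animals per
#' condition, ~2,000 genes, 200 markers per cell type at a true 50-fold
#' specificity, negative binomial noise (Var = mu + phi mu^2, phi = 0.1),
#' library sizes log-uniform in \[5e5, 2e6\], and a disease composition
#' shift that doubles the microglial fraction (0.10 to 0.20) at the
#' expense of neurons (0.60 to 0.50). Setting `regulation` instead
#' applies within-cell-type fold changes at fixed proportions.
#'
#' @param nGenes number of genes.
#' @param cellTypes the three cell types, in profile order.
#' @param meanlog,sdlog log-normal parameters of baseline expression.
#' @param markerCounts genes specific to each cell type (profile order).
#' @param markerFold minimum true specificity fold of marker genes.
#' @param markerFloor pseudo-floor to which a marker's expression in the
#'   two non-target types is zeroed (expression units); the realized
#'   specificity is at least `markerFold`.
#' @param markerMeanlog,markerSdlog log-normal parameters of marker
#'   expression in their own type.
#' @param dispersion NB dispersion phi (Var = mu + phi mu^2).
#' @param libRange range of library sizes (log-uniform).
#' @param nReps animals per condition.
#' @param piControl,piTreated cell-type proportions of bulk tissue per
#'   condition (must sum to 1; profile order).
#' @param regulation `NULL`, or `list(nGenes=, fold=, cellType=)`
#'   describing within-cell-type regulation in the treated condition.
#' @param intronFactor ratio of total uniquely aligned reads to exonic
#'   library size (amplified CNS libraries carry many intronic reads).
#' @param geneLengthRange range of simulated union-exon lengths (bp).
#' @param splicing list: `nEvents`, `depth` (reads per event/sample),
#'   `baselineRange` of control inclusion frequencies, `logitShift`
#'   applied in the treated condition, `nReps` per condition,
#'   `propSameFeatures` (fraction of variants whose 5'/3' counts measure
#'   identical features).
#' @param qpcr list: `intercept` (Ct of unit abundance), `sigma`
#'   (replicate noise, cycles), `failThreshold` (Ct above which a
#'   replicate fails), `nReplicates`, `hkAbundance`.
#' @return validated configuration list of class `"triCellSimConfig"`.
#' @export
simulationConfig <- function(nGenes = 2000,
                             cellTypes = c("microglia", "astrocyte",
                                           "neuron"),
                             meanlog = log(10), sdlog = 1.5,
                             markerCounts = c(200, 200, 200),
                             markerFold = 50, markerFloor = 0.05,
                             markerMeanlog = log(50), markerSdlog = 1,
                             dispersion = 0.1,
                             libRange = c(5e5, 2e6),
                             nReps = 5,
                             piControl = c(0.10, 0.30, 0.60),
                             piTreated = c(0.20, 0.30, 0.50),
                             regulation = NULL,
                             intronFactor = 1.3,
                             geneLengthRange = c(500, 10000),
                             splicing = list(),
                             qpcr = list()) {
    cfg <- list(nGenes = nGenes, cellTypes = cellTypes, meanlog = meanlog,
                sdlog = sdlog, markerCounts = markerCounts,
                markerFold = markerFold, markerFloor = markerFloor,
                markerMeanlog = markerMeanlog,
                markerSdlog = markerSdlog, dispersion = dispersion,
                libRange = libRange, nReps = nReps,
                piControl = setNames(piControl, cellTypes),
                piTreated = setNames(piTreated, cellTypes),
                regulation = regulation, intronFactor = intronFactor,
                geneLengthRange = geneLengthRange,
                splicing = utils::modifyList(
                    list(nEvents = 50, depth = 60,
                         baselineRange = c(0.2, 0.8), logitShift = 0,
                         nReps = 5, propSameFeatures = 0.2), splicing),
                qpcr = utils::modifyList(
                    list(intercept = 35, sigma = 0.15, failThreshold = 33,
                         nReplicates = 3, hkAbundance = 2^12), qpcr))
    if (length(cellTypes) != 3L) stop("exactly three cell types")
    if (sum(markerCounts) > nGenes)
        stop("marker counts exceed the number of genes")
    if (abs(sum(piControl) - 1) > 1e-9 || abs(sum(piTreated) - 1) > 1e-9)
        stop("cell-type proportions must sum to 1")
    if (dispersion <= 0) stop("dispersion must be > 0")
    if (!is.null(regulation)) {
        if (!all(c("nGenes", "fold", "cellType") %in% names(regulation)))
            stop("regulation needs nGenes, fold and cellType")
        if (!regulation$cellType %in% cellTypes)
            stop("unknown regulation cell type: ", regulation$cellType)
    }
    class(cfg) <- "triCellSimConfig"
    cfg
}

#' Draw the ground-truth expression model
#'
#' Per-gene mean expression theta in each cell type is log-normal;
#' marker genes get their expression in the two non-target types set to
#' `theta / markerFold`, achieving the configured specificity exactly.
#' Regulated genes (when configured) are drawn uniformly from the gene
#' universe and recorded with their target cell type and fold. Gene
#' lengths are uniform over `geneLengthRange`.
#'
#' @param config from [simulationConfig()].
#' @param seed integer seed; the same seed reproduces the same truth.
#' @return list of class `"triCellTruth"`: `theta` (genes x 3 matrix),
#'   `markerType` (per-gene cell type or `NA`), `geneLength`,
#'   `regulation` (`data.frame` of gene_id, cell_type, fold),
#'   `piControl`, `piTreated`, `config`.
#' @export
generateReferenceTruth <- function(config, seed) {
    stopifnot(inherits(config, "triCellSimConfig"))
    set.seed(seed)
    n <- config$nGenes
    genes <- sprintf("gene%05d", seq_len(n))
    theta <- matrix(rlnorm(n * 3, config$meanlog, config$sdlog), n, 3,
                    dimnames = list(genes, config$cellTypes))
    markerType <- rep(NA_character_, n)
    at <- 0L
    for (i in seq_len(3)) {
        k <- config$markerCounts[i]
        if (k == 0) next
        idx <- at + seq_len(k); at <- at + k
        markerType[idx] <- config$cellTypes[i]
        own <- rlnorm(k, config$markerMeanlog, config$markerSdlog)
        ## non-target expression zeroed to the pseudo-floor (never above
        ## own/markerFold, so the specificity fold is at least markerFold)
        theta[idx, ] <- pmin(config$markerFloor, own / config$markerFold)
        theta[idx, i] <- own
    }
    geneLength <- round(runif(n, config$geneLengthRange[1],
                              config$geneLengthRange[2]))
    regulation <- data.frame(gene_id = character(), cell_type = character(),
                             fold = numeric(), stringsAsFactors = FALSE)
    if (!is.null(config$regulation)) {
        reg <- config$regulation
        regGenes <- sample(genes, reg$nGenes)
        regulation <- data.frame(gene_id = regGenes,
                                 cell_type = reg$cellType, fold = reg$fold,
                                 stringsAsFactors = FALSE)
    }
    structure(list(theta = theta, markerType = setNames(markerType, genes),
                   geneLength = setNames(geneLength, genes),
                   regulation = regulation,
                   piControl = config$piControl,
                   piTreated = config$piTreated, config = config),
              class = "triCellTruth")
}

## theta with regulation folds applied (treated condition only)
.regulatedTheta <- function(truth, condition, treated) {
    theta <- truth$theta
    if (condition == treated && nrow(truth$regulation)) {
        for (k in seq_len(nrow(truth$regulation))) {
            r <- truth$regulation[k, ]
            theta[r$gene_id, r$cell_type] <-
                theta[r$gene_id, r$cell_type] * r$fold
        }
    }
    theta
}

.nbCounts <- function(mu, phi) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / phi), nrow(mu),
           dimnames = dimnames(mu))
}

#' Simulate sorted-cell count matrices
#'
#' For every cell type and condition, draws `nReps` samples with
#' NB-distributed counts around `libSize * theta / sum(theta)`, with
#' regulation folds applied in the treated condition's target cell type.
#' Total uniquely aligned reads exceed the exonic library size by
#' `intronFactor`.
#'
#' @param truth from [generateReferenceTruth()].
#' @param seed integer seed.
#' @param conditions two condition labels, control first.
#' @return a [CellCountSet] with all sorted samples.
#' @export
generateSortedCounts <- function(truth, seed,
                                 conditions = c("control", "disease")) {
    stopifnot(inherits(truth, "triCellTruth"))
    set.seed(seed)
    cfg <- truth$config
    blocks <- list(); meta <- list()
    for (cond in conditions) {
        theta <- .regulatedTheta(truth, cond, conditions[2])
        for (ct in cfg$cellTypes) {
            libs <- exp(runif(cfg$nReps, log(cfg$libRange[1]),
                              log(cfg$libRange[2])))
            prob <- theta[, ct] / sum(theta[, ct])
            mu <- outer(prob, libs)
            ids <- sprintf("%s_%s_%d", ct, cond, seq_len(cfg$nReps))
            colnames(mu) <- ids
            blocks[[length(blocks) + 1L]] <- .nbCounts(mu, cfg$dispersion)
            meta[[length(meta) + 1L]] <- data.frame(
                sample_id = ids, condition = cond, cell_type = ct,
                total_uniq_reads = round(libs * cfg$intronFactor),
                stringsAsFactors = FALSE)
        }
    }
    CellCountSet(do.call(cbind, blocks), truth$geneLength,
                 do.call(rbind, meta))
}

#' Simulate bulk-tissue count matrices
#'
#' Bulk samples are NB draws around proportion-weighted mixtures of the
#' (possibly regulated) cell-type profiles:
#' `mu_gj = libSize_j * sum_c pi_c theta_gc / normalizer`. The control
#' and treated conditions use `piControl` and `piTreated`; regulation
#' folds (when configured) also act on the treated mixture, as regulated
#' cells are part of the tissue.
#'
#' @inheritParams generateSortedCounts
#' @param pi optional 2-row matrix (control, treated) of proportions
#'   overriding the truth's.
#' @return a [CellCountSet] of bulk samples.
#' @export
generateBulkCounts <- function(truth, seed,
                               conditions = c("control", "disease"),
                               pi = NULL) {
    stopifnot(inherits(truth, "triCellTruth"))
    set.seed(seed)
    cfg <- truth$config
    if (is.null(pi))
        pi <- rbind(truth$piControl, truth$piTreated)
    blocks <- list(); meta <- list()
    for (i in seq_along(conditions)) {
        cond <- conditions[i]
        theta <- .regulatedTheta(truth, cond, conditions[2])
        mix <- as.numeric(theta %*% pi[i, cfg$cellTypes])
        prob <- mix / sum(mix)
        libs <- exp(runif(cfg$nReps, log(cfg$libRange[1]),
                          log(cfg$libRange[2])))
        mu <- outer(prob, libs)
        ids <- sprintf("bulk_%s_%d", cond, seq_len(cfg$nReps))
        colnames(mu) <- ids
        rownames(mu) <- rownames(theta)
        blocks[[i]] <- .nbCounts(mu, cfg$dispersion)
        meta[[i]] <- data.frame(sample_id = ids, condition = cond,
                                cell_type = "bulk",
                                total_uniq_reads =
                                    round(libs * cfg$intronFactor),
                                stringsAsFactors = FALSE)
    }
    CellCountSet(do.call(cbind, blocks), truth$geneLength,
                 do.call(rbind, meta))
}

#' Simulate cassette splicing events
#'
#' Two-variant events: per sample, the inclusion count is binomial with
#' the event's inclusion frequency and the configured read depth, and
#' the skipping count is the remainder. Treated samples have the
#' inclusion frequency shifted by `logitShift` on the logit scale. The
#' skipping variant is listed first in each event (matching the usual
#' discovery order); 5'/3' counts are a binomial split of the variant
#' total except for `propSameFeatures` of variants, whose two counts
#' measure the same features and are equal to the total.
#'
#' @param config from [simulationConfig()] (the `splicing` element).
#' @param seed integer seed.
#' @param conditions two condition labels, control first.
#' @return list: `events` (long-format event table ready for
#'   [summarizeVariantCounts()]) and `truth` (`data.frame` of per-event
#'   control/treated inclusion frequencies).
#' @export
generateSplicingCounts <- function(config, seed,
                                   conditions = c("vehicle", "LPS")) {
    stopifnot(inherits(config, "triCellSimConfig"))
    set.seed(seed)
    sp <- config$splicing
    samples <- c(sprintf("%s_%d", conditions[1], seq_len(sp$nReps)),
                 sprintf("%s_%d", conditions[2], seq_len(sp$nReps)))
    sampleCond <- rep(conditions, each = sp$nReps)
    p0 <- runif(sp$nEvents, sp$baselineRange[1], sp$baselineRange[2])
    p1 <- plogis(qlogis(p0) + sp$logitShift)
    sameFeat <- runif(2 * sp$nEvents) < sp$propSameFeatures
    rows <- vector("list", sp$nEvents)
    for (e in seq_len(sp$nEvents)) {
        ev <- sprintf("ev%03d", e)
        pInc <- ifelse(sampleCond == conditions[1], p0[e], p1[e])
        inc <- rbinom(length(samples), sp$depth, pInc)
        skp <- sp$depth - inc
        split53 <- function(total, same) {
            if (same) cbind(total, total)
            else { c5 <- rbinom(length(total), total, 0.5)
                   cbind(c5, total - c5) }
        }
        sk53 <- split53(skp, sameFeat[2 * e - 1])
        in53 <- split53(inc, sameFeat[2 * e])
        rows[[e]] <- data.frame(
            event_id = ev,
            variant_id = rep(paste0(ev, c("_skip", "_incl")),
                             each = length(samples)),
            role = rep(c("skipping", "inclusion"), each = length(samples)),
            retained_intron = FALSE,
            same_features = rep(sameFeat[c(2 * e - 1, 2 * e)],
                                each = length(samples)),
            sample_id = rep(samples, 2),
            count5p = c(sk53[, 1], in53[, 1]),
            count3p = c(sk53[, 2], in53[, 2]),
            stringsAsFactors = FALSE)
    }
    list(events = .rbindRows(rows),
         truth = data.frame(event_id = sprintf("ev%03d",
                                               seq_len(sp$nEvents)),
                            vfreq_ctrl = p0, vfreq_trt = p1,
                            stringsAsFactors = FALSE))
}

#' Simulate a qPCR plate from true abundances
#'
#' Each technical replicate's Ct follows
#' `Ct = intercept - log2(abundance) + Normal(0, sigma)` (amplification
#' efficiency exactly 2); replicates whose Ct exceeds `failThreshold`
#' are marked as fails, so abundances below the detection floor fail on
#' all replicates and exercise the Ct^max + 1 imputation path.
#'
#' @param abundance `data.frame` with columns `sample_id`, `assay_id`,
#'   `abundance` and optionally `cell_type`, `condition`, `assay_role`.
#'   Housekeeping rows are included like any other assay (typically at a
#'   constant abundance).
#' @param config from [simulationConfig()] (the `qpcr` element).
#' @param seed integer seed.
#' @return long-format plate table for [summarizeCt()].
#' @export
generateQpcrPlate <- function(abundance, config, seed) {
    stopifnot(inherits(config, "triCellSimConfig"))
    set.seed(seed)
    q <- config$qpcr
    n <- nrow(abundance)
    rows <- lapply(seq_len(q$nReplicates), function(r) {
        ct <- q$intercept - log2(abundance$abundance) +
            rnorm(n, 0, q$sigma)
        cbind(abundance[setdiff(colnames(abundance), "abundance")],
              data.frame(replicate_idx = r, ct = ct,
                         pass = is.finite(ct) & ct <= q$failThreshold))
    })
    out <- .rbindRows(rows)
    out <- out[order(match(out$sample_id, unique(abundance$sample_id)),
                     match(out$assay_id, unique(abundance$assay_id)),
                     out$replicate_idx), ]
    rownames(out) <- NULL
    out
}

#' Simulate a complete sorted + bulk study
#'
#' Convenience wrapper drawing the truth, the sorted-cell counts and the
#' bulk counts with sub-seeds derived from one master seed.
#'
#' @param config from [simulationConfig()].
#' @param seed master integer seed.
#' @param conditions two condition labels, control first.
#' @return list with `truth`, `sorted` and `bulk` (both [CellCountSet]).
#' @export
simulateStudy <- function(config, seed,
                          conditions = c("control", "disease")) {
    truth <- generateReferenceTruth(config, seed)
    list(truth = truth,
         sorted = generateSortedCounts(truth, seed + 1000L, conditions),
         bulk = generateBulkCounts(truth, seed + 2000L, conditions))
}
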