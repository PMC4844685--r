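## qPCR Ct processing: technical-replicate averaging with failure
## imputation, -dCt housekeeping normalization, ddCt for splicing
## (inclusion vs skipping assays) and for treatment contrasts, and
## per-cell-type testing.
##
## Plate tables are long-format data.frames with columns sample_id,
## cell_type, condition, assay_id, assay_role (one of constitutive,
## inclusion, skipping, target, housekeeping), replicate_idx, ct, pass.

.checkPlate <- function(plate) {
    need <- c("sample_id", "assay_id", "ct", "pass")
    miss <- setdiff(need, colnames(plate))
    if (length(miss))
        stop("plate table lacks column(s): ", paste(miss, collapse = ", "))
    if (any(plate$pass & (!is.finite(plate$ct) | plate$ct <= 0)))
        stop("passing Ct values must be finite and positive")
    invisible(plate)
}

.carryCols <- function(plate) intersect(c("cell_type", "condition",
                                          "assay_role"), colnames(plate))

#' Average technical replicates, imputing total failures at Ct^max + 1
#'
#' Technical replicates are averaged per (sample, assay), omitting fail
#' calls. When an assay fails on all replicates of a sample, its Ct is
#' imputed at one cycle beyond the assay's highest passing Ct in any
#' sample (Ct^max + 1) — marking abundance below the detection floor —
#' and flagged. An assay with no passing replicate anywhere has no
#' Ct^max and is an error.
#'
#' @param plate long-format plate table (see above).
#' @return `data.frame` with one row per (sample, assay): the metadata
#'   columns, `ct` and logical `imputed`.
#' @export
summarizeCt <- function(plate) {
    .checkPlate(plate)
    ctMax <- tapply(ifelse(plate$pass, plate$ct, NA_real_), plate$assay_id,
                    function(x) if (all(is.na(x))) NA_real_
                                else max(x, na.rm = TRUE))
    key <- factor(paste(plate$sample_id, plate$assay_id, sep = "\r"),
                  unique(paste(plate$sample_id, plate$assay_id, sep = "\r")))
    rows <- lapply(split(plate, key), function(d) {
        ok <- d$pass
        if (any(ok)) {
            ct <- mean(d$ct[ok]); imputed <- FALSE
        } else {
            mx <- ctMax[[d$assay_id[1]]]
            if (is.na(mx))
                stop("assay '", d$assay_id[1], "' failed in every sample; ",
                     "Ct^max is undefined and imputation is impossible")
            ct <- mx + 1; imputed <- TRUE
        }
        cbind(d[1, c("sample_id", "assay_id", .carryCols(d)), drop = FALSE],
              data.frame(ct = ct, imputed = imputed))
    })
    .rbindRows(rows)
}

#' Housekeeping-normalized -dCt values
#'
#' For each sample and non-housekeeping assay,
#' `-dCt = -(Ct_target - mean(Ct_housekeeping))`; higher values mean
#' higher abundance. The housekeeping set is configurable — a single
#' loading control (e.g. Actb) for splicing work, or an averaged pair
#' (e.g. Gapdh and Rpl37a) for gene-level analyses. Samples missing any
#' housekeeping assay are excluded with a warning. The imputed flag
#' propagates from the target or any housekeeping Ct.
#'
#' @param ctTable output of [summarizeCt()].
#' @param housekeeping character vector of housekeeping assay ids
#'   (default `"Actb"`).
#' @return `data.frame` with metadata columns, `minus_delta_ct` and
#'   `imputed`, one row per (sample, non-housekeeping assay).
#' @export
deltaCt <- function(ctTable, housekeeping = "Actb") {
    miss <- setdiff(housekeeping, ctTable$assay_id)
    if (length(miss))
        stop("housekeeping assay(s) absent from the table: ",
             paste(miss, collapse = ", "))
    rows <- lapply(split(ctTable, factor(ctTable$sample_id,
                                         unique(ctTable$sample_id))),
                   function(d) {
        hk <- d[d$assay_id %in% housekeeping, , drop = FALSE]
        if (nrow(hk) < length(housekeeping)) {
            warning("sample ", d$sample_id[1],
                    " lacks housekeeping assay(s); excluded")
            return(NULL)
        }
        t <- d[!d$assay_id %in% housekeeping, , drop = FALSE]
        t$minus_delta_ct <- -(t$ct - mean(hk$ct))
        t$imputed <- t$imputed | any(hk$imputed)
        t$ct <- NULL
        t
    })
    .rbindRows(rows)
}

#' Splicing ddCt: inclusion minus skipping
#'
#' For each sample and splicing event,
#' `ddCt = (-dCt_inclusion) - (-dCt_skipping)`; lower values indicate
#' more exon skipping. Assays are paired within events via `assayEvent`;
#' a sample missing one of the two isoform assays is excluded with a
#' warning, and the imputed flag propagates from either assay.
#'
#' @param minusDct output of [deltaCt()] containing assays with
#'   `assay_role` `"inclusion"` and `"skipping"`.
#' @param assayEvent named character vector mapping `assay_id` to an
#'   event identifier; when omitted, an `event_id` column on `minusDct`
#'   is used.
#' @return `data.frame` with `sample_id`, `cell_type`, `condition` (when
#'   available), `event_id`, `ddct`, `imputed`.
#' @export
ddctSplicing <- function(minusDct, assayEvent = NULL) {
    if (!is.null(assayEvent))
        minusDct$event_id <- unname(assayEvent[minusDct$assay_id])
    if (is.null(minusDct$event_id))
        stop("supply 'assayEvent' or an event_id column")
    if (is.null(minusDct$assay_role))
        stop("an assay_role column is required")
    d <- minusDct[minusDct$assay_role %in% c("inclusion", "skipping") &
                  !is.na(minusDct$event_id), , drop = FALSE]
    key <- factor(paste(d$sample_id, d$event_id, sep = "\r"),
                  unique(paste(d$sample_id, d$event_id, sep = "\r")))
    rows <- lapply(split(d, key), function(s) {
        inc <- s[s$assay_role == "inclusion", , drop = FALSE]
        skp <- s[s$assay_role == "skipping", , drop = FALSE]
        if (nrow(inc) != 1L || nrow(skp) != 1L) {
            warning("sample ", s$sample_id[1], ", event ", s$event_id[1],
                    ": missing inclusion or skipping assay; excluded")
            return(NULL)
        }
        meta <- intersect(c("cell_type", "condition"), colnames(s))
        cbind(s[1, c("sample_id", meta), drop = FALSE],
              data.frame(event_id = s$event_id[1],
                         ddct = inc$minus_delta_ct - skp$minus_delta_ct,
                         imputed = inc$imputed | skp$imputed))
    })
    .rbindRows(rows)
}

#' Per-cell-type test of splicing ddCt between conditions
#'
#' Within each cell type, compares ddCt values between the two
#' conditions for every event with a two-sided Student's t-test
#' (equal-variance by default; Welch optionally), including imputed
#' values, then applies BH correction across the cell type's events.
#' A cell type / event with fewer than 2 samples in a condition is
#' skipped with a warning.
#'
#' @param ddct output of [ddctSplicing()] with `condition` and
#'   `cell_type` columns.
#' @param control reference condition; defaults to the first factor
#'   level of `condition`.
#' @param var.equal `TRUE` (default) for Student's test, `FALSE` for
#'   Welch.
#' @return `data.frame` with `cell_type`, `event_id`, `mean_ctrl`,
#'   `mean_trt`, `delta`, `p`, `adj_p`.
#' @export
testDdct <- function(ddct, control = NULL, var.equal = TRUE) {
    cond <- as.factor(ddct$condition)
    if (nlevels(droplevels(cond)) != 2L)
        stop("'condition' must have exactly two levels")
    cond <- droplevels(cond)
    if (is.null(control)) control <- levels(cond)[1]
    trt <- setdiff(levels(cond), control)
    out <- lapply(split(seq_len(nrow(ddct)), ddct$cell_type),
                  function(idx) {
        d <- ddct[idx, ]; cc <- cond[idx]
        rows <- lapply(split(seq_len(nrow(d)), d$event_id), function(j) {
            x1 <- d$ddct[j][cc[j] == control]
            x2 <- d$ddct[j][cc[j] == trt]
            if (length(x1) < 2L || length(x2) < 2L) {
                warning("cell type ", d$cell_type[1], ", event ",
                        d$event_id[j][1],
                        ": fewer than 2 samples per condition; skipped")
                return(NULL)
            }
            p <- if (var.equal) .studentP(x1, x2) else .welchP(x1, x2)
            data.frame(cell_type = d$cell_type[1],
                       event_id = d$event_id[j][1],
                       mean_ctrl = mean(x1), mean_trt = mean(x2),
                       delta = mean(x2) - mean(x1), p = p,
                       stringsAsFactors = FALSE)
        })
        r <- .rbindRows(rows)
        if (!is.null(r) && nrow(r)) r$adj_p <- adjustBH(r$p)
        r
    })
    .rbindRows(out)
}

#' Treatment ddCt per assay and cell type
#'
#' The group-mean difference of -dCt between conditions (treatment minus
#' control) per assay and cell type. Under perfect amplification
#' efficiency this is the log2 fold change of the target's abundance;
#' positive values mean induction by treatment. A (assay, cell type)
#' stratum missing one condition yields `NA` for that stratum.
#'
#' @param minusDct output of [deltaCt()] with `condition` and
#'   `cell_type` columns.
#' @param control reference condition; defaults to the first factor
#'   level.
#' @return `data.frame` with `cell_type`, `assay_id`,
#'   `mean_minus_dct_ctrl`, `mean_minus_dct_trt`, `ddct`.
#' @export
ddctTreatment <- function(minusDct, control = NULL) {
    cond <- as.factor(minusDct$condition)
    if (nlevels(droplevels(cond)) != 2L)
        stop("'condition' must have exactly two levels")
    cond <- droplevels(cond)
    if (is.null(control)) control <- levels(cond)[1]
    trt <- setdiff(levels(cond), control)
    key <- factor(paste(minusDct$cell_type, minusDct$assay_id, sep = "\r"),
                  unique(paste(minusDct$cell_type, minusDct$assay_id,
                               sep = "\r")))
    rows <- lapply(split(seq_len(nrow(minusDct)), key), function(idx) {
        d <- minusDct[idx, ]; cc <- cond[idx]
        m1 <- if (any(cc == control))
            mean(d$minus_delta_ct[cc == control]) else NA_real_
        m2 <- if (any(cc == trt))
            mean(d$minus_delta_ct[cc == trt]) else NA_real_
        data.frame(cell_type = d$cell_type[1], assay_id = d$assay_id[1],
                   mean_minus_dct_ctrl = m1, mean_minus_dct_trt = m2,
                   ddct = m2 - m1, stringsAsFactors = FALSE)
    })
    .rbindRows(rows)
}
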