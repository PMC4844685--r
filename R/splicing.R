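## Splice-variant usage: count summarization, variant frequency, the
## filtering cascade, and a replicate-aware differential-usage test.
##
## A splicing event is a set of (usually 2) variants, e.g. the inclusion
## and skipping isoforms of a cassette exon. Event tables are long-format
## data.frames with columns event_id, variant_id, role, retained_intron,
## same_features, sample_id, count5p, count3p (the read counts supporting
## the variant's 5' and 3' splice-graph features).

.checkEventTable <- function(events, counted = FALSE) {
    need <- c("event_id", "variant_id", "sample_id",
              if (counted) "count" else c("count5p", "count3p"))
    miss <- setdiff(need, colnames(events))
    if (length(miss))
        stop("event table lacks column(s): ", paste(miss, collapse = ", "))
    invisible(events)
}

#' Summarize a variant's 5' and 3' feature counts into one count
#'
#' Each variant gets a single per-sample count: the sum of its 5' and 3'
#' counts when they measure distinct features, or the single unique value
#' when `same_features` is `TRUE` (summing would double-count). A
#' `same_features` variant with unequal 5'/3' counts violates that
#' contract and is an error.
#'
#' @param events long-format event table (see above). A missing
#'   `same_features` column defaults to `FALSE`.
#' @return the table with a `count` column replacing `count5p`/`count3p`.
#' @export
summarizeVariantCounts <- function(events) {
    .checkEventTable(events)
    if (is.null(events$same_features)) events$same_features <- FALSE
    if (any(events$count5p < 0 | events$count3p < 0))
        stop("counts must be nonnegative")
    same <- as.logical(events$same_features)
    bad <- same & events$count5p != events$count3p
    if (any(bad))
        stop("same_features variants with unequal 5'/3' counts: ",
             paste(unique(events$variant_id[bad]), collapse = ", "))
    events$count <- ifelse(same, events$count5p,
                           events$count5p + events$count3p)
    events$count5p <- events$count3p <- NULL
    events
}

#' Per-sample variant frequency within each event
#'
#' vFreq is a variant's share of its event's total count in a sample,
#' ranging from 0 (fully skipped) to 1 (fully included); it is undefined
#' (`NA`) in samples where the event total is 0. Defined frequencies sum
#' to 1 within an event and sample, and are invariant to rescaling all of
#' a sample's counts.
#'
#' @param counts summarized event table from [summarizeVariantCounts()].
#' @return the table with a `vfreq` column added.
#' @export
computeVariantFreq <- function(counts) {
    .checkEventTable(counts, counted = TRUE)
    key <- paste(counts$event_id, counts$sample_id, sep = "\r")
    tot <- as.numeric(tapply(counts$count, key, sum)[key])
    counts$vfreq <- ifelse(tot > 0, counts$count / tot, NA_real_)
    counts
}

#' Filtering cascade for testable splice variants
#'
#' Applies, in order: (1) drop variants lacking at least `minCount` counts
#' in at least `minSamples` samples (of any condition); (2) drop events
#' left with a single variant — that variant is effectively constitutive;
#' (3) drop retained-intron events (prone to artefacts when libraries
#' carry many intronic reads); (4) mark each remaining event's first
#' variant (in input order, generally a skipping variant) as excluded from
#' testing, to limit the number of tests. The cascade is order-dependent
#' and idempotent.
#'
#' @param counts summarized event table ([summarizeVariantCounts()]),
#'   optionally already carrying `vfreq`.
#' @param minCount,minSamples the count filter (defaults 5 and 3).
#' @return the surviving rows with a logical `testable` column.
#' @export
filterSplicingVariants <- function(counts, minCount = 5, minSamples = 3) {
    .checkEventTable(counts, counted = TRUE)
    if (is.null(counts$retained_intron)) counts$retained_intron <- FALSE
    counts$.row <- seq_len(nrow(counts))
    ## (1) count filter per variant
    vkey <- paste(counts$event_id, counts$variant_id, sep = "\r")
    nPass <- tapply(counts$count >= minCount, vkey, sum)
    counts <- counts[nPass[vkey] >= minSamples, , drop = FALSE]
    ## (2) events reduced to a single variant are constitutive
    nVar <- tapply(counts$variant_id, counts$event_id,
                   function(v) length(unique(v)))
    counts <- counts[nVar[counts$event_id] >= 2, , drop = FALSE]
    ## (3) retained-intron events
    isRI <- tapply(counts$retained_intron, counts$event_id, any)
    counts <- counts[!isRI[counts$event_id], , drop = FALSE]
    ## (4) each event's first remaining variant (input order) is not tested
    counts <- counts[order(counts$.row), , drop = FALSE]
    first <- vapply(split(counts, counts$event_id), function(d)
        d$variant_id[which.min(d$.row)], character(1))
    counts$testable <- counts$variant_id != first[counts$event_id]
    counts$.row <- NULL
    rownames(counts) <- NULL
    counts
}

#' Differential variant usage between two conditions
#'
#' For every testable variant, compares variant frequencies between the
#' two conditions with a Welch t-test on logit-transformed vFreq, with
#' vFreq clamped to \[0.01, 0.99\] so boundary frequencies stay finite.
#' The reported effect `delta` is the difference of raw mean vFreq
#' (treatment minus control). BH correction is applied across the
#' testable variants only. Samples with undefined vFreq are dropped per
#' variant; a variant with fewer than two defined values in a condition
#' is skipped with a warning.
#'
#' @param vfreq table from [computeVariantFreq()], filtered by
#'   [filterSplicingVariants()] (a `testable` column is honoured when
#'   present; otherwise every variant is tested).
#' @param conditions per-sample condition labels, named by `sample_id`
#'   (two levels).
#' @param control reference condition; defaults to the first factor
#'   level.
#' @param clamp vFreq clamping bounds (default `c(0.01, 0.99)`).
#' @return `data.frame` with `event_id`, `variant_id`,
#'   `mean_vfreq_ctrl`, `mean_vfreq_trt`, `delta`, `p`, `adj_p`.
#' @export
testDifferentialUsage <- function(vfreq, conditions, control = NULL,
                                  clamp = c(0.01, 0.99)) {
    if (is.null(vfreq$vfreq)) stop("run computeVariantFreq() first")
    if (is.null(vfreq$testable)) vfreq$testable <- TRUE
    nm <- names(conditions)
    if (is.null(nm)) stop("'conditions' must be named by sample_id")
    conditions <- as.factor(conditions)
    if (nlevels(droplevels(conditions)) != 2L)
        stop("'conditions' must have exactly two levels")
    conditions <- droplevels(conditions)
    names(conditions) <- nm
    if (is.null(control)) control <- levels(conditions)[1]
    trt <- setdiff(levels(conditions), control)
    v <- vfreq[vfreq$testable, , drop = FALSE]
    cond <- conditions[v$sample_id]
    keyOf <- paste(v$event_id, v$variant_id, sep = "\r")
    rows <- lapply(split(seq_len(nrow(v)), factor(keyOf, unique(keyOf))),
                   function(idx) {
        d <- v[idx, ]
        cc <- cond[idx]
        x1 <- d$vfreq[cc == control & !is.na(d$vfreq)]
        x2 <- d$vfreq[cc == trt & !is.na(d$vfreq)]
        if (length(x1) < 2L || length(x2) < 2L) {
            warning("variant ", d$variant_id[1], " of event ",
                    d$event_id[1],
                    " has fewer than 2 defined vFreq values in a ",
                    "condition; skipped")
            return(NULL)
        }
        l1 <- qlogis(pmin(pmax(x1, clamp[1]), clamp[2]))
        l2 <- qlogis(pmin(pmax(x2, clamp[1]), clamp[2]))
        p <- .welchP(l1, l2)
        data.frame(event_id = d$event_id[1], variant_id = d$variant_id[1],
                   mean_vfreq_ctrl = mean(x1), mean_vfreq_trt = mean(x2),
                   delta = mean(x2) - mean(x1), p = p,
                   stringsAsFactors = FALSE)
    })
    out <- .rbindRows(rows)
    if (is.null(out) || !nrow(out))
        return(data.frame(event_id = character(), variant_id = character(),
                          mean_vfreq_ctrl = numeric(),
                          mean_vfreq_trt = numeric(), delta = numeric(),
                          p = numeric(), adj_p = numeric()))
    out$adj_p <- adjustBH(out$p)
    out
}

## rbind a list of data.frame rows, ignoring NULLs; NULL when all are
.rbindRows <- function(rows) {
    rows <- Filter(Negate(is.null), rows)
    if (!length(rows)) return(NULL)
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    rownames(out) <- NULL
    out
}

## scalar Welch t p-value robust to zero-variance groups
.welchP <- function(x1, x2) {
    v1 <- var(x1); v2 <- var(x2)
    se2 <- v1 / length(x1) + v2 / length(x2)
    if (se2 == 0) return(if (mean(x1) == mean(x2)) 1 else 0)
    tstat <- (mean(x2) - mean(x1)) / sqrt(se2)
    df <- se2^2 / ((v1 / length(x1))^2 / (length(x1) - 1) +
                   (v2 / length(x2))^2 / (length(x2) - 1))
    2 * pt(-abs(tstat), df)
}

## scalar Student (equal-variance) t p-value robust to zero variance
.studentP <- function(x1, x2) {
    n1 <- length(x1); n2 <- length(x2)
    sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
    if (sp2 == 0) return(if (mean(x1) == mean(x2)) 1 else 0)
    tstat <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    2 * pt(-abs(tstat), n1 + n2 - 2)
}
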