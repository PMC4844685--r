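## Independent brute-force oracles and small fixture builders. These are
## deliberately written as plain loops, separate from the package's
## vectorized implementations.

## median-of-ratios size factors, anchored to geometric mean 1
bruteSizeFactors <- function(m) {
    n <- ncol(m)
    keep <- apply(m, 1, function(r) all(r > 0))
    mm <- m[keep, , drop = FALSE]
    geo <- apply(mm, 1, function(r) prod(r)^(1 / length(r)))
    s <- vapply(seq_len(n), function(j) median(mm[, j] / geo), numeric(1))
    s / prod(s)^(1 / n)
}

## Benjamini-Hochberg step-up by its textbook definition
bruteBH <- function(p) {
    n <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(n)
    for (k in seq_len(n)) adj[k] <- min(1, min(n * ps[k:n] / (k:n)))
    out <- numeric(n)
    out[o] <- adj
    out
}

## exhaustive label-permutation p-value referencing the Welch statistic
## to its full permutation null distribution
brutePermutationP <- function(x1, x2) {
    tw <- function(a, b) {
        se2 <- var(a) / length(a) + var(b) / length(b)
        if (se2 == 0) return(0)
        abs(mean(a) - mean(b)) / sqrt(se2)
    }
    x <- c(x1, x2)
    n1 <- length(x1)
    idx <- utils::combn(length(x), n1)
    obs <- tw(x1, x2)
    stats <- apply(idx, 2, function(i) tw(x[i], x[-i]))
    mean(stats >= obs - 1e-12)
}

randomCounts <- function(nGenes, nSamples, seed, lambdaRange = c(1, 500)) {
    set.seed(seed)
    mu <- exp(runif(nGenes, log(lambdaRange[1]), log(lambdaRange[2])))
    matrix(rpois(nGenes * nSamples, mu), nGenes, nSamples,
           dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                           sprintf("s%02d", seq_len(nSamples))))
}

toyCountSet <- function() {
    cts <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L, 15L, 30L, 45L,
                    12L, 24L, 36L), 3, 4,
                  dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
    CellCountSet(cts, geneLength = c(1000, 2000, 500),
                 sampleData = data.frame(
                     sample_id = paste0("s", 1:4),
                     condition = rep(c("control", "disease"), each = 2),
                     cell_type = "bulk",
                     total_uniq_reads = c(1e6, 2e6, 1.5e6, 1.2e6)))
}

## hand-built event table exercising every branch of the filter cascade
toyEventTable <- function() {
    samples <- paste0("s", 1:6)
    row <- function(ev, var, role, ri, same, counts5, counts3)
        data.frame(event_id = ev, variant_id = var, role = role,
                   retained_intron = ri, same_features = same,
                   sample_id = samples, count5p = counts5,
                   count3p = counts3, stringsAsFactors = FALSE)
    rbind(
        ## e1: clean cassette, both variants pass -> inclusion testable
        row("e1", "e1_skip", "skipping", FALSE, FALSE,
            c(5, 6, 7, 0, 1, 0), c(5, 4, 3, 0, 1, 0)),
        row("e1", "e1_incl", "inclusion", FALSE, FALSE,
            c(10, 12, 9, 30, 28, 31), c(8, 10, 11, 30, 30, 29)),
        ## e2: second variant fails counts, event left with one variant
        row("e2", "e2_a", "skipping", FALSE, TRUE,
            c(6, 6, 6, 6, 6, 6), c(6, 6, 6, 6, 6, 6)),
        row("e2", "e2_b", "inclusion", FALSE, TRUE,
            c(1, 1, 1, 1, 1, 1), c(1, 1, 1, 1, 1, 1)),
        ## e3: retained intron, both variants pass counts
        row("e3", "e3_a", "other", TRUE, FALSE,
            c(10, 10, 10, 10, 10, 10), c(10, 10, 10, 10, 10, 10)),
        row("e3", "e3_b", "other", TRUE, FALSE,
            c(20, 20, 20, 20, 20, 20), c(20, 20, 20, 20, 20, 20)),
        ## e4: three passing variants -> two testable
        row("e4", "e4_a", "skipping", FALSE, FALSE,
            c(9, 9, 9, 9, 9, 9), c(1, 1, 1, 1, 1, 1)),
        row("e4", "e4_b", "inclusion", FALSE, FALSE,
            c(5, 5, 5, 5, 5, 5), c(5, 5, 5, 5, 5, 5)),
        row("e4", "e4_c", "other", FALSE, FALSE,
            c(4, 4, 4, 3, 3, 3), c(2, 2, 2, 2, 2, 2)),
        ## e5: every variant fails the count filter
        row("e5", "e5_a", "skipping", FALSE, FALSE,
            c(1, 2, 0, 1, 2, 0), c(0, 1, 1, 0, 1, 1)),
        row("e5", "e5_b", "inclusion", FALSE, FALSE,
            c(0, 0, 1, 2, 0, 1), c(1, 1, 0, 0, 1, 0)),
        ## e6: first variant fails counts; the two remaining survive and
        ## the first of those (input order) is not testable
        row("e6", "e6_a", "skipping", FALSE, FALSE,
            c(2, 2, 2, 1, 1, 1), c(0, 0, 0, 1, 1, 1)),
        row("e6", "e6_b", "inclusion", FALSE, FALSE,
            c(7, 7, 7, 7, 7, 7), c(3, 3, 3, 3, 3, 3)),
        row("e6", "e6_c", "other", FALSE, FALSE,
            c(6, 6, 6, 6, 6, 6), c(4, 4, 4, 4, 4, 4)))
}

## hand-built four-sample qPCR plate with known arithmetic
toyQpcrPlate <- function() {
    rows <- list()
    add <- function(sample, cond, assay, role, cts, pass) {
        rows[[length(rows) + 1L]] <<- data.frame(
            sample_id = sample, cell_type = "microglia", condition = cond,
            assay_id = assay, assay_role = role,
            replicate_idx = seq_along(cts), ct = cts, pass = pass,
            stringsAsFactors = FALSE)
    }
    ## housekeeping Actb at Ct 20 everywhere
    for (s in c("v1", "v2", "l1", "l2")) {
        cond <- if (grepl("^v", s)) "vehicle" else "LPS"
        add(s, cond, "Actb", "housekeeping", c(20, 20, 20), rep(TRUE, 3))
    }
    ## inclusion assay: one fail among replicates in v1
    add("v1", "vehicle", "ev1_I", "inclusion", c(24.1, 24.3, 31),
        c(TRUE, TRUE, FALSE))
    add("v2", "vehicle", "ev1_I", "inclusion", c(24.0, 24.4, 24.2),
        rep(TRUE, 3))
    add("l1", "LPS", "ev1_I", "inclusion", c(26.0, 26.2, 26.1),
        rep(TRUE, 3))
    add("l2", "LPS", "ev1_I", "inclusion", c(26.3, 26.1, 26.2),
        rep(TRUE, 3))
    ## skipping assay: fails on all replicates of v1 (imputation path);
    ## its highest passing Ct anywhere is 31.0 (sample v2)
    add("v1", "vehicle", "ev1_S", "skipping", c(35, 36, 37), rep(FALSE, 3))
    add("v2", "vehicle", "ev1_S", "skipping", c(31.0, 30.8, 30.9),
        c(TRUE, FALSE, FALSE))
    add("l1", "LPS", "ev1_S", "skipping", c(22.0, 22.2, 22.1),
        rep(TRUE, 3))
    add("l2", "LPS", "ev1_S", "skipping", c(22.4, 22.2, 22.0),
        rep(TRUE, 3))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
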