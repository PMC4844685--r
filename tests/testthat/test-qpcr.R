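test_that("replicate averaging omits fails and imputes at Ct^max + 1", {
    ct <- summarizeCt(toyQpcrPlate())
    get <- function(s, a) ct[ct$sample_id == s & ct$assay_id == a, ]
    expect_equal(get("v1", "ev1_I")$ct, 24.2)      # mean of passing pair
    expect_false(get("v1", "ev1_I")$imputed)
    expect_equal(get("v2", "ev1_S")$ct, 31.0)      # single passing value
    expect_false(get("v2", "ev1_S")$imputed)
    ## all replicates failed; assay's best Ct anywhere is 31.0
    expect_equal(get("v1", "ev1_S")$ct, 32.0)
    expect_true(get("v1", "ev1_S")$imputed)
    ## imputed Ct exceeds every observed passing Ct for the assay
    passing <- toyQpcrPlate()
    passing <- passing[passing$assay_id == "ev1_S" & passing$pass, ]
    expect_true(get("v1", "ev1_S")$ct > max(passing$ct))

    allFail <- data.frame(sample_id = c("s1", "s2"), assay_id = "dead",
                          replicate_idx = 1, ct = c(38, 39), pass = FALSE)
    expect_error(summarizeCt(allFail), "failed in every sample")
})

test_that("-dCt subtracts the averaged housekeeping Ct", {
    ct <- data.frame(sample_id = "s1", cell_type = "neuron",
                     condition = "vehicle",
                     assay_id = c("tgt", "tgt2", "Actb", "Gapdh",
                                  "Rpl37a"),
                     assay_role = c("target", "target",
                                    rep("housekeeping", 3)),
                     ct = c(25, 24, 20, 19, 21), imputed = FALSE)
    d1 <- deltaCt(ct, housekeeping = "Actb")
    expect_equal(d1$minus_delta_ct[d1$assay_id == "tgt"], -5)
    ## averaged two-gene housekeeping: mean(19, 21) = 20, target 24 -> -4
    d2 <- deltaCt(ct, housekeeping = c("Gapdh", "Rpl37a"))
    expect_equal(d2$minus_delta_ct[d2$assay_id == "tgt2"], -4)
    ct0 <- ct
    ct0$ct[1] <- 20
    expect_equal(deltaCt(ct0, "Actb")$minus_delta_ct[1], 0)
    ## missing housekeeping excludes the sample with a warning
    noHk <- ct[ct$assay_id == "tgt", ]
    noHk$sample_id <- "s2"
    expect_warning(out <- deltaCt(rbind(ct, noHk), "Actb"),
                   "lacks housekeeping")
    expect_false("s2" %in% out$sample_id)
})

test_that("splicing ddCt is inclusion minus skipping with flag carry-over", {
    md <- data.frame(sample_id = rep("s1", 2), cell_type = "microglia",
                     condition = "vehicle",
                     assay_id = c("I", "S"),
                     assay_role = c("inclusion", "skipping"),
                     minus_delta_ct = c(-5, -8),
                     imputed = c(FALSE, TRUE))
    dd <- ddctSplicing(md, assayEvent = c(I = "ev1", S = "ev1"))
    expect_equal(dd$ddct, 3)
    expect_true(dd$imputed)                     # from the skipping assay
    mdEq <- md
    mdEq$minus_delta_ct <- c(-4, -4)
    expect_equal(ddctSplicing(mdEq, c(I = "ev1", S = "ev1"))$ddct, 0)
    ## a lone isoform assay cannot form a ddCt
    expect_warning(out <- ddctSplicing(md[1, ], c(I = "ev1", S = "ev1")),
                   "missing inclusion or skipping")
    expect_null(out)
})

test_that("the toy plate flows end to end with hand-computed values", {
    md <- deltaCt(summarizeCt(toyQpcrPlate()), housekeeping = "Actb")
    dd <- ddctSplicing(md, assayEvent = c(ev1_I = "ev1", ev1_S = "ev1"))
    expect_equal(dd$ddct[match(c("v1", "v2", "l1", "l2"), dd$sample_id)],
                 c(7.8, 6.8, -4.0, -4.0), tolerance = 1e-9)
    expect_equal(dd$imputed[dd$sample_id == "v1"], TRUE)
    res <- testDdct(dd, control = "vehicle")
    expect_lt(res$p, 0.01)                       # lower ddCt after LPS
    expect_equal(res$delta, -11.3, tolerance = 1e-9)
})

test_that("Student's ddCt test separates groups and is exact under ties", {
    dd <- data.frame(sample_id = paste0("s", 1:8),
                     cell_type = "astrocyte",
                     condition = rep(c("vehicle", "LPS"), each = 4),
                     event_id = "ev",
                     ddct = c(3, 3.01, 2.99, 3, -1, -1.02, -0.98, -1),
                     imputed = FALSE)
    res <- testDdct(dd, control = "vehicle")
    expect_lt(res$p, 1e-8)
    ident <- dd
    ident$ddct <- 2
    expect_equal(testDdct(ident, control = "vehicle")$p, 1)
    few <- dd[c(1, 5:8), ]
    expect_warning(out <- testDdct(few, control = "vehicle"),
                   "fewer than 2 samples")
    expect_null(out)
})

test_that("ddCt under the null keeps the BH-adjusted rate at bay", {
    hits <- 0
    total <- 0
    for (seed in 1:20) {
        set.seed(seed)
        rows <- expand.grid(event_id = sprintf("ev%02d", 1:27),
                            cell_type = c("microglia", "astrocyte",
                                          "neuron"),
                            sample_id = paste0("s", 1:8),
                            stringsAsFactors = FALSE)
        rows$condition <- ifelse(as.integer(sub("s", "",
                                                rows$sample_id)) <= 4,
                                 "vehicle", "LPS")
        rows$ddct <- rnorm(nrow(rows), 0, 0.5)
        rows$imputed <- FALSE
        res <- testDdct(rows, control = "vehicle")
        hits <- hits + sum(res$adj_p <= 0.05)
        total <- total + nrow(res)
    }
    expect_lte(hits / total, 0.10)
})

test_that("treatment ddCt is the group-mean -dCt difference", {
    md <- data.frame(sample_id = paste0("s", 1:8),
                     cell_type = "microglia",
                     condition = rep(c("saline", "LPS"), each = 4),
                     assay_id = "Tnf", assay_role = "target",
                     minus_delta_ct = c(rep(-5, 4), rep(-2, 4)),
                     imputed = FALSE)
    dd <- ddctTreatment(md, control = "saline")
    expect_equal(dd$ddct, 3)                    # ~8-fold induction
    mdEq <- md
    mdEq$minus_delta_ct <- -4
    expect_equal(ddctTreatment(mdEq, control = "saline")$ddct, 0)
})

test_that("an abolished response shows ddCt ~ 0 in the knockout", {
    ## wild-type astrocytes induce the target 8-fold; knockouts do not
    set.seed(14)
    mk <- function(geno, lpsShift) data.frame(
        sample_id = paste0(geno, 1:8), cell_type = "astrocyte",
        condition = rep(c("saline", "LPS"), each = 4),
        assay_id = paste0("tgt_", geno), assay_role = "target",
        minus_delta_ct = c(rnorm(4, -6, 0.1),
                           rnorm(4, -6 + lpsShift, 0.1)),
        imputed = FALSE)
    dd <- ddctTreatment(rbind(mk("wt", 3), mk("ko", 0)),
                        control = "saline")
    expect_gt(dd$ddct[dd$assay_id == "tgt_wt"], 2.5)
    expect_lt(abs(dd$ddct[dd$assay_id == "tgt_ko"]), 0.3)
})

test_that("ddCt is invariant to per-sample global Ct shifts", {
    set.seed(8)
    plate <- toyQpcrPlate()
    shifted <- plate
    for (s in unique(plate$sample_id)) {
        delta <- runif(1, -3, 3)
        shifted$ct[shifted$sample_id == s] <-
            shifted$ct[shifted$sample_id == s] + delta
    }
    ## keep the same pass/fail pattern so only the arithmetic is probed
    dd0 <- ddctSplicing(deltaCt(summarizeCt(plate), "Actb"),
                        c(ev1_I = "ev1", ev1_S = "ev1"))
    dd1 <- ddctSplicing(deltaCt(summarizeCt(shifted), "Actb"),
                        c(ev1_I = "ev1", ev1_S = "ev1"))
    keep <- !dd0$imputed
    expect_equal(dd1$ddct[keep], dd0$ddct[keep], tolerance = 1e-9)
})

test_that("treatment ddCt recovers simulated log2 fold changes", {
    biases <- numeric(20)
    for (seed in 1:20) {
        cfg <- simulationConfig(qpcr = list(sigma = 0.15,
                                            nReplicates = 1,
                                            intercept = 30))
        samples <- paste0(rep(c("saline", "LPS"), each = 4), "_", 1:4)
        cond <- rep(c("saline", "LPS"), each = 4)
        ab <- data.frame(sample_id = rep(samples, 2),
                         cell_type = "microglia",
                         condition = rep(cond, 2),
                         assay_id = rep(c("GeneX", "Gapdh"), each = 8),
                         assay_role = rep(c("target", "housekeeping"),
                                          each = 8),
                         abundance = c(ifelse(cond == "LPS", 8, 1),
                                       rep(2^12, 8)))
        plate <- generateQpcrPlate(ab, cfg, seed = seed)
        dd <- ddctTreatment(deltaCt(summarizeCt(plate), "Gapdh"),
                            control = "saline")
        biases[seed] <- dd$ddct - log2(8)
    }
    expect_lt(abs(mean(biases)), 0.1)
})
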