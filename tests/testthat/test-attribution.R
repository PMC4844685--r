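makeProfile <- function(m, types = c("microglia", "astrocyte", "neuron")) {
    colnames(m) <- types
    buildReferenceProfiles(
        m[, c(1, 1, 2, 2, 3, 3), drop = FALSE] * 1,  # two identical samples per type
        rep(types, each = 2), types)
}

test_that("reference profiles average within cell types", {
    expr <- cbind(m1 = c(4, 1), m2 = c(6, 3), a1 = c(2, 2), a2 = c(2, 4),
                  n1 = c(0, 10), n2 = c(0, 12))
    rownames(expr) <- c("gA", "gB")
    ct <- c("microglia", "microglia", "astrocyte", "astrocyte",
            "neuron", "neuron")
    prof <- buildReferenceProfiles(expr, ct)
    expect_equal(profileMeans(prof)["gA", ],
                 c(microglia = 5, astrocyte = 2, neuron = 0))
    ## permuting samples changes nothing
    perm <- sample(6)
    prof2 <- buildReferenceProfiles(expr[, perm], ct[perm])
    expect_equal(profileMeans(prof2), profileMeans(prof))
    ## single sample per type equals that sample
    prof1 <- buildReferenceProfiles(expr[, c(1, 3, 5)],
                                    c("microglia", "astrocyte", "neuron"))
    expect_equal(unname(profileMeans(prof1)["gB", ]), c(1, 2, 10))
    expect_error(buildReferenceProfiles(expr[, 1:4], ct[1:4]),
                 "neuron")
})

test_that("simplex projection maps pure vectors to the triangle corners", {
    m <- rbind(pure1 = c(5, 0, 0), pure3 = c(0, 0, 7),
               centre = c(1, 1, 1))
    s <- projectToSimplex(m)
    expect_equal(s[s$gene_id == "pure1", c("x", "y")],
                 data.frame(x = -1, y = 0), ignore_attr = TRUE)
    expect_equal(s[s$gene_id == "pure3", c("x", "y")],
                 data.frame(x = 0, y = sqrt(3)), ignore_attr = TRUE)
    expect_equal(s[s$gene_id == "centre", c("x", "y")],
                 data.frame(x = 0, y = sqrt(3) / 3), ignore_attr = TRUE)
    expect_equal(s$f1 + s$f2 + s$f3, rep(1, 3))
})

test_that("projection is scale-invariant and stays inside the triangle", {
    set.seed(11)
    m <- matrix(rexp(300), 100, 3,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
    s <- projectToSimplex(m)
    s2 <- projectToSimplex(m * 37.5)
    expect_equal(s2$x, s$x, tolerance = 1e-12)
    expect_equal(s2$y, s$y, tolerance = 1e-12)
    ## barycentric fractions nonnegative and normalized => inside the
    ## triangle; check the planar inequalities explicitly
    expect_true(all(s$y >= -1e-12 & s$y <= sqrt(3) + 1e-12))
    expect_true(all(sqrt(3) * s$x + s$y <= sqrt(3) + 1e-9))
    expect_true(all(-sqrt(3) * s$x + s$y <= sqrt(3) + 1e-9))
    ## all-zero genes are excluded with a recorded reason
    m0 <- rbind(m, dead = c(0, 0, 0))
    s0 <- projectToSimplex(m0)
    expect_false("dead" %in% s0$gene_id)
    expect_identical(attr(s0, "excluded")$gene_id, "dead")
})

test_that("marker selection honours the fold threshold and pseudocount", {
    m <- rbind(boundary = c(100, 5, 4),
               under = c(100, 6, 4),
               zeros = c(50, 0, 0))
    prof <- makeProfile(m)
    ## pseudocount 0: (100/5, 100/4) both >= 20 -> marker
    mk0 <- selectMarkers(prof, fold = 20, pseudocount = 0)
    expect_true("boundary" %in% markerGenes(mk0$microglia))
    expect_false("under" %in% markerGenes(mk0$microglia))
    ## default pseudocount 0.1: 50.1 / 0.1 = 501 >> 20
    mk <- selectMarkers(prof, fold = 20, pseudocount = 0.1)
    expect_true("zeros" %in% markerGenes(mk$microglia))
    expect_error(selectMarkers(prof, fold = 1), "> 1")
})

test_that("marker sets are disjoint across cell types", {
    set.seed(5)
    m <- matrix(rlnorm(600, 2, 2), 200, 3,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
    mk <- selectMarkers(makeProfile(m), fold = 2)
    all3 <- unlist(lapply(mk, markerGenes))
    expect_false(anyDuplicated(all3) > 0)
})

test_that("attribution assigns by dominant share with the tie rule", {
    prof <- makeProfile(rbind(dominant = c(18, 1, 1),
                              spread = c(4, 3.5, 2.5),
                              tied = c(5, 5, 0)))
    de <- data.frame(gene_id = c("dominant", "spread", "tied", "ghost"),
                     log2_fc = c(2, 2, 2, 2),
                     p_value = rep(0.001, 4), adj_p = rep(0.01, 4),
                     prefilter_pass = TRUE,
                     mean_ctrl = 10, mean_trt = 40)
    calls <- attributeBulkChanges(de, prof)
    expect_equal(calls$assigned[calls$gene_id == "dominant"], "microglia")
    expect_equal(calls$assigned[calls$gene_id == "spread"], "mixed")
    ## equal shares and equal absolute expression: first type in order
    expect_equal(calls$assigned[calls$gene_id == "tied"], "microglia")
    expect_equal(calls$assigned[calls$gene_id == "ghost"], "unassigned")
    expect_equal(rowSums(calls[calls$gene_id != "ghost",
                               c("share_t1", "share_t2", "share_t3")]),
                 rep(1, 3), ignore_attr = TRUE)
    ## non-significant genes are not attributed at all
    de2 <- de; de2$adj_p <- 0.2
    expect_equal(nrow(attributeBulkChanges(de2, prof)), 0)
})

test_that("higher absolute expression wins between co-upregulated types", {
    ## both genes up in bulk; gfapLike has 10x higher astrocyte level
    prof <- makeProfile(rbind(gfapLike = c(3, 30, 0.5),
                              micLike = c(30, 3, 0.5)))
    de <- data.frame(gene_id = c("gfapLike", "micLike"),
                     log2_fc = c(2, 2), p_value = 0.001, adj_p = 0.01,
                     prefilter_pass = TRUE, mean_ctrl = 5, mean_trt = 20)
    calls <- attributeBulkChanges(de, prof)
    expect_equal(calls$assigned, c("astrocyte", "microglia"))
})

test_that("change-mode classification follows sorted evidence and priors", {
    prof <- makeProfile(rbind(gComp = c(20, 1, 1),
                              gReg = c(20, 1, 1),
                              gNeu = c(1, 1, 20)))
    de <- data.frame(gene_id = c("gComp", "gReg", "gNeu"),
                     log2_fc = c(log2(3), log2(3), 1.5),
                     p_value = 0.001, adj_p = 0.01, prefilter_pass = TRUE,
                     mean_ctrl = 10, mean_trt = 30)
    calls <- attributeBulkChanges(de, prof)
    sortedNull <- function(genes, lfc = 0, adj = 0.8)
        data.frame(gene_id = genes, log2_fc = lfc, p_value = adj,
                   adj_p = adj, prefilter_pass = TRUE,
                   mean_ctrl = 1, mean_trt = 1)
    mic <- sortedNull(de$gene_id)
    mic[mic$gene_id == "gReg", c("log2_fc", "p_value", "adj_p")] <-
        list(log2(2.5), 0.001, 0.01)
    sorted <- list(microglia = mic,
                   astrocyte = sortedNull(de$gene_id),
                   neuron = sortedNull(de$gene_id))
    ## with a microglial composition prior
    cls <- classifyChangeMode(calls, sorted,
                              compositionTypes = "microglia")
    expect_equal(cls$change_mode[cls$gene_id == "gComp"], "composition")
    expect_equal(cls$change_mode[cls$gene_id == "gReg"], "both")
    ## neuron: unchanged sorted, no prior -> unassigned
    expect_equal(cls$change_mode[cls$gene_id == "gNeu"], "unassigned")
    ## without the prior the sorted-significant gene is pure regulation
    cls2 <- classifyChangeMode(calls, sorted)
    expect_equal(cls2$change_mode[cls2$gene_id == "gReg"], "regulation")
    expect_equal(cls2$change_mode[cls2$gene_id == "gComp"], "unassigned")
    ## a missing sorted table leaves genes unassigned with a warning
    expect_warning(
        cls3 <- classifyChangeMode(calls, sorted[c("astrocyte", "neuron")],
                                   compositionTypes = "microglia"),
        "no sorted-cell differential table")
    expect_true(all(cls3$change_mode[cls3$assigned == "microglia"] ==
                    "unassigned"))
})

test_that("marker shift detects a shifted marker distribution", {
    set.seed(21)
    genes <- sprintf("g%03d", 1:300)
    lfc <- rnorm(300, 0, 0.1)
    lfc[1:30] <- lfc[1:30] + 1
    de <- data.frame(gene_id = genes, log2_fc = lfc, p_value = 0.5,
                     adj_p = 0.5, prefilter_pass = TRUE,
                     mean_ctrl = 10, mean_trt = 10)
    mk <- list(microglia = new("MarkerSet", cellType = "microglia",
                               genes = genes[1:30], fold = 20,
                               pseudocount = 0.1))
    d <- markerShiftDiagnostic(mk, de)
    expect_equal(d$shift, 1, tolerance = 0.15)
    expect_lt(d$p_value, 1e-6)
    ## an empty marker set is skipped with a warning
    mk$astrocyte <- new("MarkerSet", cellType = "astrocyte",
                        genes = character(), fold = 20, pseudocount = 0.1)
    expect_warning(d2 <- markerShiftDiagnostic(mk, de), "no markers")
    expect_true(is.na(d2$shift[d2$cell_type == "astrocyte"]))
})

test_that("markers drawn from the background show no systematic shift", {
    pvals <- numeric(20)
    shifts <- numeric(20)
    genes <- sprintf("g%03d", 1:300)
    for (seed in 1:20) {
        set.seed(seed)
        de <- data.frame(gene_id = genes, log2_fc = rnorm(300),
                         p_value = 0.5, adj_p = 0.5,
                         prefilter_pass = TRUE, mean_ctrl = 1,
                         mean_trt = 1)
        mk <- list(x = new("MarkerSet", cellType = "microglia",
                           genes = sample(genes, 30), fold = 20,
                           pseudocount = 0.1))
        d <- markerShiftDiagnostic(mk, de)
        pvals[seed] <- d$p_value
        shifts[seed] <- d$shift
    }
    expect_lte(mean(pvals <= 0.05), 0.25)      # near-uniform p under null
    expect_lt(abs(mean(shifts)), 0.15)
})

test_that("heat-map transform floors, Z-scores per dataset, and caps", {
    ## flooring: log2(0.001) ~ -9.97 -> -4 before Z
    m <- rbind(g1 = c(0.001, 1, 16), g2 = c(2, 2, 2))
    colnames(m) <- paste0("s", 1:3)
    z <- heatmapZscoreMatrix(m)
    ## post-floor row (-4, 0, 4): Z = (-1, 0, 1)
    expect_equal(unname(z["g1", ]), c(-1, 0, 1))
    expect_equal(unname(z["g2", ]), c(0, 0, 0))   # constant row
    ## Z-scoring is per dataset label
    m2 <- rbind(g = c(1, 2, 4, 256, 512, 1024))
    colnames(m2) <- paste0("s", 1:6)
    z2 <- heatmapZscoreMatrix(m2, datasetLabels = rep(c("d1", "d2"),
                                                      each = 3))
    expect_equal(unname(z2["g", 1:3]), unname(z2["g", 4:6]))
    ## capping: one extreme sample among many near-constant ones
    vals <- c(rep(1, 40), 2^40)
    m3 <- matrix(vals, 1, dimnames = list("g", NULL))
    z3 <- heatmapZscoreMatrix(m3)
    expect_equal(max(z3), 4)
    expect_error(heatmapZscoreMatrix(m, floor = 4, cap = -4), "less than")
})

test_that("variable-gene selection is by SD with deterministic ties", {
    set.seed(3)
    m <- matrix(rnorm(200 * 6), 200, 6,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
    sel <- selectVariableGenes(m, fraction = 0.025)
    expect_length(sel, 5)                     # ceiling(0.025 * 200)
    ## a dominant-SD gene ranks first
    m["g117", ] <- c(-20, 20, -20, 20, -20, 20)
    expect_equal(selectVariableGenes(m, 0.025)[1], "g117")
    ## exact ties broken lexicographically
    tied <- rbind(b = c(0, 1), a = c(1, 2), c = c(5, 5))
    expect_equal(selectVariableGenes(tied, fraction = 0.5), c("a", "b"))
})

test_that("probe collapse keeps the highest-IQR probe per gene", {
    pm <- rbind(p1 = c(1, 2, 3, 4),      # IQR 1.5
                p2 = c(0, 5, 10, 15),    # IQR 7.5
                p3 = c(9, 9, 9, 9))
    map <- data.frame(probe_id = c("p1", "p2", "p3"),
                      gene_id = c("gA", "gA", "gB"))
    out <- collapseProbesByIQR(pm, map)
    expect_equal(unname(out["gA", ]), unname(pm["p2", ]))
    expect_equal(unname(out["gB", ]), unname(pm["p3", ]))
    ## IQR tie -> lexicographically smallest probe id
    pm2 <- rbind(pz = c(1, 2, 3), pa = c(2, 3, 4))
    map2 <- setNames(c("g", "g"), c("pz", "pa"))
    expect_equal(attr(collapseProbesByIQR(pm2, map2),
                      "probe_selected")[["g"]], "pa")
    expect_error(collapseProbesByIQR(pm, setNames(c("gA", "gB"),
                                                  c("p1", "p1"))),
                 "at most one gene")
})

test_that("four-way pairing flattens sub-threshold genes to FC = 1", {
    deA <- data.frame(gene_id = c("g1", "g2", "g3"),
                      log2_fc = c(0.3, 2, 0.2),
                      p_value = c(0.9, 0.001, 0.9),
                      adj_p = c(0.9, 0.01, 0.9),
                      prefilter_pass = TRUE,
                      mean_ctrl = c(0.2, 10, 0.5),
                      mean_trt = c(0.4, 40, 0.6))
    deB <- data.frame(gene_id = c("g1", "g2", "g3"),
                      log2_fc = c(log2(5), 2, 0.1),
                      p_value = c(0.001, 0.001, 0.9),
                      adj_p = c(0.01, 0.01, 0.9),
                      prefilter_pass = TRUE,
                      mean_ctrl = c(5, 12, 0.3),
                      mean_trt = c(25, 50, 0.4))
    fw <- prepareFourway(deA, deB)   # A = astrocyte-like, B = microglia-like
    ## g1: unexpressed in A -> (FC 1, 5x), B-only
    expect_equal(fw$log2_fc_a[fw$gene_id == "g1"], 0)
    expect_equal(fw$log2_fc_b[fw$gene_id == "g1"], log2(5))
    expect_equal(fw$category[fw$gene_id == "g1"], "b-only")
    expect_equal(fw$category[fw$gene_id == "g2"], "both")
    ## below threshold in both contrasts -> (1, 1), no category
    expect_equal(unlist(fw[fw$gene_id == "g3",
                           c("log2_fc_a", "log2_fc_b")]),
                 c(log2_fc_a = 0, log2_fc_b = 0))
    expect_equal(fw$category[fw$gene_id == "g3"], "none")
})
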