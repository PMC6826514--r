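test_that("the same config and seed reproduce the dataset exactly", {
    cfg <- simulationConfig(n_genes = 40, conditions = c("A", "B"),
                            modules = list(list(
                                genes = c("G0001", "G0002"),
                                loadings = c(1, -1), strength = 0.9)))
    d1 <- simulateDataset(cfg, seed = 99)
    d2 <- simulateDataset(cfg, seed = 99)
    expect_identical(assay(rawData(d1), "foreground"),
                     assay(rawData(d2), "foreground"))
    expect_identical(groundTruth(d1), groundTruth(d2))
    d3 <- simulateDataset(cfg, seed = 100)
    expect_false(identical(assay(rawData(d1), "foreground"),
                           assay(rawData(d3), "foreground")))
})

test_that("zero noise and no factors yield identical replicates", {
    cfg <- simulationConfig(n_genes = 10, conditions = "A",
                            replicate_cv = 0, spot_noise_cv = 0,
                            background_cv = 0, fraction_control = 0,
                            fraction_corrupted = 0,
                            fraction_low_signal = 0)
    ds <- simulateDataset(cfg, 1)
    st <- computeREV(summarizeTranscripts(
        normalizeIterative(filterSpots(rawData(ds)))))
    expect_true(all(st@table$rev == 0))
    prof <- replicateProfile(st, "A")
    expect_true(all(apply(prof, 1, sd) == 0))
})

test_that("programmed correlation signs drive downstream rho", {
    # designated pairs embedded in a larger pool of unrelated,
    # well-quantified genes: median normalization needs a dense array
    # for stable per-sample scale factors
    cfg <- simulationConfig(
        n_genes = 500, conditions = "A", replicate_cv = 20,
        spot_noise_cv = 0, fraction_control = 0, fraction_corrupted = 0,
        fraction_low_signal = 0,
        base_level_log2 = function(n) rnorm(n, 1.5, 1),
        redundancy_sampler = function(n) rep(2L, n),
        modules = list(
            list(genes = c("G0001", "G0002"), loadings = c(1, 1),
                 strength = 0.999),
            list(genes = c("G0003", "G0004"), loadings = c(1, -1),
                 strength = 0.999)))
    ds <- simulateDataset(cfg, 5)
    st <- summarizeTranscripts(
        normalizeIterative(filterSpots(rawData(ds))))
    rec <- coordinatePairs(st, "A")
    r12 <- rec$rho[rec$gene_a == "G0001" & rec$gene_b == "G0002"]
    r34 <- rec$rho[rec$gene_a == "G0003" & rec$gene_b == "G0004"]
    expect_gt(r12, 0.95)
    expect_lt(r34, -0.95)
})

test_that("realized replicate CVs match the programmed value", {
    cfg <- simulationConfig(n_genes = 300, conditions = "A",
                            replicate_cv = 20, spot_noise_cv = 0,
                            fraction_control = 0, fraction_corrupted = 0,
                            fraction_low_signal = 0)
    ds <- simulateDataset(cfg, 7)
    se <- rawData(ds)
    v <- assay(se, "signal")
    rd <- rowData(se)
    cvs <- vapply(unique(rd$transcript_id), function(g) {
        prof <- colMeans(v[rd$transcript_id == g, , drop = FALSE])
        100 * sd(prof) / mean(prof)
    }, 0)
    expect_lt(abs(median(cvs) / 20 - 1), 0.10)
})

test_that("injected filter labels match the configured fractions", {
    cfg <- simulationConfig(n_genes = 400, conditions = "A",
                            fraction_control = 0.05,
                            fraction_corrupted = 0.02,
                            fraction_low_signal = 0.03)
    ds <- simulateDataset(cfg, 3)
    truth <- groundTruth(ds)$spots
    n_gene_spots <- sum(truth$label != "control")
    expect_equal(sum(truth$label == "corrupted") / n_gene_spots, 0.02,
                 tolerance = 0.15)
    expect_equal(sum(truth$label == "low_signal") / n_gene_spots, 0.03,
                 tolerance = 0.15)
    # the filter agrees with the truth labels
    se <- filterSpots(rawData(ds))
    rep <- filterReport(se)
    expect_equal(rep$n_removed_control, sum(truth$label == "control"))
    expect_equal(rep$n_removed_corrupted, sum(truth$label == "corrupted"))
    expect_gte(rep$n_removed_low_signal, sum(truth$label == "low_signal"))
})

test_that("truth tables list designated pairs and round-trip", {
    cfg <- simulationConfig(n_genes = 10, conditions = "A",
                            modules = list(list(
                                genes = c("G0001", "G0002", "G0003"),
                                loadings = c(1, 1, 1), strength = 0.9)))
    ds <- simulateDataset(cfg, 2)
    truth <- groundTruth(ds)
    expect_equal(nrow(truth$pairs), 3)          # C(3,2) positive pairs
    expect_true(all(truth$pairs$true_sign == "+"))
    expect_equal(truth$pairs$true_rho, rep(0.9, 3))
    dir <- tempfile()
    paths <- groundTruthReport(ds, dir)
    expect_true(all(file.exists(paths)))
    back <- read.delim(paths[["pairs"]])
    expect_equal(back$true_rho, truth$pairs$true_rho)
    expect_equal(back$gene_a, truth$pairs$gene_a)
})

test_that("infeasible variance decompositions are rejected", {
    expect_error(simulateDataset(simulationConfig(
        n_genes = 4, conditions = "A",
        modules = list(
            list(genes = c("G0001", "G0002"), loadings = c(1, 1),
                 strength = 0.7),
            list(genes = c("G0001", "G0003"), loadings = c(1, 1),
                 strength = 0.7))), 1),
        "infeasible")
})

test_that("a simulated table written to disk reads back equivalently", {
    cfg <- simulationConfig(n_genes = 15, conditions = c("A", "B"))
    ds <- simulateDataset(cfg, 4)
    p <- tempfile(fileext = ".tsv")
    writeSpotTable(ds, p)
    se <- readSpotTable(p)
    expect_equal(dim(se), dim(rawData(ds)))
    expect_equal(assay(se, "foreground"),
                 assay(rawData(ds), "foreground")[rownames(se),
                                                  colnames(se)],
                 tolerance = 1e-6)
})
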