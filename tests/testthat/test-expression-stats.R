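test_that("per-spot summaries use the n-1 standard deviation", {
    st <- makeStats(list(Gx = G3))
    tb <- st@table
    expect_equal(tb$combined_mean, 1.00)
    expect_equal(tb$spot_means[[1]], 1.00)
    expect_equal(tb$spot_sds[[1]], 0.41633, tolerance = 1e-4)

    st <- makeStats(list(Gc = c(2, 2, 2, 2)))
    expect_equal(st@table$spot_means[[1]], 2)
    expect_equal(st@table$spot_sds[[1]], 0)

    # combined mean is the mean of spot means
    st <- makeStats(list(Gm = rbind(c(1, 1, 1, 1), c(3, 3, 3, 3))))
    expect_equal(st@table$combined_mean, 2.0)
    expect_equal(st@table$redundancy, 2L)
})

test_that("coefficient of variation reproduces the worked example", {
    expect_equal(round(coefficientOfVariation(G3)), 42)
    expect_equal(coefficientOfVariation(G3), 41.63, tolerance = 1e-3)
    expect_equal(round(coefficientOfVariation(G1)), 5)
    expect_equal(coefficientOfVariation(c(7, 7, 7)), 0)
    expect_error(coefficientOfVariation(c(-1, 1)), "zero mean")
    expect_error(coefficientOfVariation(3), "at least 2")
})

test_that("redundancy correction matches an independent quantile oracle", {
    cfg <- revConfig()
    # sigma-CI convention at R = 1: df = 3
    lo <- oracleChisqQuantile(0.025, 3)
    hi <- oracleChisqQuantile(0.975, 3)
    expect_equal(redundancyCorrection(1, cfg),
                 0.5 * (sqrt(3 / hi) + sqrt(3 / lo)), tolerance = 1e-8)
    # spot checks across the redundancy range and both conventions
    for (R in c(2, 7, 28)) {
        df <- 4 * R - 1
        lo <- oracleChisqQuantile(0.025, df)
        hi <- oracleChisqQuantile(0.975, df)
        expect_equal(redundancyCorrection(R, cfg),
                     0.5 * (sqrt(df / hi) + sqrt(df / lo)),
                     tolerance = 1e-8)
        expect_equal(redundancyCorrection(R, revConfig(
                         quantile_convention = "variance-ci")),
                     0.5 * (df / hi + df / lo), tolerance = 1e-8)
    }
    expect_error(redundancyCorrection(0, cfg), ">= 1")
})

test_that("the correction is positive and non-increasing in redundancy", {
    for (conv in c("sigma-ci", "variance-ci")) {
        corr <- redundancyCorrection(1:28,
                    revConfig(quantile_convention = conv))
        expect_true(all(corr > 0))
        expect_true(all(diff(corr) <= 0))
    }
})

test_that("REV collapses to correction x CV for a single spot", {
    st <- computeREV(makeStats(list(Gx = G3)))
    expect_equal(st@table$rev,
                 redundancyCorrection(1) * coefficientOfVariation(G3),
                 tolerance = 1e-10)
    # all spot SDs zero -> REV 0
    st <- computeREV(makeStats(list(Gc = c(2, 2, 2, 2))))
    expect_equal(st@table$rev, 0)
})

test_that("REV pools spot CVs as a root mean square", {
    # two spots engineered to CVs of 3% and 4%
    mk <- function(cv) {
        # values 1 + cv * z with z of zero mean, unit sample sd
        z <- c(-1, 0, 0, 1); z <- z / sd(z)
        (1 + cv * z) / mean(1 + cv * z)
    }
    m <- rbind(mk(0.03), mk(0.04))
    st <- computeREV(makeStats(list(Gp = m)))
    pooled <- sqrt((3^2 + 4^2) / 2)
    expect_equal(st@table$rev, redundancyCorrection(2) * pooled,
                 tolerance = 1e-6)
    expect_equal(pooled, sqrt(12.5))
})

test_that("REV is invariant under global rescaling of a transcript", {
    set.seed(21)
    m <- matrix(2^rnorm(12, 0, 0.3), 3, 4)
    a <- computeREV(makeStats(list(G = m)))@table$rev
    b <- computeREV(makeStats(list(G = 100 * m)))@table$rev
    expect_equal(a, b, tolerance = 1e-12)
})

test_that("REV metadata records the convention in force", {
    st <- computeREV(makeStats(list(Gx = G3)))
    md <- revMetadata(st)
    expect_equal(md$rev_convention, "sigma-ci")
    expect_equal(md$rev_epsilon, 0.05)
    expect_true(all(c("R1", "R28") %in% names(
        md$rev_correction_endpoints)))
})

test_that("regulation calls act on fold change and corrected p", {
    two_cond <- function(va, vb) {
        mats <- list(A = va, B = vb)
        df <- do.call(rbind, lapply(names(mats), function(cn)
            data.frame(spot_id = "s1", transcript_id = "Gx",
                       condition = cn, replicate = 1:4,
                       value = mats[[cn]], is_control = FALSE,
                       is_corrupted = FALSE, stringsAsFactors = FALSE)))
        se <- genofabric:::.spotExperimentFromLong(
            df, spotDialect("pre-normalized"))
        summarizeTranscripts(se, assay_name = "signal")
    }
    st <- two_cond(G1, G1)
    rc <- regulationCall(st, "Gx", "A", "B")
    expect_equal(rc$fold_change, 1.0)
    expect_equal(rc$status, "NC")

    set.seed(22)
    base <- 2^rnorm(4, 0, 0.05)
    up <- 2.5 * 2^rnorm(4, 0, 0.05)
    st <- two_cond(up, base)
    rc <- regulationCall(st, "Gx", "A", "B")
    expect_equal(rc$status, "UP")
    expect_equal(rc$p_value, oracleWelchP(up, base), tolerance = 1e-10)
    expect_gte(rc$corrected_p, rc$p_value)

    st <- two_cond(1.2 * base, base)
    rc <- regulationCall(st, "Gx", "A", "B")
    expect_equal(rc$status, "NC")

    st <- two_cond(base / 2.5, base)
    rc <- regulationCall(st, "Gx", "A", "B")
    expect_equal(rc$status, "DOWN")
    expect_lt(rc$fold_change, -1.5)
})

test_that("group summaries average REVs and normalize medians", {
    st <- computeREV(makeStats(list(Ga = G1, Gb = G2, Gc = G3)))
    gs <- groupSummary(st, c("Ga", "Gb", "Gc"), "A")
    expect_equal(gs$mean_rev, mean(st@table$rev))
    expect_equal(gs$n_genes, 3)
    one <- groupSummary(st, "Ga", "A")
    expect_equal(one$mean_rev, st@table$rev[1])
    expect_error(groupSummary(st, character(0), "A"), "empty")
})

test_that("REV distribution comparison is a two-tailed Welch test", {
    expect_equal(compareREVDistributions(1:4, 1:4), 1)
    expect_lt(compareREVDistributions(c(1, 2, 3, 4),
                                      c(101, 102, 103, 104)), 1e-6)
    set.seed(23)
    for (i in 1:5) {
        a <- rnorm(10, 20, 5); b <- rnorm(8, 25, 8)
        expect_equal(compareREVDistributions(a, b), oracleWelchP(a, b),
                     tolerance = 1e-10)
    }
})
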