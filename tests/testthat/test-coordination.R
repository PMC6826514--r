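test_that("replicate correlations reproduce the worked example", {
    expect_equal(pearsonRho(G1, G2), -0.985, tolerance = 5e-4)
    expect_equal(pearsonRho(G2, G3), 0.986, tolerance = 5e-4)
    x <- c(1, 2, 3, 5)
    expect_equal(pearsonRho(x, x), 1)
    expect_equal(pearsonRho(x, 10 - x), -1)
    expect_true(is.na(pearsonRho(x, c(2, 2, 2, 2))))
    expect_error(pearsonRho(x, x[1:3]), "length")
})

test_that("degrees of freedom follow the 4R - 2 rule", {
    expect_equal(pairDF(1, 1), 2L)
    expect_equal(pairDF(2, 2), 6L)
    expect_equal(pairDF(3, 3), 10L)
    # unequal redundancy: conservative min rule by default
    expect_equal(pairDF(1, 3), 2L)
    expect_equal(pairDF(2, 5), 6L)
    # all-spot-pairings alternative
    expect_equal(pairDF(2, 3, rule = "allspots"), 22L)
    expect_error(pairDF(0, 1), ">= 1")
})

test_that("critical rho matches the printed thresholds and a numeric
           t-quantile oracle", {
    expect_equal(round(criticalRho(2, 0.05), 2), 0.95)
    expect_equal(round(criticalRho(6, 0.05), 2), 0.71)
    for (df in c(1:10, 20, 50, 120)) {
        tstar <- oracleTQuantile(0.975, df)
        expect_equal(criticalRho(df, 0.05), tstar / sqrt(tstar^2 + df),
                     tolerance = 1e-9)
    }
    # strictly decreasing in df, increasing as alpha decreases
    expect_true(all(diff(criticalRho(1:120, 0.05)) < 0))
    expect_true(all(criticalRho(1:120, 0.01) > criticalRho(1:120, 0.05)))
})

test_that("classification respects thresholds and sign symmetry", {
    cfg <- classificationConfig()
    expect_equal(classifyPair(0.99, 2, cfg), "POS")
    expect_equal(classifyPair(-0.96, 2, cfg), "NEG")
    expect_equal(classifyPair(0.30, 2, cfg), "UNCLASSIFIED")
    expect_equal(classifyPair(0.01, 2, cfg), "IND")
    expect_equal(classifyPair(NA, 2, cfg), "UNCLASSIFIED")
    # negating rho swaps POS and NEG, fixes IND/UNCLASSIFIED
    set.seed(31)
    for (rho in runif(50, -1, 1)) {
        for (df in c(2, 6, 10)) {
            a <- classifyPair(rho, df, cfg)
            b <- classifyPair(-rho, df, cfg)
            swapped <- c(POS = "NEG", NEG = "POS", IND = "IND",
                         UNCLASSIFIED = "UNCLASSIFIED")
            expect_equal(b, unname(swapped[a]))
        }
    }
})

test_that("pair enumeration is combinatorially exact", {
    expect_equal(countPairs(3), 3)
    expect_equal(nrow(enumeratePairs(c("c", "a", "b"))), 3)
    # brute-force check on small sets
    for (n in 2:8) {
        genes <- paste0("g", seq_len(n))
        pairs <- enumeratePairs(genes)
        expect_equal(nrow(pairs), countPairs(n))
        expect_equal(anyDuplicated(apply(pairs, 1, function(r)
            paste(sort(r), collapse = "|"))), 0)
        expect_true(all(pairs[, 1] < pairs[, 2]))  # canonical order
    }
    x <- enumeratePairs(c("a", "b"), c("c", "d", "e"))
    expect_equal(nrow(x), 6)
    expect_error(enumeratePairs(c("a", "b"), c("b", "c")), "disjoint")
})

test_that("coordination records cover the full pair universe", {
    set.seed(32)
    genes <- paste0("G", 1:6)
    vals <- lapply(genes, function(g) 2^rnorm(4, 0, 0.3))
    names(vals) <- genes
    vals$G6 <- rep(1, 4)  # constant profile -> undefined correlation
    st <- makeStats(vals)
    rec <- coordinatePairs(st, "A", genes)
    expect_equal(nrow(rec), countPairs(6))
    expect_true(all(rec$classification[rec$gene_a == "G6" |
                                       rec$gene_b == "G6"] ==
                    "UNCLASSIFIED"))
    expect_true(all(is.na(rec$rho) | abs(rec$rho) <= 1))
    # POS implies rho > 0 and p < alpha; NEG the mirror image
    pos <- rec$classification == "POS"
    neg <- rec$classification == "NEG"
    expect_true(all(rec$rho[pos] > 0 & rec$p_value[pos] < 0.05))
    expect_true(all(rec$rho[neg] < 0 & rec$p_value[neg] < 0.05))
})

test_that("log2 transform is applied by default and can be disabled", {
    st <- makeStats(list(Ga = G1, Gb = G2))
    raw <- coordinatePairs(st, "A", c("Ga", "Gb"),
                           config = classificationConfig(use_log2 = FALSE))
    expect_equal(raw$rho, cor(G1, G2), tolerance = 1e-12)
    logged <- coordinatePairs(st, "A", c("Ga", "Gb"))
    expect_equal(logged$rho, cor(log2(G1), log2(G2)), tolerance = 1e-12)
})

test_that("the all-spot-pairings rule stacks every spot combination", {
    set.seed(33)
    ma <- matrix(2^rnorm(8, 0, 0.2), 2, 4)
    mb <- matrix(2^rnorm(4, 0, 0.2), 1, 4)
    st <- makeStats(list(Ga = ma, Gb = mb))
    cfg <- classificationConfig(use_log2 = FALSE,
                                unequal_redundancy_rule = "allspots")
    rec <- coordinatePairs(st, "A", c("Ga", "Gb"), config = cfg)
    xa <- c(t(ma[c(1, 2), ])); xb <- c(t(mb[c(1, 1), ]))
    expect_equal(rec$rho, cor(xa, xb), tolerance = 1e-12)
    expect_equal(rec$df, 4L * 2L * 1L - 2L)
})

test_that("reversal detection flags opposite significant signs only", {
    # fixture mirroring the printed reversal table: values significant
    # at df = 6 (genes probed by two spots)
    mkrec <- function(pairs, rho, cls) {
        data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                   condition = "x", rho = rho, df = 6,
                   p_value = NA_real_, classification = cls,
                   stringsAsFactors = FALSE)
    }
    pairs <- rbind(c("Adcy8", "Calm2"), c("Atp2b1", "Camk4"),
                   c("Calm1", "Calm2"), c("Grm5", "Oxtr"))
    a <- mkrec(pairs, c(0.93590, -0.90327, 0.95, 0.80),
               c("POS", "NEG", "POS", "UNCLASSIFIED"))
    b <- mkrec(pairs, c(-0.90817, 0.96986, 0.97, -0.95),
               c("NEG", "POS", "POS", "NEG"))
    rv <- detectReversals(a, b)
    expect_equal(nrow(rv), 2)
    expect_setequal(rv$gene_a, c("Adcy8", "Atp2b1"))
    expect_equal(rv$rho_a[rv$gene_a == "Adcy8"], 0.93590)
    expect_equal(rv$rho_b[rv$gene_a == "Adcy8"], -0.90817)
    # POS in both -> absent; POS vs UNCLASSIFIED -> absent
    expect_false("Calm1" %in% rv$gene_a)
    expect_false("Grm5" %in% rv$gene_a)
    # symmetric up to role swap
    rv2 <- detectReversals(b, a)
    expect_setequal(paste(rv$gene_a, rv$gene_b),
                    paste(rv2$gene_a, rv2$gene_b))
    expect_error(detectReversals(a, a[1:2, ]), "universes")
})

test_that("factor-imposed coordination is recovered with the right sign", {
    genes <- sprintf("G%04d", 1:60)
    cfg <- simulationConfig(
        n_genes = 60, conditions = "A", replicate_cv = 20,
        spot_noise_cv = 0, fraction_control = 0, fraction_corrupted = 0,
        fraction_low_signal = 0,
        base_level_log2 = function(n) rnorm(n, 1.5, 1),
        redundancy_sampler = function(n) rep(2L, n),
        modules = list(
            list(genes = genes[1:6], loadings = rep(1, 6),
                 strength = 0.99),
            list(genes = genes[7:12],
                 loadings = c(1, 1, 1, -1, -1, -1), strength = 0.99)))
    hits <- 0; total <- 0; inverted <- 0
    for (seed in 1:5) {
        ds <- simulateDataset(cfg, seed)
        st <- summarizeTranscripts(
            normalizeIterative(filterSpots(rawData(ds))))
        rec <- coordinatePairs(st, "A", genes[1:12])
        truth <- groundTruth(ds)$pairs
        key <- function(d) paste(d$gene_a, d$gene_b)
        m <- match(key(truth), key(rec))
        got <- rec$classification[m]
        want <- ifelse(truth$true_sign == "+", "POS", "NEG")
        total <- total + length(got)
        hits <- hits + sum(got == want)
        opp <- c("POS" = "NEG", "NEG" = "POS")
        inverted <- inverted +
            sum(got == opp[want] & abs(truth$true_rho) >= 0.99)
    }
    expect_gte(hits / total, 0.9)
    expect_equal(inverted, 0)
})
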