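# Fixture builders and independent oracles used across the suite.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Long-format spot table rows for a fully crossed design.
makeSpotLong <- function(spot_ids, transcripts, conditions = "A",
                         replicates = 1:4, fg, bg = NULL,
                         is_control = FALSE, is_corrupted = FALSE) {
    grid <- expand.grid(si = seq_along(spot_ids), condition = conditions,
                        replicate = replicates, stringsAsFactors = FALSE)
    n <- nrow(grid)
    data.frame(spot_id = spot_ids[grid$si],
               transcript_id = transcripts[grid$si],
               condition = grid$condition, replicate = grid$replicate,
               foreground = rep_len(fg, n),
               background = if (is.null(bg)) 100 else rep_len(bg, n),
               is_control = rep_len(is_control, length(spot_ids))[grid$si],
               is_corrupted = rep_len(is_corrupted,
                                      length(spot_ids))[grid$si],
               stringsAsFactors = FALSE)
}

writeSpotLong <- function(df, path = tempfile(fileext = ".tsv")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# SpotExperiment straight from a signal matrix (spots x samples).
makeSE <- function(values, transcripts = rownames(values),
                   conditions = "A",
                   replicates = seq_len(ncol(values) / length(conditions))) {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
    if (is.null(transcripts)) transcripts <- rownames(values)
    df <- data.frame(
        spot_id = rep(rownames(values), times = ncol(values)),
        transcript_id = rep(transcripts, times = ncol(values)),
        condition = rep(rep(conditions, each = length(replicates)),
                        each = nrow(values)),
        replicate = rep(rep(replicates, times = length(conditions)),
                        each = nrow(values)),
        value = as.vector(values),
        is_control = FALSE, is_corrupted = FALSE,
        stringsAsFactors = FALSE)
    genofabric:::.spotExperimentFromLong(df, spotDialect("pre-normalized"))
}

# TranscriptStats built from per-gene replicate matrices (one spot each) or
# a list of spot x replicate matrices per gene.
makeStats <- function(gene_values, condition = "A") {
    mats <- lapply(gene_values, function(v) {
        if (is.matrix(v)) v else matrix(v, nrow = 1)
    })
    nrep <- ncol(mats[[1]])
    rows <- do.call(rbind, lapply(names(mats), function(g) {
        m <- mats[[g]]
        data.frame(spot_id = sprintf("%s_s%d", g, seq_len(nrow(m))),
                   transcript_id = g,
                   stringsAsFactors = FALSE)
    }))
    vals <- do.call(rbind, mats)
    rownames(vals) <- rows$spot_id
    df <- data.frame(
        spot_id = rep(rows$spot_id, times = nrep),
        transcript_id = rep(rows$transcript_id, times = nrep),
        condition = condition,
        replicate = rep(seq_len(nrep), each = nrow(rows)),
        value = as.vector(vals),
        is_control = FALSE, is_corrupted = FALSE,
        stringsAsFactors = FALSE)
    se <- genofabric:::.spotExperimentFromLong(df,
              spotDialect("pre-normalized"))
    summarizeTranscripts(se, assay_name = "signal")
}

# --- independent oracles -------------------------------------------------

# chi-square quantile by numeric inversion of the CDF
oracleChisqQuantile <- function(p, df) {
    uniroot(function(x) pchisq(x, df) - p, c(1e-12, df + 200 * sqrt(df)),
            tol = 1e-12)$root
}

# t quantile by numeric inversion of the CDF
oracleTQuantile <- function(p, df) {
    uniroot(function(x) pt(x, df) - p, c(0, 1e6), tol = 1e-12)$root
}

# Welch two-sample two-tailed p-value from first principles
oracleWelchP <- function(x, y) {
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    2 * pt(-abs(tt), df)
}

G1 <- c(0.95, 0.98, 1.01, 1.06)
G2 <- c(1.05, 1.01, 1.00, 0.94)
G3 <- c(1.50, 1.10, 0.90, 0.50)
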