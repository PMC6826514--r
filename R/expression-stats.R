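#' Per-transcript, per-condition expression summaries
#'
#' Groups normalized spot values by transcript and condition.  For each spot
#' \eqn{k} probing transcript \eqn{i} the replicate mean \eqn{\mu_{ik}} and
#' sample standard deviation \eqn{s_{ik}} (n-1 denominator) are computed;
#' the transcript's combined mean is the mean of its spot means and its
#' redundancy \eqn{R_i} is its number of probing spots.  Replicate-level
#' spot-averaged profiles are retained for coordination analysis.  The REV
#' column is left unset until \code{\link{computeREV}} is applied.
#'
#' @param x a \linkS4class{SpotExperiment} carrying a \code{normalized}
#'   assay (or \code{signal}, used as fallback with a message).
#' @param assay_name assay to summarize; default \code{"normalized"}.
#' @return a \linkS4class{TranscriptStats}.
#' @export
summarizeTranscripts <- function(x, assay_name = "normalized") {
    stopifnot(is(x, "SpotExperiment"))
    if (!assay_name %in% assayNames(x))
        stop("assay '", assay_name, "' not found; run normalizeIterative()",
             " or pass assay_name explicitly")
    v <- assay(x, assay_name)
    cd <- colData(x)
    rd <- rowData(x)
    conditions <- unique(cd$condition)
    rows <- list(); profiles <- list(); spotValues <- list()
    for (cond in conditions) {
        cols <- which(cd$condition == cond)
        if (length(cols) < 2)
            stop("condition '", cond, "' has fewer than 2 replicates")
        sub <- v[, cols, drop = FALSE]
        sub <- sub[, order(cd$replicate[cols]), drop = FALSE]
        tx <- sort(unique(rd$transcript_id))
        prof <- matrix(NA_real_, length(tx), ncol(sub),
                       dimnames = list(tx, NULL))
        sv <- vector("list", length(tx)); names(sv) <- tx
        tab <- vector("list", length(tx))
        for (j in seq_along(tx)) {
            idx <- which(rd$transcript_id == tx[j])
            m <- sub[idx, , drop = FALSE]
            mu <- rowMeans(m)
            s <- apply(m, 1, stats::sd)
            prof[j, ] <- colMeans(m)
            sv[[j]] <- m
            tab[[j]] <- list(transcript_id = tx[j], condition = cond,
                             redundancy = length(idx),
                             combined_mean = mean(mu),
                             spot_means = unname(mu), spot_sds = unname(s))
        }
        rows <- c(rows, tab)
        profiles[[cond]] <- prof
        spotValues[[cond]] <- sv
    }
    tb <- DataFrame(
        transcript_id = vapply(rows, `[[`, "", "transcript_id"),
        condition = vapply(rows, `[[`, "", "condition"),
        redundancy = vapply(rows, `[[`, 0L, "redundancy"),
        combined_mean = vapply(rows, `[[`, 0, "combined_mean"),
        rev = NA_real_)
    tb$spot_means <- lapply(rows, `[[`, "spot_means")
    tb$spot_sds <- lapply(rows, `[[`, "spot_sds")
    methods::new("TranscriptStats", table = tb, profiles = profiles,
                 spotValues = spotValues, metadata = list())
}

#' Coefficient of variation, in percent
#'
#' @param values numeric vector of length >= 2 with nonzero mean.
#' @return \code{100 * sd(values) / mean(values)} (n-1 denominator).
#' @examples
#' coefficientOfVariation(c(1.50, 1.10, 0.90, 0.50))  # ~41.6
#' @export
coefficientOfVariation <- function(values) {
    if (length(values) < 2) stop("need at least 2 values")
    m <- mean(values)
    if (m == 0) stop("zero mean: CV undefined")
    100 * stats::sd(values) / m
}

#' Configuration of the REV estimator
#'
#' The relative expression variability multiplies the pooled CV by a
#' redundancy-dependent correction: the mid-point of a chi-square interval
#' estimate at \code{4 R - 1} degrees of freedom and significance level
#' \code{epsilon}.  The exact quantile convention behind the interval is
#' configurable:
#' \describe{
#'   \item{\code{"sigma-ci"}}{(default) mid-point of the confidence interval
#'     for a standard deviation:
#'     \eqn{\frac12(\sqrt{df/\chi^2_{1-\epsilon/2}} +
#'     \sqrt{df/\chi^2_{\epsilon/2}})}.}
#'   \item{\code{"variance-ci"}}{same without the square roots (interval for
#'     a variance).}
#' }
#' Neither convention reproduces the historically reported endpoint values
#' of the correction exactly; the convention in force and its R = 1 and
#' R = 28 endpoints are therefore recorded in the result metadata rather
#' than silently absorbed.
#'
#' @param epsilon significance level of the interval (default 0.05).
#' @param replicates_per_spot biological replicates per spot (default 4);
#'   degrees of freedom are \code{replicates_per_spot * R - 1}.
#' @param quantile_convention \code{"sigma-ci"} or \code{"variance-ci"}.
#' @return a \code{rev_config} list.
#' @export
revConfig <- function(epsilon = 0.05, replicates_per_spot = 4L,
                      quantile_convention = c("sigma-ci", "variance-ci")) {
    stopifnot(epsilon > 0, epsilon < 1, replicates_per_spot >= 2)
    structure(list(epsilon = epsilon,
                   replicates_per_spot = as.integer(replicates_per_spot),
                   quantile_convention = match.arg(quantile_convention)),
              class = "rev_config")
}

#' Redundancy correction factor of the REV estimator
#'
#' Mid chi-square interval factor at \code{replicates_per_spot * R - 1}
#' degrees of freedom and level \code{epsilon}; monotonically non-increasing
#' in the redundancy R, so transcripts probed by many spots get slightly
#' smaller (more credited) variability estimates.
#'
#' @param redundancy integer R >= 1 (vectorized).
#' @param config a \code{\link{revConfig}}.
#' @return positive correction factor(s).
#' @export
redundancyCorrection <- function(redundancy, config = revConfig()) {
    stopifnot(inherits(config, "rev_config"))
    if (any(redundancy < 1)) stop("redundancy must be >= 1")
    df <- config$replicates_per_spot * redundancy - 1
    lo <- stats::qchisq(config$epsilon / 2, df)
    hi <- stats::qchisq(1 - config$epsilon / 2, df)
    switch(config$quantile_convention,
           "sigma-ci" = 0.5 * (sqrt(df / hi) + sqrt(df / lo)),
           "variance-ci" = 0.5 * (df / hi + df / lo))
}

#' Pooled, redundancy-corrected relative expression variability
#'
#' For each transcript and condition,
#' \deqn{REV_i = correction(R_i) \times 100 \sqrt{\frac{1}{R_i}
#'   \sum_{k=1}^{R_i} (s_{ik}/\mu_{ik})^2},}
#' i.e. the root-mean-square of the per-spot CVs times the chi-square
#' mid-interval redundancy correction (see
#' \code{\link{redundancyCorrection}}).  REV is scale-free: rescaling all
#' replicate values of a transcript leaves it unchanged.
#'
#' @param stats a \linkS4class{TranscriptStats}.
#' @param config a \code{\link{revConfig}}.
#' @return the \linkS4class{TranscriptStats} with the \code{rev} column
#'   filled (percent) and convention metadata attached.
#' @export
computeREV <- function(stats, config = revConfig()) {
    stopifnot(is(stats, "TranscriptStats"))
    tb <- stats@table
    rev <- mapply(function(mu, s, R) {
        if (any(mu == 0)) stop("zero spot mean: REV undefined")
        unname(redundancyCorrection(R, config) *
               100 * sqrt(mean((s / mu)^2)))
    }, tb$spot_means, tb$spot_sds, tb$redundancy)
    tb$rev <- as.numeric(rev)
    stats@table <- tb
    stats@metadata$rev_convention <- config$quantile_convention
    stats@metadata$rev_epsilon <- config$epsilon
    stats@metadata$rev_correction_endpoints <-
        c(R1 = redundancyCorrection(1, config),
          R28 = redundancyCorrection(28, config))
    stats@metadata$rev_note <- paste(
        "chi-square mid-interval convention:", config$quantile_convention,
        "- endpoint values depend on the convention and are reported here",
        "rather than calibrated to any external anchor")
    stats
}

#' Compare a transcript across two conditions (surrogate regulation call)
#'
#' A deliberately simple surrogate for full regulation-significance
#' machinery: the fold change is the ratio of combined means (reported as a
#' negative reciprocal when below 1), the p-value comes from a
#' heteroscedastic (Welch) two-sample t-test on the replicate-level
#' spot-averaged profiles, and a Bonferroni-style correction is applied
#' only within the transcript's redundancy group
#' (\code{corrected_p = min(1, R * p)}) --- never across distinct genes.
#'
#' @param stats a \linkS4class{TranscriptStats} covering both conditions.
#' @param transcript transcript symbol.
#' @param condition treated condition label.
#' @param reference reference condition label.
#' @param fold_threshold minimum |fold| to call regulation (default 1.5).
#' @param alpha significance level on the corrected p (default 0.05).
#' @return a one-row data.frame: \code{transcript_id}, \code{fold_change},
#'   \code{p_value}, \code{corrected_p}, \code{status} (UP/DOWN/NC),
#'   \code{method} (labelled "surrogate").
#' @export
regulationCall <- function(stats, transcript, condition, reference,
                           fold_threshold = 1.5, alpha = 0.05) {
    stopifnot(is(stats, "TranscriptStats"), fold_threshold >= 1)
    tb <- stats@table
    a <- which(tb$transcript_id == transcript & tb$condition == condition)
    b <- which(tb$transcript_id == transcript & tb$condition == reference)
    if (!length(a) || !length(b))
        stop("transcript '", transcript, "' not summarized in both",
             " conditions")
    xa <- replicateProfile(stats, condition)[transcript, ]
    xb <- replicateProfile(stats, reference)[transcript, ]
    ratio <- tb$combined_mean[a] / tb$combined_mean[b]
    fold <- if (ratio >= 1) ratio else -1 / ratio
    p <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else stats::t.test(xa, xb, var.equal = FALSE)$p.value
    R <- tb$redundancy[a]
    cp <- min(1, R * p)
    status <- if (abs(fold) >= fold_threshold && cp < alpha) {
        if (fold > 0) "UP" else "DOWN"
    } else "NC"
    data.frame(transcript_id = transcript, fold_change = fold,
               p_value = p, corrected_p = cp, status = status,
               method = "surrogate", stringsAsFactors = FALSE)
}

#' Regulation calls for every transcript of a condition pair
#'
#' @inheritParams regulationCall
#' @return a data.frame with one row per transcript.
#' @export
regulationCalls <- function(stats, condition, reference,
                            fold_threshold = 1.5, alpha = 0.05) {
    tx <- unique(stats@table$transcript_id)
    do.call(rbind, lapply(tx, regulationCall, stats = stats,
                          condition = condition, reference = reference,
                          fold_threshold = fold_threshold, alpha = alpha))
}

#' Gene-group summary: average REV and median expression
#'
#' @param stats a \linkS4class{TranscriptStats} with REV computed.
#' @param genes character vector of member transcript symbols.
#' @param condition condition to summarize.
#' @param reference optional reference condition; when given, the median
#'   expression is divided by the group median in the reference condition.
#' @return list with \code{mean_rev}, \code{median_expression},
#'   \code{n_genes}.
#' @export
groupSummary <- function(stats, genes, condition, reference = NULL) {
    stopifnot(is(stats, "TranscriptStats"))
    if (!length(genes)) stop("empty gene group")
    tb <- stats@table
    sel <- tb$transcript_id %in% genes & tb$condition == condition
    if (!any(sel)) stop("no group member summarized in '", condition, "'")
    med <- stats::median(tb$combined_mean[sel])
    if (!is.null(reference)) {
        ref <- tb$transcript_id %in% genes & tb$condition == reference
        med <- med / stats::median(tb$combined_mean[ref])
    }
    list(mean_rev = mean(tb$rev[sel]), median_expression = med,
         n_genes = sum(sel))
}

#' Welch test for equality of two REV-distribution means
#'
#' Heteroscedastic (two-sample, unequal variance) t-test, two-tailed.
#'
#' @param revs_a,revs_b numeric vectors (length >= 2 each).
#' @return the two-tailed p-value.
#' @export
compareREVDistributions <- function(revs_a, revs_b) {
    if (length(revs_a) < 2 || length(revs_b) < 2)
        stop("need at least 2 entries per group")
    if (stats::sd(revs_a) == 0 && stats::sd(revs_b) == 0)
        return(if (isTRUE(all.equal(mean(revs_a), mean(revs_b)))) 1 else 0)
    stats::t.test(revs_a, revs_b, var.equal = FALSE)$p.value
}
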