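#' Fabric-wide reference means for PWR scoring
#'
#' Arithmetic means of the combined expression level and the REV over all N
#' quantified unigenes of a condition --- the whole quantified transcriptome,
#' not just the gene subset under analysis, so that PWR scores from
#' different subsets are mutually comparable.
#'
#' @param stats a \linkS4class{TranscriptStats} with REV computed.
#' @param condition condition label.
#' @return list: \code{condition}, \code{n_unigenes},
#'   \code{mean_expression}, \code{mean_rev}.
#' @export
fabricSummary <- function(stats, condition) {
    stopifnot(is(stats, "TranscriptStats"))
    tb <- stats@table
    sel <- tb$condition == condition
    if (!any(sel)) stop("unknown condition: ", condition)
    if (anyNA(tb$rev[sel]))
        stop("REV not computed; run computeREV() first")
    structure(list(condition = condition, n_unigenes = sum(sel),
                   mean_expression = mean(tb$combined_mean[sel]),
                   mean_rev = mean(tb$rev[sel])),
              class = "fabric_summary")
}

#' Pair-wise relevance score of a gene pair
#'
#' \deqn{PWR_{ij} = \frac{\mu_i \mu_j}{\bar\mu^2} \times \rho_{ij}^2 \times
#'   \frac{\overline{REV}^2}{REV_i\, REV_j}}
#' A pair scores highly when both genes are expressed above the fabric
#' average, strongly coordinated (either sign), and under tighter-than-
#' average abundance control (low REV).  The score is symmetric in the two
#' genes and invariant under global rescaling of all expression levels or
#' of all REVs.  No significance gate is applied to rho.
#'
#' @param mu_i,mu_j combined mean expression of the two genes.
#' @param rev_i,rev_j their REVs (strictly positive).
#' @param rho_ij replicate-level Pearson coefficient (\code{NA} propagates).
#' @param fabric a \code{\link{fabricSummary}}.
#' @return list: \code{pwr} and its \code{factors} (expression,
#'   correlation, control terms).
#' @export
pwrScore <- function(mu_i, mu_j, rev_i, rev_j, rho_ij, fabric) {
    stopifnot(inherits(fabric, "fabric_summary"))
    if (any(c(rev_i, rev_j) <= 0))
        stop("zero or negative REV: control term undefined")
    if (fabric$mean_expression <= 0 || fabric$mean_rev <= 0)
        stop("fabric means must be positive")
    expr_term <- (mu_i * mu_j) / fabric$mean_expression^2
    corr_term <- rho_ij^2
    ctrl_term <- fabric$mean_rev^2 / (rev_i * rev_j)
    list(pwr = expr_term * corr_term * ctrl_term,
         factors = c(expression = expr_term, correlation = corr_term,
                     control = ctrl_term))
}

#' PWR records for a set of coordination records
#'
#' @param stats a \linkS4class{TranscriptStats} with REV computed.
#' @param records data.frame from \code{\link{coordinatePairs}}.
#' @param condition condition label (defaults to the records' condition).
#' @param fabric optional precomputed \code{\link{fabricSummary}}.
#' @return the records with \code{pwr} and factor columns appended.
#' @export
pwrRecords <- function(stats, records, condition = NULL, fabric = NULL) {
    stopifnot(is(stats, "TranscriptStats"))
    if (is.null(condition)) condition <- unique(records$condition)
    stopifnot(length(condition) == 1)
    if (is.null(fabric)) fabric <- fabricSummary(stats, condition)
    tb <- stats@table
    sel <- tb$condition == condition
    mu <- tb$combined_mean[sel]; names(mu) <- tb$transcript_id[sel]
    rv <- tb$rev[sel]; names(rv) <- tb$transcript_id[sel]
    expr_term <- (mu[records$gene_a] * mu[records$gene_b]) /
        fabric$mean_expression^2
    corr_term <- records$rho^2
    ctrl_term <- fabric$mean_rev^2 / (rv[records$gene_a] * rv[records$gene_b])
    records$pwr <- unname(expr_term * corr_term * ctrl_term)
    records$factor_expression <- unname(expr_term)
    records$factor_correlation <- unname(corr_term)
    records$factor_control <- unname(ctrl_term)
    records
}

#' Dense PWR landscape over a cross-set pair universe
#'
#' @param pwr_records output of \code{\link{pwrRecords}} on cross-set
#'   records (every A x B pair present).
#' @param set_a,set_b row and column gene orders (defaults: sorted unique
#'   symbols in the records).
#' @return numeric matrix, rows = set A, columns = set B; pairs whose PWR
#'   is undefined (undefined rho) are \code{NA}.
#' @export
pwrLandscape <- function(pwr_records, set_a = NULL, set_b = NULL) {
    if (is.null(set_a)) set_a <- sort(unique(pwr_records$gene_a))
    if (is.null(set_b)) set_b <- sort(unique(pwr_records$gene_b))
    m <- matrix(NA_real_, length(set_a), length(set_b),
                dimnames = list(set_a, set_b))
    idx <- cbind(match(pwr_records$gene_a, set_a),
                 match(pwr_records$gene_b, set_b))
    if (anyNA(idx)) stop("records reference genes outside the given sets")
    m[idx] <- pwr_records$pwr
    m
}

#' Top-k PWR pairs ("medallion" report)
#'
#' Ranks pairs by decreasing PWR; ties broken lexicographically by
#' (gene_a, gene_b), so the ranking is stable under record order.
#' Undefined scores rank last and are dropped.
#'
#' @param pwr_records output of \code{\link{pwrRecords}}.
#' @param k number of pairs to report.
#' @return the k highest-scoring rows (all rows, with a message, if fewer
#'   are available).
#' @export
topPairs <- function(pwr_records, k) {
    stopifnot(k >= 1)
    rec <- pwr_records[!is.na(pwr_records$pwr), , drop = FALSE]
    ord <- order(-rec$pwr, rec$gene_a, rec$gene_b)
    rec <- rec[ord, , drop = FALSE]
    if (k > nrow(rec)) {
        message("only ", nrow(rec), " scored pairs available (k = ", k, ")")
        k <- nrow(rec)
    }
    out <- rec[seq_len(k), , drop = FALSE]
    rownames(out) <- NULL
    out
}
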