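#' Pearson correlation across biological replicates
#'
#' Thin wrapper around the product-moment correlation with the
#' preconditions of replicate-level coordination analysis made explicit:
#' equal lengths of at least 3, and an \code{NA} result (rather than an
#' error) when either profile is constant, so that downstream records
#' surface as UNCLASSIFIED instead of being dropped.
#'
#' @param x,y numeric replicate profiles of equal length >= 3.
#' @return the Pearson coefficient, or \code{NA} if undefined.
#' @export
pearsonRho <- function(x, y) {
    if (length(x) != length(y)) stop("profiles differ in length")
    if (length(x) < 3) stop("need at least 3 paired replicates")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
}

#' Degrees of freedom for a redundancy-aware pair correlation
#'
#' With R spots probing each gene and \code{replicates} biological
#' replicates, the correlation test uses \code{replicates * R - 2} degrees
#' of freedom.  When the two genes are probed by unequal numbers of spots
#' the conservative default takes R = min(R_i, R_j); the alternative
#' \code{"allspots"} rule credits every spot pairing
#' (\code{replicates * R_i * R_j - 2}), which overstates the information
#' content and is off by default.
#'
#' @param redundancy_a,redundancy_b spot redundancies (>= 1).
#' @param replicates biological replicates (default 4).
#' @param rule \code{"min"} (default) or \code{"allspots"}.
#' @return integer degrees of freedom.
#' @export
pairDF <- function(redundancy_a, redundancy_b, replicates = 4L,
                   rule = c("min", "allspots")) {
    rule <- match.arg(rule)
    if (any(c(redundancy_a, redundancy_b) < 1))
        stop("redundancy must be >= 1")
    R <- switch(rule,
                min = pmin(redundancy_a, redundancy_b),
                allspots = redundancy_a * redundancy_b)
    as.integer(replicates * R - 2)
}

#' Minimal |rho| significant at a given level
#'
#' Inverts the two-tailed t-test of a Pearson coefficient: with
#' \eqn{t^* = t_{1-\alpha/2, df}}, the threshold is
#' \eqn{t^*/\sqrt{t^{*2} + df}}; strictly decreasing in df.
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha two-tailed level (default 0.05).
#' @return the critical |rho| in (0, 1).
#' @examples
#' round(criticalRho(2), 2)   # 0.95
#' round(criticalRho(6), 2)   # 0.71
#' @export
criticalRho <- function(df, alpha = 0.05) {
    stopifnot(all(df >= 1), alpha > 0, alpha < 1)
    tstar <- stats::qt(1 - alpha / 2, df)
    tstar / sqrt(tstar^2 + df)
}

#' Classification thresholds for pair coordination
#'
#' @param alpha significance level for POS/NEG calls (default 0.05).
#' @param independence_threshold |rho| below which a pair is called
#'   significantly independent (IND); default 0.05.
#' @param use_log2 correlate log2-transformed expression values
#'   (default TRUE).
#' @param unequal_redundancy_rule df rule for unequal redundancies; see
#'   \code{\link{pairDF}}.
#' @return a \code{classification_config} list.
#' @export
classificationConfig <- function(alpha = 0.05, independence_threshold = 0.05,
                                 use_log2 = TRUE,
                                 unequal_redundancy_rule = c("min",
                                                             "allspots")) {
    stopifnot(alpha > 0, alpha < 1,
              independence_threshold >= 0, independence_threshold < 1)
    structure(list(alpha = alpha,
                   independence_threshold = independence_threshold,
                   use_log2 = isTRUE(use_log2),
                   unequal_redundancy_rule =
                       match.arg(unequal_redundancy_rule)),
              class = "classification_config")
}

#' Classify a pair correlation
#'
#' POS if rho exceeds the critical value at \code{alpha}, NEG if it falls
#' below its negative, IND if |rho| is under the independence threshold,
#' otherwise (or when rho is undefined) UNCLASSIFIED.
#'
#' @param rho Pearson coefficient (may be \code{NA}).
#' @param df degrees of freedom.
#' @param config a \code{\link{classificationConfig}}.
#' @return one of \code{"POS"}, \code{"NEG"}, \code{"IND"},
#'   \code{"UNCLASSIFIED"}.
#' @export
classifyPair <- function(rho, df, config = classificationConfig()) {
    stopifnot(inherits(config, "classification_config"))
    if (is.na(rho)) return("UNCLASSIFIED")
    if (abs(rho) > 1 + 1e-12) stop("|rho| > 1")
    crit <- criticalRho(df, config$alpha)
    if (rho > crit) "POS"
    else if (rho < -crit) "NEG"
    else if (abs(rho) < config$independence_threshold) "IND"
    else "UNCLASSIFIED"
}

#' Count gene pairs combinatorially
#'
#' Within one set of n genes there are n(n-1)/2 unordered pairs; across two
#' disjoint sets of n and m genes there are n*m pairs.
#'
#' @param n size of the (first) set, or a character vector of symbols.
#' @param m optional size (or symbol vector) of a second, disjoint set.
#' @return exact pair count (double, exact for counts below 2^53).
#' @examples
#' countPairs(93)        # 4278
#' countPairs(93, 934)   # 86862
#' @export
countPairs <- function(n, m = NULL) {
    if (is.character(n)) n <- length(unique(n))
    if (is.character(m)) m <- length(unique(m))
    stopifnot(n >= 1)
    if (is.null(m)) n * (n - 1) / 2 else n * m
}

#' Enumerate gene pairs
#'
#' Within-set enumeration yields each unordered pair once (lexicographic
#' canonical order, no self-pairs); cross-set enumeration yields all A x B
#' pairs and requires the sets to be disjoint.
#'
#' @param set_a character vector of gene symbols.
#' @param set_b optional second set for cross-set enumeration.
#' @return a two-column character matrix (\code{gene_a}, \code{gene_b})
#'   with attribute \code{count}.
#' @export
enumeratePairs <- function(set_a, set_b = NULL) {
    set_a <- unique(as.character(set_a))
    if (!length(set_a)) stop("empty gene set")
    if (is.null(set_b)) {
        set_a <- sort(set_a)
        if (length(set_a) < 2) stop("within-set enumeration needs >= 2 genes")
        idx <- utils::combn(length(set_a), 2)
        out <- cbind(gene_a = set_a[idx[1, ]], gene_b = set_a[idx[2, ]])
    } else {
        set_b <- unique(as.character(set_b))
        if (length(intersect(set_a, set_b)))
            stop("cross-set enumeration requires disjoint sets; shared: ",
                 paste(utils::head(intersect(set_a, set_b), 5),
                       collapse = ", "))
        out <- cbind(gene_a = rep(set_a, each = length(set_b)),
                     gene_b = rep(set_b, times = length(set_a)))
    }
    attr(out, "count") <- nrow(out)
    out
}

#' Replicate-level coordination records for a gene set
#'
#' For every enumerated pair, correlates the spot-averaged replicate
#' profiles of the two genes (log2-transformed by default), attaches the
#' redundancy-aware degrees of freedom, the two-tailed t-test p-value and
#' the POS/NEG/IND/UNCLASSIFIED class.  Under the \code{"allspots"} rule
#' the correlation is instead computed on the stacked spot-by-spot pairings.
#' No multiple-testing correction is applied across distinct pairs.
#'
#' @param stats a \linkS4class{TranscriptStats}.
#' @param condition condition label.
#' @param genes gene set (default: all summarized transcripts).
#' @param genes_b optional disjoint second set for cross-set records.
#' @param config a \code{\link{classificationConfig}}.
#' @return data.frame: \code{gene_a}, \code{gene_b}, \code{condition},
#'   \code{rho}, \code{df}, \code{p_value}, \code{classification}.
#' @export
coordinatePairs <- function(stats, condition, genes = NULL, genes_b = NULL,
                            config = classificationConfig()) {
    stopifnot(is(stats, "TranscriptStats"))
    prof <- replicateProfile(stats, condition)
    if (is.null(genes)) genes <- rownames(prof)
    missing <- setdiff(c(genes, genes_b), rownames(prof))
    if (length(missing))
        stop("not summarized in '", condition, "': ",
             paste(utils::head(missing, 5), collapse = ", "))
    pairs <- enumeratePairs(genes, genes_b)
    tb <- stats@table
    red <- tb$redundancy[tb$condition == condition]
    names(red) <- tb$transcript_id[tb$condition == condition]
    sv <- stats@spotValues[[condition]]
    n <- nrow(pairs)
    rho <- numeric(n); df <- integer(n); p <- numeric(n)
    cls <- character(n)
    tf <- if (config$use_log2) function(v) log2(v) else identity
    crit_cache <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
        a <- pairs[i, 1]; b <- pairs[i, 2]
        if (config$unequal_redundancy_rule == "allspots") {
            ma <- sv[[a]]; mb <- sv[[b]]
            grid <- expand.grid(ka = seq_len(nrow(ma)),
                                kb = seq_len(nrow(mb)))
            xa <- as.vector(t(ma[grid$ka, , drop = FALSE]))
            xb <- as.vector(t(mb[grid$kb, , drop = FALSE]))
        } else {
            xa <- prof[a, ]; xb <- prof[b, ]
        }
        r <- if (stats::sd(xa) == 0 || stats::sd(xb) == 0) NA_real_
             else stats::cor(tf(xa), tf(xb))
        d <- pairDF(red[[a]], red[[b]], replicates = ncol(prof),
                    rule = config$unequal_redundancy_rule)
        rho[i] <- r
        df[i] <- d
        if (is.na(r)) {
            p[i] <- NA_real_
            cls[i] <- "UNCLASSIFIED"
        } else {
            r2 <- min(abs(r), 1 - 1e-15)
            tstat <- r2 * sqrt(d / (1 - r2^2))
            p[i] <- 2 * stats::pt(-tstat, d)
            key <- as.character(d)
            if (is.null(crit_cache[[key]]))
                crit_cache[[key]] <- criticalRho(d, config$alpha)
            crit <- crit_cache[[key]]
            cls[i] <- if (r > crit) "POS"
                      else if (r < -crit) "NEG"
                      else if (abs(r) < config$independence_threshold) "IND"
                      else "UNCLASSIFIED"
        }
    }
    data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
               condition = condition, rho = rho, df = df, p_value = p,
               classification = cls, stringsAsFactors = FALSE)
}

#' Coordination profile: POS/NEG/IND percentages of a pair universe
#'
#' @param records data.frame from \code{\link{coordinatePairs}} covering
#'   every enumerated pair of the set.
#' @return named numeric vector (percent of all pairs); the remainder to
#'   100 is the UNCLASSIFIED fraction.
#' @export
coordinationProfile <- function(records) {
    n <- nrow(records)
    if (!n) return(c(POS = 0, NEG = 0, IND = 0))
    100 * c(POS = sum(records$classification == "POS"),
            NEG = sum(records$classification == "NEG"),
            IND = sum(records$classification == "IND")) / n
}

#' Detect coordination reversals between two conditions
#'
#' A reversal is a pair classified POS in one condition and NEG in the
#' other.  The comparison is symmetric: swapping the two record sets swaps
#' the roles of \code{rho_a} and \code{rho_b} but reports the same pairs.
#'
#' @param records_a,records_b record data.frames over the same pair
#'   universe (same gene_a/gene_b keys).
#' @return data.frame: \code{gene_a}, \code{gene_b}, \code{rho_a},
#'   \code{rho_b}, \code{direction} ("POS->NEG" or "NEG->POS", read from
#'   condition A to condition B).
#' @export
detectReversals <- function(records_a, records_b) {
    key <- function(r) paste(r$gene_a, r$gene_b, sep = "\r")
    ka <- key(records_a); kb <- key(records_b)
    if (!setequal(ka, kb))
        stop("record sets cover different pair universes")
    m <- match(ka, kb)
    ca <- records_a$classification
    cb <- records_b$classification[m]
    hit <- (ca == "POS" & cb == "NEG") | (ca == "NEG" & cb == "POS")
    data.frame(gene_a = records_a$gene_a[hit],
               gene_b = records_a$gene_b[hit],
               rho_a = records_a$rho[hit],
               rho_b = records_b$rho[m][hit],
               direction = ifelse(ca[hit] == "POS", "POS->NEG", "NEG->POS"),
               stringsAsFactors = FALSE)
}
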