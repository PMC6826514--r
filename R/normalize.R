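#' Iterative intra-/inter-array median normalization
#'
#' Alternates two scaling steps until the normalized values stabilise:
#' (a) \emph{inter-array}: a cross-array consensus profile (row-wise
#' geometric mean) is formed and each array is divided by the median ratio
#' of its spots to the consensus, making each spot's cross-array estimates
#' mutually consistent; (b) \emph{intra-array}: each array (sample column)
#' is divided by the median of its valid spots, so every array's median of
#' valid spots ends each iteration at exactly 1.  Iteration stops when the error functional --- by
#' default the maximum absolute relative change of any value between
#' successive iterations --- drops below \code{tolerance}.
#'
#' The procedure is deterministic, idempotent at the fixed point, and
#' invariant under global positive rescaling of the input.
#'
#' @param x a filtered \linkS4class{SpotExperiment} with positive
#'   \code{signal} values.
#' @param tolerance convergence threshold on the error functional
#'   (default 0.05, i.e. 5\%).
#' @param max_iterations iteration cap; exceeding it is an error carrying
#'   the error trace.
#' @param error_fun error functional \code{function(old, new)} returning a
#'   scalar; default \code{max(|new - old| / old)}.
#' @return the \linkS4class{SpotExperiment} with an added
#'   \code{normalized} assay; \code{normalizationInfo(x)} reports
#'   \code{iterations}, \code{final_error} and the per-iteration
#'   \code{trace}.
#' @export
normalizeIterative <- function(x, tolerance = 0.05, max_iterations = 100L,
                               error_fun = NULL) {
    stopifnot(is(x, "SpotExperiment"), tolerance > 0, max_iterations >= 1)
    v <- assay(x, "signal")
    if (anyNA(v)) stop("ragged design: NA signal values")
    if (any(v <= 0)) stop("normalization requires strictly positive values")
    if (is.null(error_fun))
        error_fun <- function(old, new) max(abs(new - old) / old)
    trace <- numeric(0)
    for (it in seq_len(max_iterations)) {
        old <- v
        # (a) inter-array: rescale each array to the consensus profile
        consensus <- exp(rowMeans(log(v)))
        ratio_med <- apply(sweep(v, 1, consensus, "/"), 2, stats::median)
        v <- sweep(v, 2, ratio_med, "/")
        # (b) intra-array: median of each array's valid spots -> 1
        v <- sweep(v, 2, apply(v, 2, stats::median), "/")
        err <- error_fun(old, v)
        trace <- c(trace, err)
        if (err < tolerance) break
    }
    if (trace[length(trace)] >= tolerance)
        stop("normalization did not converge within ", max_iterations,
             " iterations; error trace: ",
             paste(format(trace, digits = 4), collapse = ", "))
    assays(x)$normalized <- v
    metadata(x)$normalization <- list(iterations = length(trace),
                                      final_error = trace[length(trace)],
                                      tolerance = tolerance,
                                      trace = trace)
    x
}

#' @importFrom SummarizedExperiment assays<-
NULL
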