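#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

#' SpotExperiment: spot-level microarray measurements
#'
#' A \linkS4class{SummarizedExperiment} whose rows are microarray spots and
#' whose columns are samples (one condition x replicate combination each).
#' Row metadata carries \code{spot_id}, \code{transcript_id} and the
#' \code{is_control} / \code{is_corrupted} validity flags; column metadata
#' carries \code{condition} and \code{replicate}.  Assays hold per-spot
#' \code{foreground} and \code{background} channel intensities (two-channel
#' dialects add \code{foreground2}/\code{background2}), the combined
#' \code{signal}, and, after normalization, \code{normalized}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @export
setClass("SpotExperiment", contains = "SummarizedExperiment")

.validSpotExperiment <- function(object) {
    msg <- NULL
    rd <- rowData(object)
    cd <- colData(object)
    need_rd <- c("spot_id", "transcript_id", "is_control", "is_corrupted")
    miss <- setdiff(need_rd, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    need_cd <- c("condition", "replicate")
    miss <- setdiff(need_cd, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(msg)) {
        if (anyDuplicated(rd$spot_id))
            msg <- c(msg, "spot_id values must be unique")
        if (anyDuplicated(paste(cd$condition, cd$replicate, sep = "\r")))
            msg <- c(msg, "(condition, replicate) sample keys must be unique")
        for (a in intersect(c("foreground", "background",
                              "foreground2", "background2"),
                            assayNames(object))) {
            v <- assay(object, a)
            if (any(is.finite(v) & v < 0))
                msg <- c(msg, paste0("assay '", a, "' has negative values"))
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("SpotExperiment", .validSpotExperiment)

#' TranscriptStats: per-transcript, per-condition expression summaries
#'
#' Holds, for every transcript and condition, the per-spot replicate means
#' and standard deviations, the redundancy (number of spots probing the
#' transcript), the combined mean, and -- once \code{\link{computeREV}} has
#' been applied -- the redundancy-corrected relative expression variability.
#' Replicate-level spot-averaged profiles (genes x replicates, one matrix per
#' condition) are kept for coordination analysis and regulation calls, and
#' the full spot x replicate tables per transcript for the all-spot-pairings
#' correlation rule.
#'
#' @slot table a \code{DataFrame} with columns \code{transcript_id},
#'   \code{condition}, \code{redundancy}, \code{combined_mean}, \code{rev}
#'   and list-columns \code{spot_means}, \code{spot_sds}.
#' @slot profiles named list (by condition) of numeric matrices, transcripts
#'   in rows, replicates in columns, spot-averaged expression values.
#' @slot spotValues named list (by condition) of named lists (by transcript)
#'   of spot x replicate matrices.
#' @slot metadata list of provenance notes (REV convention, epsilon, ...).
#' @export
setClass("TranscriptStats",
    representation(table = "DataFrame", profiles = "list",
                   spotValues = "list", metadata = "list"))

.validTranscriptStats <- function(object) {
    tb <- object@table
    msg <- NULL
    need <- c("transcript_id", "condition", "redundancy", "combined_mean",
              "rev", "spot_means", "spot_sds")
    miss <- setdiff(need, colnames(tb))
    if (length(miss))
        msg <- c(msg, paste0("table lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(msg) && nrow(tb)) {
        nm <- lengths(tb$spot_means)
        ns <- lengths(tb$spot_sds)
        if (!all(nm == tb$redundancy) || !all(ns == tb$redundancy))
            msg <- c(msg, "spot_means/spot_sds lengths must equal redundancy")
        ok <- !is.na(tb$rev)
        if (any(tb$rev[ok] < 0))
            msg <- c(msg, "rev must be nonnegative")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("TranscriptStats", .validTranscriptStats)

#' SimulatedDataset: seeded synthetic spot-level dataset with ground truth
#'
#' @slot raw a \linkS4class{SpotExperiment} with simulated two-channel-style
#'   intensities and validity flags.
#' @slot truth list of ground-truth tables: \code{genes} (true level and CV
#'   per gene x condition), \code{pairs} (designated pairs with true
#'   correlation sign and magnitude), \code{spots} (per-spot filter labels).
#' @slot config the \code{SimulationConfig} list used for generation.
#' @slot seed integer seed the dataset was generated from.
#' @export
setClass("SimulatedDataset",
    representation(raw = "SpotExperiment", truth = "list",
                   config = "list", seed = "integer"))

setMethod("show", "SpotExperiment", function(object) {
    cat("SpotExperiment:", nrow(object), "spots x", ncol(object), "samples\n")
    cat("  conditions:",
        paste(unique(colData(object)$condition), collapse = ", "), "\n")
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
    fr <- metadata(object)$filter_report
    if (!is.null(fr))
        cat("  filtered:", fr$n_valid, "of", fr$n_input, "spots valid\n")
    nm <- metadata(object)$normalization
    if (!is.null(nm))
        cat("  normalized in", nm$iterations, "iteration(s), final error",
            format(nm$final_error, digits = 3), "\n")
    invisible(NULL)
})

setMethod("show", "TranscriptStats", function(object) {
    tb <- object@table
    cat("TranscriptStats:", length(unique(tb$transcript_id)), "transcripts x",
        length(unique(tb$condition)), "condition(s)\n")
    if (all(is.na(tb$rev))) cat("  REV: not yet computed\n")
    else cat("  REV convention:",
             object@metadata$rev_convention %||% "unset", "\n")
    invisible(NULL)
})

setMethod("show", "SimulatedDataset", function(object) {
    cat("SimulatedDataset (seed", object@seed, "):",
        object@config$n_genes, "genes,",
        length(object@config$conditions), "conditions,",
        object@config$replicates, "replicates\n")
    cat("  designated pairs:", nrow(object@truth$pairs), "\n")
    invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
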