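#' Accessors for genofabric classes
#'
#' @param x a \linkS4class{SpotExperiment}, \linkS4class{TranscriptStats} or
#'   \linkS4class{SimulatedDataset}.
#' @param condition condition label (where applicable).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname accessors
#' @export
setMethod("filterReport", "SpotExperiment",
    function(x) metadata(x)$filter_report)

#' @rdname accessors
#' @export
setGeneric("normalizationInfo",
    function(x) standardGeneric("normalizationInfo"))

#' @rdname accessors
#' @export
setMethod("normalizationInfo", "SpotExperiment",
    function(x) metadata(x)$normalization)

#' @rdname accessors
#' @export
setGeneric("transcriptTable", function(x) standardGeneric("transcriptTable"))

#' @rdname accessors
#' @export
setMethod("transcriptTable", "TranscriptStats",
    function(x) as.data.frame(x@table[, c("transcript_id", "condition",
                                          "redundancy", "combined_mean",
                                          "rev")]))

#' @rdname accessors
#' @export
setGeneric("replicateProfile",
    function(x, condition) standardGeneric("replicateProfile"))

#' @rdname accessors
#' @export
setMethod("replicateProfile", "TranscriptStats", function(x, condition) {
    if (!condition %in% names(x@profiles))
        stop("unknown condition: ", condition)
    x@profiles[[condition]]
})

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setMethod("groundTruth", "SimulatedDataset", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("rawData", function(x) standardGeneric("rawData"))

#' @rdname accessors
#' @export
setMethod("rawData", "SimulatedDataset", function(x) x@raw)

#' @rdname accessors
#' @export
setGeneric("revMetadata", function(x) standardGeneric("revMetadata"))

#' @rdname accessors
#' @export
setMethod("revMetadata", "TranscriptStats", function(x) x@metadata)
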