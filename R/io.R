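#' Describe the layout of a spot-level expression table
#'
#' A dialect maps the columns of a tab- or comma-separated spot table onto
#' the fields the pipeline needs, and states how channel intensities combine
#' into one expression value per spot.  Two dialect types are supported:
#' \code{"two-channel"} raw intensity tables (optionally with a second
#' colour, as in GenePix-style F635/B635/F532/B532 exports) and
#' \code{"pre-normalized"} single-value tables.
#'
#' @param type \code{"two-channel"} or \code{"pre-normalized"}.
#' @param columns named character vector mapping canonical field names
#'   (\code{spot_id}, \code{transcript_id}, \code{condition},
#'   \code{replicate}, and either \code{foreground}/\code{background}
#'   [+ optional \code{foreground2}/\code{background2}] or \code{value};
#'   optional \code{is_control}, \code{is_corrupted}) to column names in the
#'   file.  Defaults assume canonical names.
#' @param channel_rule how two colours combine into one signal:
#'   \code{"single"} (background-subtracted first channel), \code{"geomean"}
#'   (geometric mean of the background-subtracted channels) or
#'   \code{"ratio"} (channel 1 over channel 2).  Ignored when only one
#'   channel is present.
#' @param floor small positive value replacing non-positive
#'   background-subtracted intensities.
#' @param sep field separator ("\\t" or ",").
#' @return a \code{spot_dialect} list.
#' @export
spotDialect <- function(type = c("two-channel", "pre-normalized"),
                        columns = character(), channel_rule = c("single",
                        "geomean", "ratio"), floor = 1e-3, sep = "\t") {
    type <- match.arg(type)
    channel_rule <- match.arg(channel_rule)
    stopifnot(is.numeric(floor), floor > 0)
    canonical <- c(spot_id = "spot_id", transcript_id = "transcript_id",
                   condition = "condition", replicate = "replicate",
                   foreground = "foreground", background = "background",
                   foreground2 = "foreground2", background2 = "background2",
                   value = "value", is_control = "is_control",
                   is_corrupted = "is_corrupted")
    canonical[names(columns)] <- columns
    structure(list(type = type, columns = canonical,
                   channel_rule = channel_rule, floor = floor, sep = sep),
              class = "spot_dialect")
}

.mandatoryFields <- function(dialect) {
    base <- c("spot_id", "transcript_id", "condition", "replicate")
    if (dialect$type == "two-channel") c(base, "foreground", "background")
    else c(base, "value")
}

#' Read a spot-level expression table
#'
#' Reads a long-format spot table (one row per spot x sample), checks the
#' schema against the declared dialect, drops rows with unparseable numeric
#' fields (reporting their line numbers), and assembles a
#' \linkS4class{SpotExperiment} with spots in rows and samples
#' (condition x replicate) in columns.  For two-channel dialects the
#' combined \code{signal} assay is derived from background-subtracted
#' foreground intensities under the dialect's \code{channel_rule}, clipped
#' below at the dialect floor.
#'
#' @param path path to a TSV/CSV file.
#' @param dialect a \code{\link{spotDialect}}.
#' @return a \linkS4class{SpotExperiment}; rows rejected as malformed are
#'   reported in \code{metadata(x)$read_report}.
#' @export
readSpotTable <- function(path, dialect = spotDialect()) {
    stopifnot(inherits(dialect, "spot_dialect"))
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                             colClasses = "character", check.names = FALSE,
                             quote = "\"", comment.char = "")
    need <- dialect$columns[.mandatoryFields(dialect)]
    miss <- setdiff(unname(need), colnames(raw))
    if (length(miss))
        stop("spot table lacks mandatory column(s): ",
             paste(miss, collapse = ", "))
    df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                     spot_id = raw[[dialect$columns["spot_id"]]],
                     transcript_id = raw[[dialect$columns["transcript_id"]]],
                     condition = raw[[dialect$columns["condition"]]])
    numfields <- if (dialect$type == "two-channel") {
        f <- c("replicate", "foreground", "background")
        if (dialect$columns["foreground2"] %in% colnames(raw))
            f <- c(f, "foreground2", "background2")
        f
    } else c("replicate", "value")
    for (f in numfields) {
        col <- dialect$columns[f]
        if (!col %in% colnames(raw)) stop("missing column: ", col)
        df[[f]] <- suppressWarnings(as.numeric(raw[[col]]))
    }
    for (f in c("is_control", "is_corrupted")) {
        col <- dialect$columns[f]
        df[[f]] <- if (col %in% colnames(raw))
            as.logical(raw[[col]]) %in% TRUE else FALSE
    }
    bad <- !stats::complete.cases(df[numfields])
    read_report <- list(n_rows = nrow(df), n_bad = sum(bad),
                        bad_lines = which(bad) + 1L)  # +1: header line
    if (any(bad)) {
        warning(sum(bad), " row(s) with unparseable numeric fields dropped",
                " (lines ", paste(read_report$bad_lines, collapse = ", "),
                ")")
        df <- df[!bad, , drop = FALSE]
    }
    .spotExperimentFromLong(df, dialect, read_report)
}

.spotExperimentFromLong <- function(df, dialect, read_report = NULL) {
    sample_key <- paste(df$condition, df$replicate, sep = ".")
    samples <- unique(data.frame(key = sample_key,
                                 condition = df$condition,
                                 replicate = df$replicate,
                                 stringsAsFactors = FALSE))
    samples <- samples[order(samples$condition, samples$replicate), ]
    spots <- unique(data.frame(spot_id = df$spot_id,
                               transcript_id = df$transcript_id,
                               stringsAsFactors = FALSE))
    if (anyDuplicated(spots$spot_id))
        stop("spot_id maps to more than one transcript_id")
    spots <- spots[order(spots$spot_id), ]
    key <- paste(df$spot_id, sample_key, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (spot_id, condition, replicate) rows")
    toMat <- function(v) {
        m <- matrix(NA_real_, nrow(spots), nrow(samples),
                    dimnames = list(spots$spot_id, samples$key))
        m[cbind(match(df$spot_id, spots$spot_id),
                match(sample_key, samples$key))] <- v
        m
    }
    floorAt <- function(x) pmax(x, dialect$floor)
    assays <- list()
    if (dialect$type == "two-channel") {
        assays$foreground <- toMat(df$foreground)
        assays$background <- toMat(df$background)
        s1 <- floorAt(assays$foreground - assays$background)
        if (!is.null(df$foreground2)) {
            assays$foreground2 <- toMat(df$foreground2)
            assays$background2 <- toMat(df$background2)
            s2 <- floorAt(assays$foreground2 - assays$background2)
            assays$signal <- switch(dialect$channel_rule,
                single = s1, geomean = sqrt(s1 * s2), ratio = s1 / s2)
        } else assays$signal <- s1
    } else {
        assays$signal <- toMat(df$value)
    }
    flag <- function(f) {
        x <- tapply(df[[f]], df$spot_id, any)
        unname(x[spots$spot_id])
    }
    rd <- DataFrame(spot_id = spots$spot_id,
                    transcript_id = spots$transcript_id,
                    is_control = flag("is_control"),
                    is_corrupted = flag("is_corrupted"))
    cd <- DataFrame(condition = samples$condition,
                    replicate = as.integer(samples$replicate),
                    row.names = samples$key)
    se <- SummarizedExperiment(assays = assays, rowData = rd, colData = cd)
    se <- methods::new("SpotExperiment", se)
    if (!is.null(read_report)) metadata(se)$read_report <- read_report
    se
}

#' Apply spot-validity filters
#'
#' Removes, globally across all samples, every spot that is (in this order
#' of attribution) a control spot, corrupted in any sample, or whose
#' foreground fluorescence is less than \code{snr_factor} times its
#' background in any sample or channel ("less than" is strict, so a spot at
#' exactly the factor is retained).  The removal is global because a spot
#' failing in any sample is considered unreliable everywhere.
#'
#' @param x a \linkS4class{SpotExperiment} with raw intensities.
#' @param snr_factor required foreground/background ratio (default 2).
#' @return the filtered \linkS4class{SpotExperiment}; the tally is stored in
#'   \code{filterReport(x)} with fields \code{n_input},
#'   \code{n_removed_control}, \code{n_removed_corrupted},
#'   \code{n_removed_low_signal}, \code{n_valid}.
#' @export
filterSpots <- function(x, snr_factor = 2) {
    stopifnot(is(x, "SpotExperiment"), snr_factor > 0)
    if (nrow(x) == 0L) stop("empty spot table")
    for (a in intersect(c("foreground", "background", "signal"),
                        assayNames(x))) {
        if (anyNA(assay(x, a)))
            stop("ragged design: some spots are missing in some samples ",
                 "(assay '", a, "' has NA entries)")
    }
    rd <- rowData(x)
    low <- rep(FALSE, nrow(x))
    if (all(c("foreground", "background") %in% assayNames(x))) {
        low <- rowSums(assay(x, "foreground") <
                       snr_factor * assay(x, "background")) > 0
        if (all(c("foreground2", "background2") %in% assayNames(x)))
            low <- low | rowSums(assay(x, "foreground2") <
                                 snr_factor * assay(x, "background2")) > 0
    }
    ctrl <- rd$is_control
    corr <- !ctrl & rd$is_corrupted
    lows <- !ctrl & !rd$is_corrupted & low
    keep <- !(ctrl | corr | lows)
    report <- list(n_input = nrow(x),
                   n_removed_control = sum(ctrl),
                   n_removed_corrupted = sum(corr),
                   n_removed_low_signal = sum(lows),
                   n_valid = sum(keep))
    out <- x[keep, ]
    metadata(out)$filter_report <- report
    out
}

#' Write the normalized matrix as a long-format TSV
#'
#' @param x a normalized \linkS4class{SpotExperiment}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNormalizedTable <- function(x, path) {
    stopifnot(is(x, "SpotExperiment"),
              "normalized" %in% assayNames(x))
    v <- assay(x, "normalized")
    cd <- colData(x)
    rd <- rowData(x)
    long <- data.frame(
        spot_id = rep(rd$spot_id, times = ncol(v)),
        transcript_id = rep(rd$transcript_id, times = ncol(v)),
        condition = rep(cd$condition, each = nrow(v)),
        replicate = rep(cd$replicate, each = nrow(v)),
        value = as.vector(v))
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a filter report as JSON
#' @param report the list returned by \code{\link{filterReport}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFilterReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
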