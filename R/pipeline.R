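#' Configure an end-to-end pipeline run
#'
#' @param input path to a spot-level TSV, or \code{NULL} to simulate.
#' @param dialect a \code{\link{spotDialect}} for \code{input}.
#' @param simulation a \code{\link{simulationConfig}} used when no input
#'   table is given.
#' @param output_dir directory for stage outputs.
#' @param genesets named list of character vectors; coordination, PWR and
#'   networks are computed within each set (and across the first two sets
#'   when they are disjoint).
#' @param reference_condition condition used as regulation reference;
#'   default: the first condition found.
#' @param snr_factor,tolerance,max_iterations filtering/normalization
#'   parameters.
#' @param rev a \code{\link{revConfig}}.
#' @param classification a \code{\link{classificationConfig}}.
#' @param seed integer seed for the simulation stage.
#' @return a \code{pipeline_config} list.
#' @export
pipelineConfig <- function(input = NULL, dialect = spotDialect(),
                           simulation = simulationConfig(),
                           output_dir = tempfile("genofabric_run_"),
                           genesets = list(),
                           reference_condition = NULL,
                           snr_factor = 2, tolerance = 0.05,
                           max_iterations = 100L,
                           rev = revConfig(),
                           classification = classificationConfig(),
                           seed = 1L) {
    if (!is.null(input) && !file.exists(input))
        stop("input table not found: ", input)
    structure(list(input = input, dialect = dialect,
                   simulation = simulation, output_dir = output_dir,
                   genesets = genesets,
                   reference_condition = reference_condition,
                   snr_factor = snr_factor, tolerance = tolerance,
                   max_iterations = as.integer(max_iterations),
                   rev = rev, classification = classification,
                   seed = as.integer(seed)),
              class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of \code{\link{pipelineConfig}} (paths, thresholds, seed,
#' gene-set file paths under \code{genesets:}, one symbol per line) are
#' read from a YAML file; nested configs accept their scalar fields under
#' \code{rev:}, \code{classification:} and \code{simulation:} keys.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    genesets <- list()
    for (nm in names(y$genesets %||% list())) {
        f <- y$genesets[[nm]]
        if (!file.exists(f)) stop("gene-set file not found: ", f)
        genesets[[nm]] <- readLines(f)
    }
    args <- list(
        input = y$input, output_dir = y$output_dir %||%
            tempfile("genofabric_run_"),
        genesets = genesets,
        reference_condition = y$reference_condition,
        snr_factor = y$snr_factor %||% 2,
        tolerance = y$tolerance %||% 0.05,
        max_iterations = y$max_iterations %||% 100L,
        seed = y$seed %||% 1L)
    if (!is.null(y$rev))
        args$rev <- do.call(revConfig, y$rev)
    if (!is.null(y$classification))
        args$classification <- do.call(classificationConfig,
                                       y$classification)
    if (!is.null(y$simulation))
        args$simulation <- do.call(simulationConfig, y$simulation)
    do.call(pipelineConfig, args)
}

.configHash <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    # drop closures, which serialize environment-dependently
    flat <- rapply(unclass(config),
                   function(x) if (is.function(x)) deparse(x) else x,
                   how = "replace")
    saveRDS(flat, f, version = 2)
    unname(tools::md5sum(f))
}

#' Run the full coordination-analysis pipeline
#'
#' Executes filter -> normalize -> summarize/REV -> coordination -> PWR ->
#' networks, writing every stage output under the configured directory
#' together with a manifest recording the configuration hash, convention
#' choices and the files produced.  Deterministic for a fixed configuration
#' and seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the in-memory stage results
#'   (\code{dataset}, \code{filtered}, \code{normalized}, \code{stats},
#'   \code{records}, \code{pwr}, \code{networks}, \code{reversals},
#'   \code{manifest}).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipeline_config"))
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character(0)
    emit <- function(name, writer) {
        p <- file.path(config$output_dir, name)
        writer(p)
        outputs[[name]] <<- p
    }
    stage <- "input"
    res <- list()
    tryCatch({
        if (is.null(config$input)) {
            stage <- "simulate"
            res$dataset <- simulateDataset(config$simulation, config$seed)
            se <- rawData(res$dataset)
            emit("truth", function(p) groundTruthReport(res$dataset, p))
        } else {
            se <- readSpotTable(config$input, config$dialect)
        }
        stage <- "filter"
        res$filtered <- filterSpots(se, config$snr_factor)
        emit("filter_report.json",
             function(p) writeFilterReport(filterReport(res$filtered), p))
        stage <- "normalize"
        res$normalized <- normalizeIterative(res$filtered, config$tolerance,
                                             config$max_iterations)
        emit("normalized.tsv",
             function(p) writeNormalizedTable(res$normalized, p))
        stage <- "rev"
        res$stats <- computeREV(summarizeTranscripts(res$normalized),
                                config$rev)
        emit("transcript_stats.tsv", function(p)
            utils::write.table(transcriptTable(res$stats), p, sep = "\t",
                               quote = FALSE, row.names = FALSE))
        conditions <- unique(colData(res$normalized)$condition)
        reference <- config$reference_condition %||% conditions[1]
        if (length(conditions) > 1) {
            stage <- "regulation"
            res$regulation <- list()
            for (cond in setdiff(conditions, reference)) {
                res$regulation[[cond]] <-
                    regulationCalls(res$stats, cond, reference)
            }
            emit("regulation.tsv", function(p) {
                all <- do.call(rbind, lapply(names(res$regulation),
                    function(cn) cbind(condition = cn,
                                       res$regulation[[cn]])))
                utils::write.table(all, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
            })
        }
        genesets <- config$genesets
        if (!length(genesets))
            genesets <- list(all = unique(res$stats@table$transcript_id))
        stage <- "coordinate"
        res$records <- list(); res$networks <- list(); res$pwr <- list()
        for (cond in conditions) {
            avail <- rownames(replicateProfile(res$stats, cond))
            for (gn in names(genesets)) {
                gs <- intersect(genesets[[gn]], avail)
                if (length(gs) < 2) next
                key <- paste(gn, cond, sep = "|")
                rec <- coordinatePairs(res$stats, cond, gs,
                                       config = config$classification)
                res$records[[key]] <- rec
                emit(paste0("records_", gn, "_", make.names(cond), ".tsv"),
                     function(p) utils::write.table(rec, p, sep = "\t",
                         quote = FALSE, row.names = FALSE))
                stage <- "pwr"
                res$pwr[[key]] <- pwrRecords(res$stats, rec, cond)
                stage <- "network"
                reg <- res$regulation[[cond]]
                g <- buildNetwork(rec, gs, cond, regulation = reg)
                res$networks[[key]] <- g
                emit(paste0("network_", gn, "_", make.names(cond),
                            ".graphml"),
                     function(p) exportGraph(g, p, "graphml"))
                stage <- "coordinate"
            }
        }
        stage <- "reversals"
        res$reversals <- list()
        for (gn in names(genesets)) {
            keys <- paste(gn, conditions, sep = "|")
            keys <- keys[keys %in% names(res$records)]
            if (length(keys) < 2) next
            for (i in seq_len(length(keys) - 1)) {
                for (j in seq(i + 1, length(keys))) {
                    rv <- detectReversals(res$records[[keys[i]]],
                                          res$records[[keys[j]]])
                    nm <- paste(keys[i], keys[j], sep = " vs ")
                    res$reversals[[nm]] <- rv
                }
            }
        }
        emit("reversals.tsv", function(p) {
            all <- do.call(rbind, lapply(names(res$reversals), function(nm) {
                rv <- res$reversals[[nm]]
                if (nrow(rv)) cbind(comparison = nm, rv) else NULL
            }))
            if (is.null(all))
                all <- data.frame(comparison = character(),
                                  gene_a = character(),
                                  gene_b = character())
            utils::write.table(all, p, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        })
    }, error = function(e) {
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), "\npartial outputs under ",
             config$output_dir, call. = FALSE)
    })
    manifest <- list(
        package_version = as.character(utils::packageVersion("genofabric")),
        config_hash = .configHash(config),
        seed = config$seed,
        rev_convention = config$rev$quantile_convention,
        classification = unclass(config$classification),
        outputs = as.list(outputs))
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
    invisible(res)
}
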