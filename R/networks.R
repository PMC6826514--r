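#' Build a signed coordination graph
#'
#' Nodes are the gene set (isolated genes included); an edge joins two
#' genes when their coordination record is classified POS or NEG ---
#' independent and unclassified pairs leave no edge.  Each edge carries the
#' correlation sign and rho; each node carries its regulation status
#' (UP/DOWN/NC, defaulting to NC when no call is supplied).
#'
#' @param records classified records from \code{\link{coordinatePairs}}.
#' @param geneset character vector of node symbols.
#' @param condition condition label stored as a graph attribute.
#' @param regulation optional data.frame from \code{\link{regulationCalls}}
#'   (\code{transcript_id}, \code{status}).
#' @return an \code{igraph} graph with vertex attribute \code{status} and
#'   edge attributes \code{sign} ("+"/"-") and \code{rho}.
#' @export
buildNetwork <- function(records, geneset, condition = NULL,
                         regulation = NULL) {
    if (!length(geneset)) stop("empty gene set")
    geneset <- unique(as.character(geneset))
    outside <- !(records$gene_a %in% geneset & records$gene_b %in% geneset)
    if (any(outside)) {
        warning(sum(outside), " record(s) reference genes outside the set;",
                " skipped")
        records <- records[!outside, , drop = FALSE]
    }
    sig <- records$classification %in% c("POS", "NEG")
    ed <- records[sig, , drop = FALSE]
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(geneset), name = geneset)
    status <- rep("NC", length(geneset))
    if (!is.null(regulation)) {
        m <- match(geneset, regulation$transcript_id)
        status[!is.na(m)] <- regulation$status[m[!is.na(m)]]
    }
    igraph::V(g)$status <- status
    if (nrow(ed)) {
        g <- igraph::add_edges(g, rbind(ed$gene_a, ed$gene_b))
        igraph::E(g)$sign <- ifelse(ed$classification == "POS", "+", "-")
        igraph::E(g)$rho <- ed$rho
    }
    if (!is.null(condition)) g$condition <- condition
    g
}

.edgeTable <- function(g) {
    if (igraph::ecount(g) == 0)
        return(data.frame(gene_a = character(), gene_b = character(),
                          sign = character(), rho = numeric(),
                          stringsAsFactors = FALSE))
    el <- igraph::as_edgelist(g)
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    data.frame(gene_a = a, gene_b = b, sign = igraph::E(g)$sign,
               rho = igraph::E(g)$rho, stringsAsFactors = FALSE)
}

#' Compare two coordination graphs over the same node universe
#'
#' Partitions the pairs into edges gained in B, lost from A, sign-reversed
#' (present in both with opposite signs) and unchanged (present in both
#' with the same sign).
#'
#' @param graph_a,graph_b graphs from \code{\link{buildNetwork}} over the
#'   same vertex set.
#' @return list of data.frames \code{gained}, \code{lost},
#'   \code{reversed}, \code{unchanged}, plus a \code{counts} vector.
#' @export
diffNetworks <- function(graph_a, graph_b) {
    va <- sort(igraph::V(graph_a)$name)
    vb <- sort(igraph::V(graph_b)$name)
    if (!identical(va, vb)) stop("node universes differ")
    ea <- .edgeTable(graph_a); eb <- .edgeTable(graph_b)
    ka <- paste(ea$gene_a, ea$gene_b, sep = "\r")
    kb <- paste(eb$gene_a, eb$gene_b, sep = "\r")
    lost <- ea[!(ka %in% kb), , drop = FALSE]
    gained <- eb[!(kb %in% ka), , drop = FALSE]
    common <- intersect(ka, kb)
    ia <- match(common, ka); ib <- match(common, kb)
    flipped <- ea$sign[ia] != eb$sign[ib]
    reversed <- data.frame(gene_a = ea$gene_a[ia][flipped],
                           gene_b = ea$gene_b[ia][flipped],
                           sign_a = ea$sign[ia][flipped],
                           sign_b = eb$sign[ib][flipped],
                           rho_a = ea$rho[ia][flipped],
                           rho_b = eb$rho[ib][flipped],
                           stringsAsFactors = FALSE)
    unchanged <- ea[ia[!flipped], , drop = FALSE]
    rownames(lost) <- rownames(gained) <- rownames(unchanged) <- NULL
    list(gained = gained, lost = lost, reversed = reversed,
         unchanged = unchanged,
         counts = c(gained = nrow(gained), lost = nrow(lost),
                    reversed = nrow(reversed), unchanged = nrow(unchanged)))
}

#' Export a coordination graph
#'
#' GraphML export is round-trip safe: \code{\link{importGraph}} restores
#' node status, edge sign and rho.
#'
#' @param graph an igraph coordination graph.
#' @param path output path.
#' @param format \code{"graphml"}, \code{"tsv"} (edge list) or
#'   \code{"dot"}.
#' @return the path, invisibly.
#' @export
exportGraph <- function(graph, path, format = c("graphml", "tsv", "dot")) {
    format <- match.arg(format)
    if (format == "tsv") {
        utils::write.table(.edgeTable(graph), path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    } else {
        igraph::write_graph(graph, path, format = format)
    }
    invisible(path)
}

#' Read back a GraphML coordination graph
#' @param path a GraphML file written by \code{\link{exportGraph}}.
#' @return an igraph graph.
#' @export
importGraph <- function(path) {
    igraph::read_graph(path, format = "graphml")
}
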