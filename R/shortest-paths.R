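## Workflow 3: all co-optimal shortest paths per network between one
## source/target pair, assembled into a cross-network path matrix with order
## numbers and the preferred-intermediate-node tally. Enumeration uses
## igraph's all-shortest-paths (BFS / Dijkstra predecessor reconstruction);
## plain single-path Dijkstra would miss co-optimal alternatives.

.pathRecord <- function(label, nodes, weighted, g = NULL) {
    len <- if (weighted && !is.null(g)) {
        eids <- igraph::get_edge_ids(g, rbind(utils::head(nodes, -1),
                                              nodes[-1]))
        sum(igraph::E(g)$weight[eids])
    } else length(nodes) - 1L
    list(network = label, nodes = nodes, length = len,
         orderNumbers = setNames(seq_along(nodes) - 1L, nodes))
}

#' All shortest paths between two nodes in one network
#'
#' Enumerates every minimum-length path from \code{source} to \code{target}
#' (multiple co-optimal paths commonly exist), ordered lexicographically by
#' node sequence. By default paths minimise hop count; in weighted mode the
#' stored edge weights are used as positive costs (Dijkstra).
#'
#' @param network a \linkS4class{Network}.
#' @param source,target distinct node identifiers present in the network.
#' @param weighted use edge weights as costs (all weights must be positive;
#'   unweighted edges count 1).
#' @return list of path records, each a list with \code{network},
#'   \code{nodes} (source ... target), \code{length} (hops, or total cost in
#'   weighted mode) and \code{orderNumbers} (source = 0). Empty list, with a
#'   message, when source and target are in different components.
#' @examples
#' cyc <- Network(data.frame(from = c("A", "B", "C", "D"),
#'                           to   = c("B", "C", "D", "A")))
#' length(allShortestPaths(cyc, "A", "C"))  # two co-optimal paths
#' @export
allShortestPaths <- function(network, source, target, weighted = FALSE) {
    if (source == target)
        stop("source and target must differ")
    missing <- setdiff(c(source, target), networkNodes(network))
    if (length(missing))
        stop("unknown node(s) in network '", networkLabel(network), "': ",
             paste(missing, collapse = ", "))
    if (weighted) {
        w <- networkEdges(network)$weight
        if (any(!is.na(w) & w <= 0))
            stop("weighted shortest paths require positive edge weights")
    }
    g <- asIgraph(network, weighted = weighted)
    res <- suppressWarnings(igraph::all_shortest_paths(
        g, from = source, to = target,
        weights = if (weighted) igraph::E(g)$weight else NA))
    if (!length(res$vpaths)) {
        message(sprintf("no path between '%s' and '%s' in network '%s'",
                        source, target, networkLabel(network)))
        return(list())
    }
    paths <- lapply(res$vpaths, function(p) names(p))
    paths <- paths[.cOrder(vapply(paths, paste, character(1), collapse = "\r"))]
    lapply(paths, .pathRecord, label = networkLabel(network),
           weighted = weighted, g = g)
}

#' Cross-network shortest-path matrix
#'
#' Runs \code{\link{allShortestPaths}} for one source/target pair in every
#' selected network that contains both nodes, and tallies the preferred
#' intermediate nodes: for each node (source and target excluded, since they
#' trivially lie on every path), the number of selected networks in whose
#' shortest paths it appears -- counted once per network however many of
#' that network's co-optimal paths contain it.
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @param source,target node identifiers; each must be present in at least
#'   one selected network, and the pair must co-occur in at least one.
#' @param selected labels to analyse (default: all).
#' @param weighted use edge weights as costs.
#' @return a \linkS4class{PathMatrix}.
#' @export
pathMatrix <- function(collection, source, target, selected = NULL,
                       weighted = FALSE) {
    selected <- .resolveSelection(collection, selected, min = 1L)
    haveBoth <- vapply(selected, function(lab)
        all(c(source, target) %in% networkNodes(getNetwork(collection, lab))),
        logical(1))
    if (!any(haveBoth))
        stop(sprintf(
            "pair (%s, %s) is not present together in any selected network",
            source, target))
    records <- list()
    perNetworkNodes <- list()
    for (lab in selected[haveBoth]) {
        recs <- allShortestPaths(getNetwork(collection, lab), source, target,
                                 weighted = weighted)
        records <- c(records, recs)
        if (length(recs))
            perNetworkNodes[[lab]] <-
                setdiff(unique(unlist(lapply(recs, `[[`, "nodes"))),
                        c(source, target))
    }
    tally <- table(unlist(perNetworkNodes, use.names = FALSE))
    preferred <- sort(setNames(as.numeric(tally), names(tally)),
                      decreasing = TRUE)
    new("PathMatrix", source = source, target = target,
        weighted = weighted, records = records, preferred = preferred)
}

setMethod("show", "PathMatrix", function(object) {
    nets <- unique(vapply(object@records, `[[`, character(1), "network"))
    cat(sprintf("PathMatrix %s -> %s (%s): %d path(s) across %d network(s)\n",
                object@source, object@target,
                if (object@weighted) "weighted" else "hops",
                length(object@records), length(nets)))
    if (length(object@preferred))
        cat("  preferred intermediates:",
            paste(sprintf("%s (%d)", names(object@preferred),
                          object@preferred), collapse = ", "), "\n")
})

#' Export a PathMatrix
#'
#' JSON shape: \code{{source, target, records: [{network, path, length}],
#' preferred: [{node, count}]}}. The TSV table has one row per path.
#'
#' @param pm a \linkS4class{PathMatrix}.
#' @param path output file; JSON writer returns the string when \code{NULL}.
#' @return JSON string or \code{path}, invisibly.
#' @export
pathMatrixToJSON <- function(pm, path = NULL) {
    recs <- lapply(pm@records, function(r)
        list(network = r$network, path = r$nodes, length = r$length))
    pref <- lapply(names(pm@preferred), function(nd)
        list(node = nd, count = pm@preferred[[nd]]))
    js <- jsonlite::toJSON(list(source = pm@source, target = pm@target,
                                weighted = pm@weighted,
                                records = recs, preferred = pref),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}

#' @rdname pathMatrixToJSON
#' @export
writePathTable <- function(pm, path) {
    rows <- data.frame(
        network = vapply(pm@records, `[[`, character(1), "network"),
        length = vapply(pm@records, function(r) as.numeric(r$length),
                        numeric(1)),
        path = vapply(pm@records, function(r) paste(r$nodes, collapse = ","),
                      character(1)),
        stringsAsFactors = FALSE)
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
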