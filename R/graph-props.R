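## Global preview properties and per-node centralities, plus the
## cross-network "delta centrality" table. igraph provides the standard
## algorithms; eigenvector/HITS use a deterministic shifted power iteration
## so results are reproducible and hub == authority on undirected input.

.CENTRALITY_MEASURES <- c("degree", "betweenness", "hub", "authority",
                          "eccentricity", "eigenvector", "closeness",
                          "coreness")

#' Global network properties
#'
#' The four preview statistics shown for every uploaded network: total
#' nodes, total edges, cluster coefficient and density. The cluster
#' coefficient is the average \emph{local} clustering coefficient, with
#' nodes of degree < 2 contributing 0 to the mean; density is
#' \code{2E / (N (N - 1))} for N >= 2 and 0 otherwise.
#'
#' @param network a \linkS4class{Network}.
#' @return named list with \code{totalNodes}, \code{totalEdges},
#'   \code{clusterCoefficient}, \code{density}.
#' @seealso \code{\link{globalTransitivity}} for the global (triangle-ratio)
#'   clustering variant, \code{\link{collectionProperties}}.
#' @examples
#' tri <- Network(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
#' globalProperties(tri)  # 3 nodes, 3 edges, cc = 1, density = 1
#' @export
globalProperties <- function(network) {
    n <- numNodes(network)
    e <- numEdges(network)
    if (n == 0L)
        return(list(totalNodes = 0L, totalEdges = 0L,
                    clusterCoefficient = 0, density = 0))
    g <- asIgraph(network)
    cc <- if (e == 0L) 0 else
        mean(igraph::transitivity(g, type = "local", isolates = "zero"))
    dens <- if (n >= 2L) 2 * e / (n * (n - 1)) else 0
    list(totalNodes = n, totalEdges = e,
         clusterCoefficient = cc, density = dens)
}

#' Global transitivity (triangle ratio)
#'
#' The alternative global clustering statistic: 3 x triangles / connected
#' triples. Exposed separately from the average-local
#' \code{clusterCoefficient} reported by \code{\link{globalProperties}}.
#'
#' @param network a \linkS4class{Network}.
#' @return a single numeric value (0 for graphs without connected triples).
#' @export
globalTransitivity <- function(network) {
    if (numEdges(network) == 0L) return(0)
    t <- igraph::transitivity(asIgraph(network), type = "global")
    if (is.nan(t)) 0 else t
}

#' Property preview table for a collection
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @return data.frame with one row per network: label, totalNodes,
#'   totalEdges, clusterCoefficient, density.
#' @export
collectionProperties <- function(collection) {
    rows <- lapply(collection@networks, function(nw)
        data.frame(label = networkLabel(nw), globalProperties(nw),
                   stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

## Deterministic power iteration for the principal eigenvector of A,
## implemented on A + I (same eigenvector, guaranteed convergence on
## bipartite graphs where iteration on A alone oscillates). Uniform start,
## L2 normalisation, sup-norm convergence test; result scaled to unit max.
.principalEigenvector <- function(g, tol = 1e-8, maxIter = 1000L) {
    A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    n <- nrow(A)
    x <- rep(1 / sqrt(n), n)
    for (it in seq_len(maxIter)) {
        y <- as.numeric(A %*% x) + x
        y <- y / sqrt(sum(y^2))
        if (max(abs(y - x)) < tol) {
            y <- y / max(y)
            names(y) <- rownames(A)
            return(y)
        }
        x <- y
    }
    stop(sprintf(
        "eigenvector power iteration did not converge below tolerance %g in %d iterations",
        tol, maxIter))
}

#' Per-node centrality measures
#'
#' Computes any subset of the supported local properties: \code{degree},
#' \code{betweenness} (raw unordered-pair counts; set \code{normalized} for
#' the 2/((n-1)(n-2)) scaling), \code{hub} and \code{authority} (HITS; equal
#' on undirected graphs, both reported, unit-maximum scaled),
#' \code{eccentricity} (computed within each node's connected component),
#' \code{eigenvector} (deterministic power iteration, tolerance 1e-8, at most
#' 1000 iterations, unit-maximum scaled), \code{closeness} (within-component)
#' and \code{coreness}.
#'
#' @param network a \linkS4class{Network}.
#' @param measures character vector of measure names (default: all).
#' @param normalized use normalized betweenness instead of raw pair counts.
#' @return data.frame with a \code{node} column (sorted identifiers) and one
#'   numeric column per requested measure.
#' @examples
#' path <- Network(data.frame(from = c("A", "B"), to = c("B", "C")))
#' nodeCentralities(path, c("degree", "betweenness"))
#' @export
nodeCentralities <- function(network, measures = .CENTRALITY_MEASURES,
                             normalized = FALSE) {
    measures <- match.arg(measures, .CENTRALITY_MEASURES, several.ok = TRUE)
    g <- asIgraph(network)
    nodes <- networkNodes(network)
    needsEdge <- intersect(measures, c("hub", "authority", "eigenvector"))
    if (length(needsEdge) && numEdges(network) == 0L)
        stop(paste(needsEdge, collapse = "/"),
             " centrality requires a network with at least one edge")
    eig <- NULL
    getEig <- function() {
        if (is.null(eig)) eig <<- .principalEigenvector(g)
        eig
    }
    out <- data.frame(node = nodes, stringsAsFactors = FALSE)
    for (m in measures) {
        v <- switch(m,
            degree = igraph::degree(g),
            betweenness = igraph::betweenness(g, directed = FALSE,
                                              normalized = normalized),
            hub = getEig(),
            authority = getEig(),
            eigenvector = getEig(),
            eccentricity = igraph::eccentricity(g),
            closeness = suppressWarnings(igraph::closeness(g)),
            coreness = igraph::coreness(g))
        out[[m]] <- as.numeric(v[nodes])
    }
    out
}

#' Trace one centrality measure across networks ("delta centrality")
#'
#' Builds the measure-across-networks table behind parallel-coordinate
#' views: one row per node, one column per network, \code{NA} (the ABSENT
#' marker) where a node does not exist in a network. Rows are ordered by
#' descending value in the first selected network (absent last, ties by node
#' name).
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @param measure one centrality measure name (see
#'   \code{\link{nodeCentralities}}).
#' @param nodes optional node filter; every requested node must occur in at
#'   least one selected network.
#' @param selected network labels to include (default: all).
#' @param top optional integer: keep only the first \code{top} rows after
#'   ordering (e.g. the 10 highest-degree nodes of the first network).
#' @return data.frame: \code{node} plus one numeric column per network label.
#' @examples
#' n1 <- parseEdgeList(c("A\tB", "A\tC", "A\tD"), label = "t0")
#' n2 <- parseEdgeList(c("A\tB", "B\tC"), label = "t1")
#' deltaCentrality(loadCollection(list(n1, n2)), "degree")
#' @export
deltaCentrality <- function(collection, measure, nodes = NULL,
                            selected = NULL, top = NULL) {
    measure <- match.arg(measure, .CENTRALITY_MEASURES)
    selected <- .resolveSelection(collection, selected)
    tabs <- lapply(selected, function(lab)
        nodeCentralities(getNetwork(collection, lab), measure))
    allNodes <- .cSort(unique(unlist(lapply(tabs, `[[`, "node"))))
    if (!is.null(nodes)) {
        unknown <- setdiff(nodes, allNodes)
        if (length(unknown))
            stop("node(s) present in no selected network: ",
                 paste(unknown, collapse = ", "))
        allNodes <- allNodes[allNodes %in% nodes]
    }
    out <- data.frame(node = allNodes, stringsAsFactors = FALSE)
    for (i in seq_along(selected)) {
        v <- setNames(tabs[[i]][[measure]], tabs[[i]]$node)
        out[[selected[i]]] <- as.numeric(v[allNodes])
    }
    first <- out[[selected[1]]]
    out <- out[order(-xtfrm(first), out$node, method = "radix",
                     na.last = TRUE), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(top)) out <- utils::head(out, top)
    out
}

#' Export a centrality table as TSV
#'
#' Writes either layout produced by \code{\link{deltaCentrality}} (one
#' measure across networks) or \code{\link{nodeCentralities}} (all measures,
#' one network). Absent nodes (\code{NA}) are written as \code{ABSENT} to
#' distinguish them from genuine zero values.
#'
#' @param table data.frame from \code{\link{deltaCentrality}} or
#'   \code{\link{nodeCentralities}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCentralityTable <- function(table, path) {
    out <- table
    for (j in seq_along(out))
        if (is.numeric(out[[j]])) {
            x <- format(out[[j]])
            x[is.na(out[[j]])] <- "ABSENT"
            out[[j]] <- x
        }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
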