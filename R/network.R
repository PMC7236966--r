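#' Construct a Network from an edge table
#'
#' Low-level constructor: canonicalizes (orients and sorts) the undirected
#' edges, collapses duplicates (last occurrence wins on conflicting weights,
#' with a warning) and takes the node set as the union of the endpoints plus
#' any extra isolated nodes supplied.
#'
#' @param edges data.frame (or NULL for an edgeless network) with at least
#'   columns \code{from} and \code{to}; an optional \code{weight} column is
#'   retained.
#' @param nodes optional character vector of additional node identifiers
#'   (isolated nodes); endpoints are always included.
#' @param label network label (single string).
#' @param color display colour; \code{NA} defers to the collection palette.
#' @param allowSelfLoops keep self-loop edges instead of dropping them with a
#'   warning.
#' @return a \linkS4class{Network}.
#' @examples
#' net <- Network(data.frame(from = c("B", "A"), to = c("A", "C")), label = "n1")
#' numEdges(net)
#' @export
Network <- function(edges = NULL, nodes = NULL, label = "network",
                    color = NA_character_, allowSelfLoops = FALSE) {
    if (is.null(edges) || nrow(edges) == 0L) {
        ed <- data.frame(from = character(0), to = character(0),
                         weight = numeric(0), stringsAsFactors = FALSE)
    } else {
        stopifnot(all(c("from", "to") %in% names(edges)))
        ed <- .canonicalEdges(as.character(edges$from), as.character(edges$to),
                              if ("weight" %in% names(edges)) edges$weight else NULL,
                              allowSelfLoops = allowSelfLoops)
    }
    allNodes <- .cSort(unique(c(ed$from, ed$to, as.character(nodes))))
    new("Network", label = as.character(label), color = as.character(color),
        nodes = allNodes, edges = ed)
}

#' Accessors for Network objects
#'
#' @param x a \linkS4class{Network}.
#' @return \code{networkLabel}/\code{networkColor}: single string;
#'   \code{networkNodes}: sorted character vector; \code{networkEdges}:
#'   canonical edge data.frame; \code{numNodes}/\code{numEdges}: integer
#'   counts; \code{edgeKeys}: canonical \code{"u--v"} identity strings.
#' @name Network-accessors
#' @aliases networkLabel networkColor networkNodes networkEdges numNodes
#'   numEdges edgeKeys
NULL

#' @rdname Network-accessors
setMethod("networkLabel", "Network", function(x) x@label)
#' @rdname Network-accessors
setMethod("networkColor", "Network", function(x) x@color)
#' @rdname Network-accessors
setMethod("networkNodes", "Network", function(x) x@nodes)
#' @rdname Network-accessors
setMethod("networkEdges", "Network", function(x) x@edges)
#' @rdname Network-accessors
setMethod("numNodes", "Network", function(x) length(x@nodes))
#' @rdname Network-accessors
setMethod("numEdges", "Network", function(x) nrow(x@edges))
#' @rdname Network-accessors
setMethod("edgeKeys", "Network", function(x) {
    if (nrow(x@edges) == 0L) return(character(0))
    paste0(x@edges$from, "--", x@edges$to)
})

#' @rdname asIgraph
setMethod("asIgraph", "Network", function(x, weighted = FALSE) {
    ed <- x@edges
    g <- igraph::graph_from_data_frame(ed[, c("from", "to")], directed = FALSE,
                                       vertices = x@nodes)
    if (weighted)
        igraph::E(g)$weight <- ifelse(is.na(ed$weight), 1, ed$weight)
    g
})

setMethod("show", "Network", function(object) {
    cat(sprintf("Network '%s': %d nodes, %d edges%s%s\n",
                object@label, numNodes(object), numEdges(object),
                if (any(!is.na(object@edges$weight))) ", weighted" else "",
                if (!is.na(object@color)) paste0(" [", object@color, "]") else ""))
})

#' Accessors for NetworkCollection objects
#'
#' @param x a \linkS4class{NetworkCollection}.
#' @param label a member network's label.
#' @return \code{networkLabels}: character vector in collection order;
#'   \code{getNetwork}: the \linkS4class{Network} with that label.
#' @name NetworkCollection-accessors
#' @aliases networkLabels getNetwork
NULL

#' @rdname NetworkCollection-accessors
setMethod("networkLabels", "NetworkCollection", function(x)
    vapply(x@networks, networkLabel, character(1)))

#' @rdname NetworkCollection-accessors
setMethod("getNetwork", "NetworkCollection", function(x, label) {
    i <- match(label, networkLabels(x))
    if (is.na(i))
        stop("unknown network label: ", label)
    x@networks[[i]]
})

#' @export
setMethod("length", "NetworkCollection", function(x) length(x@networks))

#' @export
setMethod("[[", "NetworkCollection", function(x, i) {
    if (is.character(i)) getNetwork(x, i) else x@networks[[i]]
})

setMethod("show", "NetworkCollection", function(object) {
    cat(sprintf("NetworkCollection of %d networks (capacity %d)\n",
                length(object@networks), object@maxNetworks))
    for (nw in object@networks)
        cat("  -", format(networkLabel(nw), width = 12),
            sprintf("%5d nodes %6d edges\n", numNodes(nw), numEdges(nw)))
})

## Resolve a 'selected' argument (NULL = all labels) against a collection.
.resolveSelection <- function(collection, selected, min = 2L) {
    labs <- networkLabels(collection)
    if (is.null(selected)) selected <- labs
    unknown <- setdiff(selected, labs)
    if (length(unknown))
        stop("unknown network label(s): ", paste(unknown, collapse = ", "))
    selected <- labs[labs %in% selected]  # collection order
    if (length(selected) < min)
        stop(sprintf("at least %d selected networks required", min))
    selected
}
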