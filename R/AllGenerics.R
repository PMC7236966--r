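#' @rdname Network-accessors
#' @export
setGeneric("networkLabel", function(x) standardGeneric("networkLabel"))

#' @rdname Network-accessors
#' @export
setGeneric("networkColor", function(x) standardGeneric("networkColor"))

#' @rdname Network-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname Network-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname Network-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname Network-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname Network-accessors
#' @export
setGeneric("edgeKeys", function(x) standardGeneric("edgeKeys"))

#' Convert a NetCompare object to an igraph graph
#'
#' @param x a \linkS4class{Network}.
#' @param weighted logical; attach the stored weights as the igraph
#'   \code{weight} edge attribute (edges with \code{NA} weight get 1).
#' @return an undirected \code{igraph} graph whose vertex order is the
#'   (sorted) node set, so downstream algorithms are input-order invariant.
#' @export
setGeneric("asIgraph", function(x, weighted = FALSE) standardGeneric("asIgraph"))

#' @rdname NetworkCollection-accessors
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' @rdname NetworkCollection-accessors
#' @export
setGeneric("getNetwork", function(x, label) standardGeneric("getNetwork"))

#' @rdname Partition-accessors
#' @export
setGeneric("communities", function(x) standardGeneric("communities"))

#' @rdname Partition-accessors
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' @rdname RegionMap-accessors
#' @export
setGeneric("regionMembers", function(x, subset) standardGeneric("regionMembers"))
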