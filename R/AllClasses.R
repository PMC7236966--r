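## Central S4 containers. Edges are stored canonically: endpoints of every
## undirected edge are ordered C-locale-lexicographically (from <= to) and the
## edge table is sorted, so two Networks with equal node/edge sets are
## slot-identical regardless of input order.

#' Network: a labelled undirected graph over a shared node namespace
#'
#' A single association network: a set of node identifiers (gene / taxon /
#' protein names, compared case-sensitively) and a canonicalized set of
#' undirected edges with optional unitless association weights. Display
#' metadata (label, colour) travels with the graph so that comparison
#' outputs can be attributed to their parent network.
#'
#' @slot label single character, unique within a collection.
#' @slot color single character (hex or colour name) used to tag this
#'   network's contributions in comparison outputs.
#' @slot nodes character vector of node identifiers, sorted, no duplicates.
#' @slot edges data.frame with columns \code{from}, \code{to} (character,
#'   \code{from <= to} in C-locale order) and \code{weight} (numeric,
#'   \code{NA} when the input carried no weight column).
#'
#' @seealso \code{\link{parseEdgeList}}, \code{\link{loadCollection}}
#' @exportClass Network
setClass("Network",
    representation(
        label = "character",
        color = "character",
        nodes = "character",
        edges = "data.frame"
    ),
    prototype(
        label = NA_character_,
        color = NA_character_,
        nodes = character(0),
        edges = data.frame(from = character(0), to = character(0),
                           weight = numeric(0), stringsAsFactors = FALSE)
    )
)

setValidity("Network", function(object) {
    msg <- character(0)
    if (length(object@label) != 1L)
        msg <- c(msg, "'label' must be a single string")
    ed <- object@edges
    if (!all(c("from", "to", "weight") %in% names(ed)))
        msg <- c(msg, "'edges' must have columns from, to, weight")
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicate node identifiers")
    if (nrow(ed) > 0L) {
        if (!all(ed$from %in% object@nodes) || !all(ed$to %in% object@nodes))
            msg <- c(msg, "edge endpoint not present in node set")
        key <- edgeKey(ed$from, ed$to)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate canonical edges")
        if (any(.cLess(ed$to, ed$from)))
            msg <- c(msg, "edges must be stored canonically (from <= to)")
    }
    if (length(msg)) msg else TRUE
})

#' NetworkCollection: an ordered set of comparable networks
#'
#' The unit of every multi-network comparison: an ordered list of
#' \linkS4class{Network} objects sharing a node namespace. Comparison
#' operations require between 2 and \code{maxNetworks} (default 8) member
#' networks with unique labels.
#'
#' @slot networks list of \linkS4class{Network}.
#' @slot maxNetworks integer capacity bound (default 8).
#'
#' @seealso \code{\link{loadCollection}}
#' @exportClass NetworkCollection
setClass("NetworkCollection",
    representation(networks = "list", maxNetworks = "integer"),
    prototype(networks = list(), maxNetworks = 8L)
)

setValidity("NetworkCollection", function(object) {
    msg <- character(0)
    if (!all(vapply(object@networks, is, logical(1), class2 = "Network")))
        msg <- c(msg, "all members must be Network objects")
    labs <- vapply(object@networks, function(x) x@label, character(1))
    if (anyDuplicated(labs))
        msg <- c(msg, sprintf("duplicate network labels: %s; relabel before loading",
                              paste(unique(labs[duplicated(labs)]), collapse = ", ")))
    if (length(object@networks) > object@maxNetworks)
        msg <- c(msg, sprintf("collection holds %d networks but capacity is %d",
                              length(object@networks), object@maxNetworks))
    if (length(msg)) msg else TRUE
})

#' RegionMap: exact intersection regions for Venn/UpSet analysis
#'
#' For a selection of networks, maps every non-empty label subset to the
#' elements (nodes or edges) found in \emph{exactly} that subset of networks
#' -- the exclusive-region semantics underlying UpSet plots and Venn diagram
#' numbers. Regions are pairwise disjoint and jointly cover the union of the
#' selected element sets. Edge elements are encoded as
#' \code{"u--v"} strings over canonically ordered endpoints.
#'
#' @slot elementKind \code{"node"} or \code{"edge"}.
#' @slot labels the selected network labels, in collection order.
#' @slot subsets list of character vectors, one label subset per region
#'   (all \code{2^k - 1} subsets are present, possibly with zero members).
#' @slot members list of character vectors parallel to \code{subsets}.
#'
#' @seealso \code{\link{computeRegions}}, \code{\link{upsetRows}}
#' @exportClass RegionMap
setClass("RegionMap",
    representation(
        elementKind = "character",
        labels = "character",
        subsets = "list",
        members = "list"
    )
)

setValidity("RegionMap", function(object) {
    msg <- character(0)
    if (!object@elementKind %in% c("node", "edge"))
        msg <- c(msg, "elementKind must be 'node' or 'edge'")
    if (length(object@subsets) != length(object@members))
        msg <- c(msg, "subsets and members must be parallel lists")
    all_members <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(all_members))
        msg <- c(msg, "regions must be pairwise disjoint")
    if (length(msg)) msg else TRUE
})

#' Partition: a network's community structure
#'
#' Disjoint communities covering all nodes of one network, ordered by
#' descending size (ties broken by the lexicographically smallest member),
#' with the modularity of the partition.
#'
#' @slot label parent network label.
#' @slot communities list of character vectors (node sets), disjoint,
#'   covering the node set, size-ordered.
#' @slot modularity numeric Newman-Girvan modularity Q of the partition.
#'
#' @seealso \code{\link{detectCommunities}}, \code{\link{communityTransitions}}
#' @exportClass Partition
setClass("Partition",
    representation(label = "character", communities = "list",
                   modularity = "numeric")
)

setValidity("Partition", function(object) {
    members <- unlist(object@communities, use.names = FALSE)
    if (anyDuplicated(members))
        return("communities must be pairwise disjoint")
    sizes <- lengths(object@communities)
    if (is.unsorted(rev(sizes)))
        return("communities must be ordered by descending size")
    TRUE
})

#' TransitionReport: community-transition scores between two partitions
#'
#' Quantifies community reshuffling between two networks: for every cross
#' pair (community i of A, community j of B) the node-set intersection count
#' and Jaccard score, plus the cumulative sum Jaccard and the weighted sum
#' Jaccard (sum divided by the number of comparisons, times 100). Lower
#' weighted scores indicate stronger community transitions.
#'
#' @slot labelA,labelB the compared network labels.
#' @slot intersections integer matrix, |A| x |B| community pair intersection
#'   counts.
#' @slot jaccard numeric matrix of pairwise Jaccard scores.
#' @slot sumJaccard cumulative sum of all pairwise Jaccard scores.
#' @slot comparisons number of community comparisons made (all cross pairs,
#'   |A| * |B|).
#' @slot weightedSumJaccard \code{sumJaccard / comparisons * 100}.
#' @slot weightedSumJaccardNonzero alternative weighting that divides by the
#'   number of pairs with non-zero overlap (reported alongside; the all-pairs
#'   denominator is the primary score).
#'
#' @seealso \code{\link{communityTransitions}}
#' @exportClass TransitionReport
setClass("TransitionReport",
    representation(
        labelA = "character", labelB = "character",
        intersections = "matrix", jaccard = "matrix",
        sumJaccard = "numeric", comparisons = "numeric",
        weightedSumJaccard = "numeric",
        weightedSumJaccardNonzero = "numeric"
    )
)

#' PathMatrix: all shortest paths for one node pair across networks
#'
#' All co-optimal shortest paths between one source/target pair in every
#' selected network, with per-node order numbers (source = 0, target = path
#' length in hop mode) and the preferred-intermediate-node tally: for each
#' node, the number of selected networks in whose shortest paths it appears.
#'
#' @slot source,target node identifiers.
#' @slot weighted logical; hop counts (FALSE) or positive edge weights as
#'   costs (TRUE).
#' @slot records list of path records, each a list with elements
#'   \code{network}, \code{nodes} (ordered from source to target),
#'   \code{length}, and \code{orderNumbers} (named integer positions).
#' @slot preferred named numeric vector: intermediate node -> number of
#'   networks whose shortest paths contain it (source/target excluded).
#'
#' @seealso \code{\link{pathMatrix}}, \code{\link{allShortestPaths}}
#' @exportClass PathMatrix
setClass("PathMatrix",
    representation(
        source = "character", target = "character", weighted = "logical",
        records = "list", preferred = "numeric"
    )
)
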