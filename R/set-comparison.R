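## Workflow 1: exact Venn/UpSet regions over node or edge sets, and the
## derived intersection / exclusive / union comparison graphs. Edge identity
## ignores weights (presence/absence of the canonical undirected edge).

.elementSet <- function(network, elementKind) {
    if (elementKind == "node") networkNodes(network) else edgeKeys(network)
}

#' Exact intersection regions across selected networks
#'
#' Partitions the union of node (or edge) sets of the selected networks into
#' exclusive regions: each element is assigned to the unique label subset of
#' networks that contain it (standard UpSet semantics; the numbers shown in
#' Venn diagram regions). All \code{2^k - 1} subsets are represented, empty
#' regions included, so region counts can be read off for any combination.
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @param selected labels of 2--8 networks to compare (default: all).
#' @param elementKind \code{"node"} or \code{"edge"}.
#' @return a \linkS4class{RegionMap}.
#' @seealso \code{\link{upsetRows}}, \code{\link{regionMembers}},
#'   \code{\link{inclusiveCounts}}
#' @examples
#' n1 <- parseEdgeList(c("A\tB", "B\tC"), label = "n1")
#' n2 <- parseEdgeList(c("B\tC", "C\tD"), label = "n2")
#' rm <- computeRegions(loadCollection(list(n1, n2)), elementKind = "edge")
#' regionMembers(rm, c("n1", "n2"))  # the shared edge B--C
#' @export
computeRegions <- function(collection, selected = NULL,
                           elementKind = c("node", "edge")) {
    elementKind <- match.arg(elementKind)
    selected <- .resolveSelection(collection, selected)
    sets <- lapply(selected, function(lab)
        .elementSet(getNetwork(collection, lab), elementKind))
    universe <- .cSort(unique(unlist(sets)))
    k <- length(selected)
    memb <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
    if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L)
    if (length(universe) == 0L) memb <- matrix(logical(0), ncol = k)
    sig <- apply(memb, 1L, function(r) paste(which(r), collapse = ","))
    subsets <- list(); members <- list()
    for (size in seq_len(k)) {
        idx <- utils::combn(k, size, simplify = FALSE)
        for (ii in idx) {
            key <- paste(ii, collapse = ",")
            subsets[[length(subsets) + 1L]] <- selected[ii]
            members[[length(members) + 1L]] <- universe[sig == key]
        }
    }
    new("RegionMap", elementKind = elementKind, labels = selected,
        subsets = subsets, members = members)
}

#' Accessors for RegionMap objects
#'
#' @param x a \linkS4class{RegionMap}.
#' @param subset character vector of network labels identifying one region.
#' @return \code{regionMembers}: the elements found in exactly that subset
#'   of networks (the list behind "clicking on the numbers").
#' @name RegionMap-accessors
#' @aliases regionMembers
NULL

#' @rdname RegionMap-accessors
setMethod("regionMembers", "RegionMap", function(x, subset) {
    hit <- which(vapply(x@subsets, function(s) setequal(s, subset), logical(1)))
    if (!length(hit))
        stop("no region for subset {", paste(subset, collapse = ", "), "}")
    x@members[[hit]]
})

setMethod("show", "RegionMap", function(object) {
    cat(sprintf("RegionMap (%s regions) over %d networks: %s\n",
                object@elementKind, length(object@labels),
                paste(object@labels, collapse = ", ")))
    nonEmpty <- sum(lengths(object@members) > 0)
    cat(sprintf("  %d of %d regions non-empty; union size %d\n",
                nonEmpty, length(object@members),
                sum(lengths(object@members))))
})

#' UpSet rows: ordered region table
#'
#' Flattens a \linkS4class{RegionMap} into the row order of an UpSet plot,
#' sorted either by region size (\code{"set_cardinality"}) or by the number
#' of networks in the combination (\code{"combination_cardinality"}), both
#' descending with ties broken lexicographically by the label subset.
#'
#' @param regions a \linkS4class{RegionMap}.
#' @param sortBy \code{"set_cardinality"} or \code{"combination_cardinality"}.
#' @param dropEmpty drop zero-count regions (default TRUE, matching plot
#'   practice).
#' @return data.frame with columns \code{subset} (labels joined by
#'   \code{"&"}), \code{degree}, \code{count} and a list column
#'   \code{members}.
#' @export
upsetRows <- function(regions,
                      sortBy = c("set_cardinality", "combination_cardinality"),
                      dropEmpty = TRUE) {
    sortBy <- match.arg(sortBy)
    subsetStr <- vapply(regions@subsets, paste, character(1), collapse = "&")
    degree <- lengths(regions@subsets)
    count <- lengths(regions@members)
    o <- if (sortBy == "set_cardinality")
        order(-count, subsetStr, method = "radix")
    else
        order(-degree, subsetStr, method = "radix")
    out <- data.frame(subset = subsetStr[o], degree = degree[o],
                      count = count[o], stringsAsFactors = FALSE)
    out$members <- regions@members[o]
    if (dropEmpty) out <- out[out$count > 0L, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Inclusive ("shared by at least") intersection counts
#'
#' The alternative reading of intersection numbers: for each label subset,
#' how many elements are shared by \emph{at least} those networks (i.e. the
#' sum over all exclusive regions whose subset contains it).
#'
#' @param regions a \linkS4class{RegionMap}.
#' @return data.frame with columns \code{subset}, \code{degree},
#'   \code{count}.
#' @export
inclusiveCounts <- function(regions) {
    subsetStr <- vapply(regions@subsets, paste, character(1), collapse = "&")
    count <- vapply(seq_along(regions@subsets), function(i) {
        s <- regions@subsets[[i]]
        sum(lengths(regions@members[vapply(regions@subsets, function(t)
            all(s %in% t), logical(1))]))
    }, integer(1))
    data.frame(subset = subsetStr, degree = lengths(regions@subsets),
               count = count, stringsAsFactors = FALSE)
}

#' Intersection graph of selected networks
#'
#' Edges common to all selected networks; the node set is exactly the
#' endpoints of those edges.
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @param selected labels to intersect (default: all).
#' @return a \linkS4class{Network} labelled \code{"intersection"} (possibly
#'   empty).
#' @export
intersectionGraph <- function(collection, selected = NULL) {
    selected <- .resolveSelection(collection, selected)
    keys <- Reduce(intersect, lapply(selected, function(lab)
        edgeKeys(getNetwork(collection, lab))))
    Network(.splitEdgeKey(keys), label = "intersection")
}

#' Exclusive edge graphs per selected network
#'
#' For every selected network, the subgraph of edges present in that network
#' and in none of the other selected networks. Together with the shared
#' regions these exclusives partition each network's edge set.
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @param selected labels to compare (default: all).
#' @return named list of \linkS4class{Network} objects, one per selected
#'   label.
#' @export
exclusiveGraphs <- function(collection, selected = NULL) {
    selected <- .resolveSelection(collection, selected)
    keySets <- lapply(selected, function(lab)
        edgeKeys(getNetwork(collection, lab)))
    names(keySets) <- selected
    out <- lapply(selected, function(lab) {
        others <- unlist(keySets[setdiff(selected, lab)], use.names = FALSE)
        excl <- setdiff(keySets[[lab]], others)
        Network(.splitEdgeKey(excl), label = paste0(lab, ".exclusive"),
                color = networkColor(getNetwork(collection, lab)))
    })
    names(out) <- selected
    out
}

#' AnnotatedUnionGraph: union of networks with per-element membership
#'
#' The union of the selected networks where every node and edge carries the
#' set of networks containing it -- the data behind pie-chart node colouring
#' and multi-coloured edges in union views.
#'
#' @slot labels selected network labels.
#' @slot nodeMembership named list: node -> character vector of containing
#'   labels.
#' @slot edgeMembership named list: canonical edge key -> containing labels.
#' @seealso \code{\link{unionGraph}}
#' @exportClass AnnotatedUnionGraph
setClass("AnnotatedUnionGraph",
    representation(labels = "character", nodeMembership = "list",
                   edgeMembership = "list"))

setValidity("AnnotatedUnionGraph", function(object) {
    if (any(lengths(object@nodeMembership) == 0L) ||
        any(lengths(object@edgeMembership) == 0L))
        return("every membership set must be non-empty")
    TRUE
})

setMethod("show", "AnnotatedUnionGraph", function(object) {
    cat(sprintf("AnnotatedUnionGraph over %d networks: %d nodes, %d edges\n",
                length(object@labels), length(object@nodeMembership),
                length(object@edgeMembership)))
})

#' Union graph with membership annotation
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @param selected labels to union (default: all).
#' @return an \linkS4class{AnnotatedUnionGraph}.
#' @examples
#' n1 <- parseEdgeList("A\tB", label = "n1")
#' n2 <- parseEdgeList("B\tC", label = "n2")
#' ug <- unionGraph(loadCollection(list(n1, n2)))
#' ug@nodeMembership[["B"]]  # present in both networks
#' @export
unionGraph <- function(collection, selected = NULL) {
    selected <- .resolveSelection(collection, selected)
    nets <- lapply(selected, getNetwork, x = collection)
    nodeM <- list(); edgeM <- list()
    for (i in seq_along(selected)) {
        for (nd in networkNodes(nets[[i]]))
            nodeM[[nd]] <- c(nodeM[[nd]], selected[i])
        for (ek in edgeKeys(nets[[i]]))
            edgeM[[ek]] <- c(edgeM[[ek]], selected[i])
    }
    nodeM <- nodeM[.cSort(names(nodeM))]
    edgeM <- edgeM[.cSort(names(edgeM))]
    new("AnnotatedUnionGraph", labels = selected,
        nodeMembership = nodeM, edgeMembership = edgeM)
}

#' Export a RegionMap as JSON or TSV
#'
#' JSON records have the shape
#' \code{{"subset": [labels], "count": n, "members": [...]}}; the TSV table
#' has columns subset, degree, count, members (comma-joined).
#'
#' @param regions a \linkS4class{RegionMap}.
#' @param path output file; for \code{regionsToJSON}, \code{NULL} returns
#'   the JSON string.
#' @return the JSON string (invisibly when written to a file), or
#'   \code{path} for the TSV writer.
#' @export
regionsToJSON <- function(regions, path = NULL) {
    recs <- lapply(seq_along(regions@subsets), function(i)
        list(subset = regions@subsets[[i]],
             count = length(regions@members[[i]]),
             members = regions@members[[i]]))
    js <- jsonlite::toJSON(list(elementKind = regions@elementKind,
                                regions = recs),
                           auto_unbox = TRUE, pretty = TRUE)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}

#' @rdname regionsToJSON
#' @export
writeRegionTable <- function(regions, path) {
    rows <- upsetRows(regions, dropEmpty = FALSE)
    rows$members <- vapply(rows$members, paste, character(1), collapse = ",")
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export an AnnotatedUnionGraph as JSON
#'
#' Node and edge membership records directly consumable by pie-node
#' renderers.
#'
#' @param x an \linkS4class{AnnotatedUnionGraph}.
#' @param path output file; \code{NULL} returns the JSON string.
#' @return JSON string (invisibly when written).
#' @export
unionGraphToJSON <- function(x, path = NULL) {
    nodes <- lapply(names(x@nodeMembership), function(nd)
        list(node = nd, networks = x@nodeMembership[[nd]]))
    edges <- lapply(names(x@edgeMembership), function(ek) {
        ends <- .splitEdgeKey(ek)
        list(source = ends$from, target = ends$to,
             networks = x@edgeMembership[[ek]])
    })
    js <- jsonlite::toJSON(list(labels = x@labels, nodes = nodes,
                                edges = edges),
                           auto_unbox = TRUE, pretty = TRUE)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}
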