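## Network-level similarity: pairwise edge-Jaccard matrix, hierarchical
## clustering of the networks themselves (the selection dendrogram) and
## node/edge Jaccard distances of each network from the global union.

.jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) return(1)  # two empty sets: identical by convention
    length(intersect(a, b)) / u
}

#' Pairwise edge-Jaccard similarity between networks
#'
#' For every pair of networks the ratio of intersecting edges over their
#' union, \code{|E_i intersect E_j| / |E_i union E_j|}. Two empty edge sets
#' are defined as similarity 1 (identical); one empty set against a
#' non-empty one gives 0.
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @param selected labels to include (default: all).
#' @param elementKind compare edge sets (default) or node sets.
#' @return symmetric numeric matrix with unit diagonal, dimnames = labels.
#' @seealso \code{\link{clusterNetworks}}
#' @export
edgeJaccardMatrix <- function(collection, selected = NULL,
                              elementKind = c("edge", "node")) {
    elementKind <- match.arg(elementKind)
    selected <- .resolveSelection(collection, selected)
    sets <- lapply(selected, function(lab)
        .elementSet(getNetwork(collection, lab), elementKind))
    k <- length(selected)
    m <- diag(1, k)
    for (i in seq_len(k - 1))
        for (j in (i + 1):k)
            m[i, j] <- m[j, i] <- .jaccard(sets[[i]], sets[[j]])
    dimnames(m) <- list(selected, selected)
    m
}

#' Hierarchically cluster networks by Jaccard distance
#'
#' Agglomerative clustering of the networks on distance \code{d = 1 - s}
#' (s = edge-Jaccard similarity), average linkage by default. Labels are
#' ordered lexicographically before clustering so equal-distance merges are
#' resolved deterministically and independent of input order.
#'
#' @param similarity symmetric similarity matrix from
#'   \code{\link{edgeJaccardMatrix}}.
#' @param method linkage passed to \code{\link[stats]{hclust}} (default
#'   \code{"average"}, i.e. UPGMA).
#' @return an \code{\link[stats]{hclust}} tree whose merge heights are
#'   Jaccard distances.
#' @seealso \code{\link{dendrogramNewick}}
#' @export
clusterNetworks <- function(similarity, method = "average") {
    stopifnot(is.matrix(similarity), nrow(similarity) >= 2L)
    o <- .cOrder(rownames(similarity))
    d <- stats::as.dist(1 - similarity[o, o, drop = FALSE])
    stats::hclust(d, method = method)
}

#' Serialize a network dendrogram as newick
#'
#' Branch lengths are merge-height differences, so leaf-to-root distances
#' reproduce the clustering heights.
#'
#' @param hc an \code{hclust} tree from \code{\link{clusterNetworks}}.
#' @param path optional output file; \code{NULL} returns the newick string.
#' @return newick string (invisibly when written to a file).
#' @export
dendrogramNewick <- function(hc, path = NULL) {
    phy <- ape::as.phylo(hc)
    ## as.phylo() halves hclust heights (distance -> divergence); scale back
    ## so leaf-to-root depths equal the merge heights
    phy$edge.length <- phy$edge.length * 2
    nwk <- ape::write.tree(phy)
    if (is.null(path)) return(nwk)
    writeLines(nwk, path)
    invisible(nwk)
}

#' Node and edge Jaccard distances from the global union
#'
#' For each selected network, the Jaccard distance (1 - Jaccard index) of
#' its node set and of its edge set from the corresponding set of the global
#' union network of the selection -- the data behind the radar view. A
#' network equal to the union is at distance 0 on both axes; because every
#' network is a subset of the union, the index reduces to
#' \code{|S_k| / |S_union|}.
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @param selected labels to include (default: all).
#' @return data.frame with columns \code{label}, \code{nodeDistance},
#'   \code{edgeDistance}, each in [0, 1].
#' @export
unionDistances <- function(collection, selected = NULL) {
    selected <- .resolveSelection(collection, selected)
    nodeSets <- lapply(selected, function(lab)
        networkNodes(getNetwork(collection, lab)))
    edgeSets <- lapply(selected, function(lab)
        edgeKeys(getNetwork(collection, lab)))
    nodeU <- unique(unlist(nodeSets))
    edgeU <- unique(unlist(edgeSets))
    data.frame(
        label = selected,
        nodeDistance = vapply(nodeSets, function(s) 1 - .jaccard(s, nodeU),
                              numeric(1)),
        edgeDistance = vapply(edgeSets, function(s) 1 - .jaccard(s, edgeU),
                              numeric(1)),
        stringsAsFactors = FALSE)
}

#' Export similarity results
#'
#' \code{writeSimilarityMatrix} writes the TSV matrix;
#' \code{radarDistancesToJSON} emits \code{{label, node_distance,
#' edge_distance}} records.
#'
#' @param similarity matrix from \code{\link{edgeJaccardMatrix}}.
#' @param distances data.frame from \code{\link{unionDistances}}.
#' @param path output file; JSON writer returns the string when \code{NULL}.
#' @return \code{path} or JSON string, invisibly.
#' @export
writeSimilarityMatrix <- function(similarity, path) {
    utils::write.table(similarity, path, sep = "\t", quote = FALSE,
                       col.names = NA)
    invisible(path)
}

#' @rdname writeSimilarityMatrix
#' @export
radarDistancesToJSON <- function(distances, path = NULL) {
    recs <- lapply(seq_len(nrow(distances)), function(i)
        list(label = distances$label[i],
             node_distance = distances$nodeDistance[i],
             edge_distance = distances$edgeDistance[i]))
    js <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}
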