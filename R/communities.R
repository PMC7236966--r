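## Workflow 4: greedy modularity maximisation (CNM fast-greedy
## agglomeration), size-ordered community tables, pairwise
## community-transition scoring and rank-normalized centrality embeddings.

#' Detect communities by greedy modularity maximisation
#'
#' Clauset-Newman-Moore fast-greedy agglomeration: starting from singleton
#' communities, repeatedly merge the pair with the largest modularity gain
#' and cut the merge dendrogram at maximum modularity. The algorithm is
#' deterministic (no random seed); node order cannot influence the result
#' because the underlying graph is always built over the sorted node set.
#' Isolated nodes become singleton communities; an edgeless network yields
#' all singletons with modularity 0 and a warning.
#'
#' @param network a \linkS4class{Network}.
#' @return a \linkS4class{Partition} with communities ordered by descending
#'   size (ties by lexicographically smallest member) and the partition's
#'   modularity Q.
#' @examples
#' clq <- function(v) t(utils::combn(v, 2))
#' ed <- rbind(clq(c("a1", "a2", "a3", "a4")), clq(c("b1", "b2", "b3", "b4")),
#'             c("a1", "b1"))
#' net <- Network(data.frame(from = ed[, 1], to = ed[, 2]), label = "planted")
#' detectCommunities(net)  # recovers the two 4-cliques
#' @export
detectCommunities <- function(network) {
    nodes <- networkNodes(network)
    if (numEdges(network) == 0L) {
        warning("edgeless network: every node is a singleton community",
                call. = FALSE)
        comms <- as.list(nodes)
        return(new("Partition", label = networkLabel(network),
                   communities = comms, modularity = 0))
    }
    g <- asIgraph(network)
    cl <- igraph::cluster_fast_greedy(g)
    ## cut the merge dendrogram at the maximum-modularity step ourselves:
    ## the stored trace can place the maximum at a later merge than the
    ## default membership does when values differ only by float noise
    steps <- which.max(round(cl$modularity, 12L)) - 1L
    memb <- igraph::cut_at(cl, steps = steps)
    names(memb) <- igraph::V(g)$name
    comms <- split(names(memb), as.integer(memb))
    comms <- lapply(comms, .cSort)
    firsts <- vapply(comms, `[`, character(1), 1L)
    o <- order(-lengths(comms), firsts, method = "radix")
    comms <- unname(comms[o])
    q <- igraph::modularity(g, memb)
    new("Partition", label = networkLabel(network),
        communities = comms, modularity = q)
}

#' Accessors for Partition objects
#'
#' @param x a \linkS4class{Partition}.
#' @return \code{communities}: list of node-set character vectors in size
#'   order; \code{modularityScore}: the partition's modularity Q.
#' @name Partition-accessors
#' @aliases communities modularityScore
NULL

#' @rdname Partition-accessors
setMethod("communities", "Partition", function(x) x@communities)

#' @rdname Partition-accessors
setMethod("modularityScore", "Partition", function(x) x@modularity)

setMethod("show", "Partition", function(object) {
    cat(sprintf("Partition of '%s': %d communities (sizes %s), Q = %.4f\n",
                object@label, length(object@communities),
                paste(utils::head(lengths(object@communities), 8L),
                      collapse = ","),
                object@modularity))
})

#' Merged community table for a collection
#'
#' Detects communities in every selected network and merges them into one
#' table ordered by descending community size (ties by network label, then
#' community id), each row tagged with its parent network and colour.
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @param selected labels to include (default: all).
#' @param partitions optional pre-computed named list of
#'   \linkS4class{Partition} objects (names = labels) to reuse.
#' @return data.frame with columns \code{network}, \code{color},
#'   \code{communityId}, \code{size} and list column \code{members}.
#' @seealso \code{\link{queryCommunities}}
#' @export
communityTable <- function(collection, selected = NULL, partitions = NULL) {
    selected <- .resolveSelection(collection, selected)
    if (is.null(partitions)) {
        partitions <- lapply(selected, function(lab)
            detectCommunities(getNetwork(collection, lab)))
        names(partitions) <- selected
    }
    rows <- do.call(rbind, lapply(selected, function(lab) {
        p <- partitions[[lab]]
        data.frame(network = lab,
                   color = networkColor(getNetwork(collection, lab)),
                   communityId = seq_along(p@communities),
                   size = lengths(p@communities),
                   stringsAsFactors = FALSE)
    }))
    rows$members <- unlist(lapply(selected, function(lab)
        partitions[[lab]]@communities), recursive = FALSE)
    o <- order(-rows$size, rows$network, rows$communityId, method = "radix")
    rows <- rows[o, , drop = FALSE]
    rownames(rows) <- NULL
    rows
}

#' Query a community table for communities containing given nodes
#'
#' @param table data.frame from \code{\link{communityTable}}.
#' @param nodes node identifiers of interest.
#' @param mode \code{"all"}: communities containing every queried node;
#'   \code{"any"}: at least one.
#' @return the matching subset of \code{table} (possibly zero rows).
#' @export
queryCommunities <- function(table, nodes, mode = c("all", "any")) {
    mode <- match.arg(mode)
    known <- unique(unlist(table$members))
    unknown <- setdiff(nodes, known)
    if (length(unknown))
        stop("unknown node(s): ", paste(unknown, collapse = ", "))
    hit <- vapply(table$members, function(m)
        if (mode == "all") all(nodes %in% m) else any(nodes %in% m),
        logical(1))
    out <- table[hit, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Community-transition scores between two partitions
#'
#' Quantifies how the communities of one network redistribute across the
#' communities of another. For every cross pair of communities the node-set
#' intersection count and Jaccard score are computed; the sum Jaccard is
#' their cumulative sum, and the weighted sum Jaccard divides it by the
#' number of comparisons made and multiplies by 100. With the all-pairs
#' denominator (|A| x |B|, the default) a lower weighted score indicates
#' stronger community transitions. Nodes present in only one network count
#' against the pair unions: they are genuine departures.
#'
#' @param partA,partB \linkS4class{Partition} objects (non-empty).
#' @return a \linkS4class{TransitionReport}.
#' @examples
#' pa <- new("Partition", label = "A",
#'           communities = list(c("a", "b", "c"), c("d", "e", "f")),
#'           modularity = NA_real_)
#' pb <- new("Partition", label = "B",
#'           communities = list(c("c", "d", "e", "f"), c("a", "b")),
#'           modularity = NA_real_)
#' communityTransitions(pa, pb)  # sum ~ 1.583, weighted ~ 39.58
#' @export
communityTransitions <- function(partA, partB) {
    A <- partA@communities; B <- partB@communities
    if (!length(A) || !length(B))
        stop("both partitions must contain at least one community")
    nI <- matrix(0L, length(A), length(B))
    jac <- matrix(0, length(A), length(B))
    for (i in seq_along(A))
        for (j in seq_along(B)) {
            nI[i, j] <- length(intersect(A[[i]], B[[j]]))
            jac[i, j] <- nI[i, j] / length(union(A[[i]], B[[j]]))
        }
    sumJ <- sum(jac)
    comparisons <- length(A) * length(B)
    nz <- sum(nI > 0L)
    new("TransitionReport",
        labelA = partA@label, labelB = partB@label,
        intersections = nI, jaccard = jac,
        sumJaccard = sumJ, comparisons = comparisons,
        weightedSumJaccard = sumJ / comparisons * 100,
        weightedSumJaccardNonzero = if (nz) sumJ / nz * 100 else 0)
}

setMethod("show", "TransitionReport", function(object) {
    cat(sprintf(
        "TransitionReport %s -> %s: %d comparisons, sum Jaccard %.4f, weighted %.2f\n",
        object@labelA, object@labelB, object@comparisons,
        object@sumJaccard, object@weightedSumJaccard))
})

#' Sankey-ready node flow records between two partitions
#'
#' One record per node present in both partitions, giving the community it
#' belongs to in each (1-based indices into the size-ordered community
#' lists).
#'
#' @param partA,partB \linkS4class{Partition} objects.
#' @return data.frame with columns \code{node}, \code{fromCommunity},
#'   \code{toCommunity}.
#' @export
transitionFlows <- function(partA, partB) {
    mA <- rep(seq_along(partA@communities), lengths(partA@communities))
    names(mA) <- unlist(partA@communities)
    mB <- rep(seq_along(partB@communities), lengths(partB@communities))
    names(mB) <- unlist(partB@communities)
    shared <- .cSort(intersect(names(mA), names(mB)))
    data.frame(node = shared,
               fromCommunity = unname(mA[shared]),
               toCommunity = unname(mB[shared]),
               stringsAsFactors = FALSE)
}

#' Rank-normalized centrality embedding for a network pair
#'
#' Computes degree, hub score and betweenness for every (network, node)
#' observation of the two compared networks, pools the observations of both
#' networks per measure, converts them to ascending ranks (ties receive the
#' average rank) and divides by the pooled observation count, yielding
#' values in (0, 1] comparable across the pair -- the heatmap embedding
#' shown beside community transitions.
#'
#' @param netA,netB \linkS4class{Network} objects (each with at least one
#'   edge, required by the hub score).
#' @return data.frame with columns \code{network}, \code{node},
#'   \code{degree}, \code{hub}, \code{betweenness} (rank-normalized).
#' @export
rankEmbedding <- function(netA, netB) {
    meas <- c("degree", "hub", "betweenness")
    tabs <- lapply(list(netA, netB), function(nw) {
        ct <- nodeCentralities(nw, meas)
        data.frame(network = networkLabel(nw), ct, stringsAsFactors = FALSE)
    })
    pooled <- do.call(rbind, tabs)
    for (m in meas)
        pooled[[m]] <- rank(pooled[[m]], ties.method = "average") /
            nrow(pooled)
    rownames(pooled) <- NULL
    pooled
}

#' Export community results
#'
#' \code{writeCommunityTable} writes the merged table as TSV (members
#' comma-joined); \code{partitionToJSON} emits a partition (or a
#' \linkS4class{TransitionReport}, via \code{transitionToJSON}) as JSON.
#'
#' @param table data.frame from \code{\link{communityTable}}.
#' @param partition a \linkS4class{Partition}.
#' @param report a \linkS4class{TransitionReport}.
#' @param path output file; JSON writers return the string when \code{NULL}.
#' @return \code{path} or the JSON string, invisibly.
#' @export
writeCommunityTable <- function(table, path) {
    out <- table
    out$members <- vapply(out$members, paste, character(1), collapse = ",")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCommunityTable
#' @export
partitionToJSON <- function(partition, path = NULL) {
    js <- jsonlite::toJSON(
        list(network = partition@label,
             modularity = partition@modularity,
             communities = lapply(seq_along(partition@communities), function(i)
                 list(id = i, size = length(partition@communities[[i]]),
                      members = partition@communities[[i]]))),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}

#' @rdname writeCommunityTable
#' @export
transitionToJSON <- function(report, path = NULL) {
    pairs <- list()
    for (i in seq_len(nrow(report@jaccard)))
        for (j in seq_len(ncol(report@jaccard)))
            if (report@intersections[i, j] > 0L)
                pairs[[length(pairs) + 1L]] <- list(
                    communityA = i, communityB = j,
                    intersection = report@intersections[i, j],
                    jaccard = report@jaccard[i, j])
    js <- jsonlite::toJSON(
        list(networkA = report@labelA, networkB = report@labelB,
             comparisons = report@comparisons,
             sum_jaccard = report@sumJaccard,
             weighted_sum_jaccard = report@weightedSumJaccard,
             weighted_sum_jaccard_nonzero = report@weightedSumJaccardNonzero,
             pair_scores = pairs),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}
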