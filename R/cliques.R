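## Workflow 5: maximal-clique enumeration with a minimum-size filter and
## cross-network tracking of clique members. Enumeration is igraph's
## Bron-Kerbosch with pivoting; rows are ordered deterministically
## (descending size, then lexicographic member lists).

#' Maximal cliques of size >= k in one network
#'
#' Enumerates the \emph{maximal} cliques (complete subgraphs not contained
#' in any larger complete subgraph) with at least \code{k} members. Setting
#' \code{k = 2} includes isolated dyads; the default \code{k = 3} starts at
#' triads.
#'
#' @param network a \linkS4class{Network}.
#' @param k minimum clique size (>= 2).
#' @param nodeFilter optional node identifiers; only cliques containing
#'   \emph{all} of them are returned.
#' @return data.frame with columns \code{network}, \code{cliqueId},
#'   \code{size} and list column \code{members} (each member vector sorted),
#'   ordered by descending size then lexicographic members.
#' @examples
#' clq <- function(v) t(utils::combn(v, 2))
#' net <- Network(data.frame(from = clq(LETTERS[1:4])[, 1],
#'                           to = clq(LETTERS[1:4])[, 2]), label = "k4")
#' findCliques(net, k = 3)
#' @export
findCliques <- function(network, k = 3L, nodeFilter = NULL) {
    k <- as.integer(k)
    if (k < 2L)
        stop("minimum clique size k must be >= 2")
    g <- asIgraph(network)
    cl <- if (numEdges(network) == 0L) list() else
        igraph::max_cliques(g, min = k)
    members <- lapply(cl, function(v) .cSort(names(v)))
    if (!is.null(nodeFilter))
        members <- members[vapply(members, function(m)
            all(nodeFilter %in% m), logical(1))]
    o <- .cOrder(-lengths(members),
                 vapply(members, paste, character(1), collapse = "\r"))
    members <- members[o]
    out <- data.frame(network = rep(networkLabel(network),
                                    length(members)),
                      cliqueId = seq_along(members),
                      size = lengths(members),
                      stringsAsFactors = FALSE)
    out$members <- members
    out
}

#' Merged clique table for a collection
#'
#' @param collection a \linkS4class{NetworkCollection}.
#' @param selected labels to include (default: all).
#' @param k minimum clique size.
#' @param nodeFilter passed to \code{\link{findCliques}}.
#' @return row-bound clique tables, ordered by descending size then network.
#' @export
cliqueTable <- function(collection, selected = NULL, k = 3L,
                        nodeFilter = NULL) {
    selected <- .resolveSelection(collection, selected)
    tabs <- lapply(selected, function(lab)
        findCliques(getNetwork(collection, lab), k = k,
                    nodeFilter = nodeFilter))
    out <- do.call(rbind, tabs)
    o <- order(-out$size, out$network, out$cliqueId, method = "radix")
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Track clique members across other networks
#'
#' For a clique found in one network, reports for every other selected
#' network which members are present there, which are absent, and how many
#' of the clique's internal edges are retained (the induced edge count; a
#' clique intact elsewhere retains all \code{choose(size, 2)} edges).
#'
#' @param members character vector of clique member identifiers.
#' @param collection a \linkS4class{NetworkCollection}.
#' @param selected labels to track across (default: all).
#' @return data.frame with columns \code{network}, \code{presentCount},
#'   \code{absentCount}, \code{inducedEdges} and list columns
#'   \code{present}, \code{absent}.
#' @export
trackClique <- function(members, collection, selected = NULL) {
    selected <- .resolveSelection(collection, selected, min = 1L)
    members <- .cSort(unique(members))
    rows <- lapply(selected, function(lab) {
        nw <- getNetwork(collection, lab)
        present <- intersect(members, networkNodes(nw))
        absent <- setdiff(members, present)
        ed <- networkEdges(nw)
        induced <- sum(ed$from %in% members & ed$to %in% members)
        data.frame(network = lab, presentCount = length(present),
                   absentCount = length(absent), inducedEdges = induced,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$present <- lapply(selected, function(lab)
        intersect(members, networkNodes(getNetwork(collection, lab))))
    out$absent <- lapply(out$present, function(p) setdiff(members, p))
    out
}

#' Export clique results
#'
#' TSV clique table (members comma-joined) and JSON tracking records.
#'
#' @param table data.frame from \code{\link{findCliques}} or
#'   \code{\link{cliqueTable}}.
#' @param tracking data.frame from \code{\link{trackClique}}.
#' @param path output file; the JSON writer returns the string when
#'   \code{NULL}.
#' @return \code{path} or JSON string, invisibly.
#' @export
writeCliqueTable <- function(table, path) {
    out <- table
    out$members <- vapply(out$members, paste, character(1), collapse = ",")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCliqueTable
#' @export
trackingToJSON <- function(tracking, path = NULL) {
    recs <- lapply(seq_len(nrow(tracking)), function(i)
        list(network = tracking$network[i],
             present = tracking$present[[i]],
             absent = tracking$absent[[i]],
             induced_edges = tracking$inducedEdges[i]))
    js <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}
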