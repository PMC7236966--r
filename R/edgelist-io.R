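#' Parse a delimited edge list into a Network
#'
#' Reads one edge per line from a character vector, using configurable
#' delimiter and 1-based source/target/weight column positions. Undirected
#' semantics: the source/target distinction is only a parsing convention and
#' every edge is stored with canonically ordered endpoints. Duplicate edges
#' collapse to one (last weight read wins, with a warning when weights
#' conflict); self-loops are dropped with a warning unless
#' \code{allowSelfLoops}. Blank lines and lines starting with \code{#} are
#' skipped. Node identifiers are taken verbatim after trimming surrounding
#' whitespace and are compared case-sensitively.
#'
#' @param lines character vector of input lines (see \code{\link{readEdgeList}}
#'   for the file-path convenience wrapper).
#' @param label network label attached to the result.
#' @param delimiter single field-separator character (default tab).
#' @param sourceCol,targetCol 1-based column indices of the two endpoint
#'   columns; must differ.
#' @param weightCol optional 1-based column index of a numeric edge weight.
#' @param hasHeader skip the first non-blank, non-comment line.
#' @param allowSelfLoops keep self-loops instead of dropping them.
#' @param color display colour for the network (default: assigned at
#'   collection load time).
#' @return a \linkS4class{Network}.
#' @examples
#' parseEdgeList(c("geneA\tgeneB", "geneB\tgeneC"), label = "t16h")
#' parseEdgeList("A,B,0.57", label = "w", delimiter = ",", weightCol = 3)
#' @export
parseEdgeList <- function(lines, label, delimiter = "\t",
                          sourceCol = 1L, targetCol = 2L, weightCol = NULL,
                          hasHeader = FALSE, allowSelfLoops = FALSE,
                          color = NA_character_) {
    stopifnot(nchar(delimiter) == 1L)
    sourceCol <- as.integer(sourceCol); targetCol <- as.integer(targetCol)
    if (sourceCol == targetCol)
        stop("sourceCol and targetCol must differ")
    if (!is.null(weightCol)) {
        weightCol <- as.integer(weightCol)
        if (weightCol %in% c(sourceCol, targetCol))
            stop("weightCol must differ from sourceCol and targetCol")
    }
    lineNo <- seq_along(lines)
    keep <- !grepl("^\\s*$", lines) & !grepl("^\\s*#", lines)
    lines <- lines[keep]; lineNo <- lineNo[keep]
    if (hasHeader && length(lines)) {
        lines <- lines[-1L]; lineNo <- lineNo[-1L]
    }
    if (!length(lines))
        stop("empty edge list for network '", label, "'")
    fields <- strsplit(lines, delimiter, fixed = TRUE)
    need <- max(sourceCol, targetCol, weightCol %||% 0L)
    short <- lengths(fields) < need
    if (any(short))
        stop(sprintf("network '%s': line %d has %d field(s), need %d",
                     label, lineNo[which(short)[1]],
                     lengths(fields)[which(short)[1]], need))
    getcol <- function(i) trimws(vapply(fields, `[`, character(1), i))
    from <- getcol(sourceCol)
    to <- getcol(targetCol)
    if (any(from == "") || any(to == ""))
        stop(sprintf("network '%s': empty node identifier at line %d",
                     label, lineNo[which(from == "" | to == "")[1]]))
    weight <- if (is.null(weightCol)) NULL else {
        w <- suppressWarnings(as.numeric(getcol(weightCol)))
        if (anyNA(w))
            stop(sprintf("network '%s': non-numeric weight at line %d",
                         label, lineNo[which(is.na(w))[1]]))
        w
    }
    Network(data.frame(from = from, to = to,
                       weight = if (is.null(weight)) NA_real_ else weight,
                       stringsAsFactors = FALSE),
            label = label, color = color, allowSelfLoops = allowSelfLoops)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a delimited edge-list file
#'
#' @param path path to a plain-text edge list.
#' @param label network label; defaults to the file name without extension.
#' @param ... passed to \code{\link{parseEdgeList}}.
#' @return a \linkS4class{Network}.
#' @export
readEdgeList <- function(path, label = NULL, ...) {
    if (is.null(label))
        label <- sub("\\.[^.]*$", "", basename(path))
    parseEdgeList(readLines(path, warn = FALSE), label = label, ...)
}

#' Write a Network as a canonical TSV edge list
#'
#' Emits \code{source<TAB>target[<TAB>weight]} with canonically ordered
#' endpoints and rows; re-parsing the output reproduces the node and edge
#' sets exactly (isolated nodes are not representable in an edge list and
#' are dropped with a warning).
#'
#' @param network a \linkS4class{Network}.
#' @param path output file path (or connection).
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(network, path) {
    ed <- networkEdges(network)
    isolated <- setdiff(networkNodes(network), c(ed$from, ed$to))
    if (length(isolated))
        warning(sprintf("%d isolated node(s) not representable in an edge list",
                        length(isolated)), call. = FALSE)
    out <- if (any(!is.na(ed$weight))) ed else ed[, c("from", "to")]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Assemble parsed Networks into a NetworkCollection
#'
#' The unit of all comparisons: an ordered collection of 2 to
#' \code{maxNetworks} (default 8) networks with unique labels. Networks
#' without an explicit colour are assigned one from a fixed colour-blind-safe
#' palette, in collection order.
#'
#' @param networks list of \linkS4class{Network} objects (input order is
#'   preserved).
#' @param maxNetworks capacity bound; the engine is designed for at most 8
#'   simultaneously compared networks.
#' @return a \linkS4class{NetworkCollection}.
#' @examples
#' n1 <- parseEdgeList(c("A\tB", "B\tC"), label = "control")
#' n2 <- parseEdgeList(c("B\tC", "C\tD"), label = "treated")
#' loadCollection(list(n1, n2))
#' @export
loadCollection <- function(networks, maxNetworks = 8L) {
    if (!is.list(networks) || !all(vapply(networks, is, logical(1), "Network")))
        stop("'networks' must be a list of Network objects")
    if (length(networks) < 2L)
        stop("at least 2 networks are required for comparison (got ",
             length(networks), ")")
    if (length(networks) > maxNetworks)
        stop(sprintf("too many networks: %d supplied, maximum is %d",
                     length(networks), maxNetworks))
    palette <- rep_len(.defaultPalette, length(networks))
    for (i in seq_along(networks))
        if (is.na(networkColor(networks[[i]])))
            networks[[i]]@color <- palette[i]
    new("NetworkCollection", networks = networks,
        maxNetworks = as.integer(maxNetworks))
}
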