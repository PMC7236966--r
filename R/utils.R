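## Internal helpers: C-locale ordering and canonical edge handling.
## All lexicographic comparisons in the package go through these so that
## canonical edge orientation and tie-breaks are locale-independent.

## C-locale sort of a character vector.
.cSort <- function(x) sort(x, method = "radix")

## Vectorised C-locale strict less-than.
.cLess <- function(a, b) {
    codes <- match(c(a, b), .cSort(unique(c(a, b))))
    n <- length(a)
    codes[seq_len(n)] < codes[n + seq_len(n)]
}

## Order rows of a character matrix / parallel vectors C-locale-wise.
.cOrder <- function(...) order(..., method = "radix")

#' Canonical edge identity string
#'
#' Encodes an undirected edge as \code{"u--v"} with endpoints in canonical
#' (C-locale lexicographic) order; used as the element identity in all edge
#' set operations, which ignore weights.
#'
#' @param from,to character endpoint vectors (any orientation).
#' @return character vector of canonical edge keys.
#' @examples
#' edgeKey(c("B", "A"), c("A", "B"))  # both "A--B"
#' @export
edgeKey <- function(from, to) {
    swap <- .cLess(to, from)
    u <- ifelse(swap, to, from)
    v <- ifelse(swap, from, to)
    paste0(u, "--", v)
}

## Inverse of edgeKey (first "--" is the separator; endpoints never contain it
## in the supported namespaces).
.splitEdgeKey <- function(keys) {
    parts <- strsplit(keys, "--", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, character(1), 1L),
               to = vapply(parts, function(p) paste(p[-1], collapse = "--"),
                           character(1)),
               stringsAsFactors = FALSE)
}

## Canonicalize an edge table: orient endpoints, drop/keep self loops,
## collapse duplicates (last occurrence wins on weight), sort rows.
.canonicalEdges <- function(from, to, weight = NULL,
                            allowSelfLoops = FALSE, warnDuplicates = TRUE) {
    if (is.null(weight)) weight <- rep(NA_real_, length(from))
    loops <- from == to
    if (any(loops) && !allowSelfLoops) {
        warning(sprintf("dropped %d self-loop edge(s): %s", sum(loops),
                        paste(unique(from[loops]), collapse = ", ")),
                call. = FALSE)
        from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
    }
    swap <- .cLess(to, from)
    u <- ifelse(swap, to, from)
    v <- ifelse(swap, from, to)
    key <- paste0(u, "--", v)
    dup <- duplicated(key, fromLast = TRUE)
    if (any(dup)) {
        conflicting <- tapply(weight, key, function(w)
            length(unique(w[!is.na(w)])) > 1L)
        if (warnDuplicates && any(conflicting, na.rm = TRUE))
            warning(sprintf(
                "duplicate edges with conflicting weights (%s); last occurrence kept",
                paste(utils::head(names(conflicting)[which(conflicting)], 5L),
                      collapse = ", ")), call. = FALSE)
        u <- u[!dup]; v <- v[!dup]; weight <- weight[!dup]
    }
    o <- .cOrder(u, v)
    data.frame(from = u[o], to = v[o], weight = as.numeric(weight)[o],
               stringsAsFactors = FALSE)
}

## Default qualitative palette for network colours (colour-blind safe Okabe-Ito).
.defaultPalette <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
                     "#0072B2", "#D55E00", "#CC79A7", "#999999")
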