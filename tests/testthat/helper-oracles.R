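# Fixture builders and independent brute-force oracles. The oracles work
# from plain adjacency lists built directly off edge pairs, never through
# the package's graph machinery, so implementation and check stay on
# separate routes.

# Build a Network from "u-v" strings, e.g. netFromPairs(c("A-B", "B-C")).
netFromPairs <- function(pairs, label = "net", nodes = NULL) {
    parts <- strsplit(pairs, "-", fixed = TRUE)
    Network(data.frame(from = vapply(parts, `[`, character(1), 1),
                       to = vapply(parts, `[`, character(1), 2),
                       stringsAsFactors = FALSE),
            nodes = nodes, label = label)
}

cliquePairs <- function(v) {
    cmb <- utils::combn(v, 2)
    paste0(cmb[1, ], "-", cmb[2, ])
}

# Random simple graph as a plain edge data.frame over given node names.
randomEdgeDf <- function(nodes, m) {
    pairs <- utils::combn(nodes, 2)
    pick <- sample.int(ncol(pairs), min(m, ncol(pairs)))
    data.frame(from = pairs[1, pick], to = pairs[2, pick],
               stringsAsFactors = FALSE)
}

# Adjacency list (named list of neighbour character vectors) from edges.
adjList <- function(edges, nodes) {
    adj <- setNames(vector("list", length(nodes)), nodes)
    for (i in seq_len(nrow(edges))) {
        u <- edges$from[i]; v <- edges$to[i]
        adj[[u]] <- c(adj[[u]], v)
        adj[[v]] <- c(adj[[v]], u)
    }
    adj
}

# Exhaustive enumeration of ALL simple paths source -> target (depth-first),
# then keep the minimum-length ones. Only for small graphs.
oracleAllShortestPaths <- function(edges, nodes, source, target) {
    adj <- adjList(edges, nodes)
    paths <- list()
    walk <- function(path) {
        last <- path[length(path)]
        if (last == target) {
            paths[[length(paths) + 1L]] <<- path
            return(invisible())
        }
        for (nb in adj[[last]])
            if (!nb %in% path) walk(c(path, nb))
    }
    walk(source)
    if (!length(paths)) return(list())
    len <- lengths(paths)
    paths <- paths[len == min(len)]
    paths[order(vapply(paths, paste, character(1), collapse = "\r"),
                method = "radix")]
}

# Brute-force betweenness (raw unordered-pair counts): for every pair,
# enumerate all shortest paths and credit interior nodes fractionally.
oracleBetweenness <- function(edges, nodes) {
    bw <- setNames(numeric(length(nodes)), nodes)
    prs <- utils::combn(nodes, 2)
    for (i in seq_len(ncol(prs))) {
        sp <- oracleAllShortestPaths(edges, nodes, prs[1, i], prs[2, i])
        if (!length(sp)) next
        for (p in sp) {
            interior <- p[-c(1, length(p))]
            bw[interior] <- bw[interior] + 1 / length(sp)
        }
    }
    bw
}

# Exhaustive clique enumeration: grow complete subgraphs vertex by vertex
# (each clique visited once via its sorted representation), then keep the
# maximal ones of size >= k.
oracleMaxCliques <- function(edges, nodes, k = 2L) {
    nodes <- sort(nodes, method = "radix")
    adj <- lapply(adjList(edges, nodes), unique)
    cliques <- list()
    grow <- function(cl, candidates) {
        cliques[[length(cliques) + 1L]] <<- cl
        for (i in seq_along(candidates)) {
            v <- candidates[i]
            keep <- candidates[-seq_len(i)]
            grow(c(cl, v), intersect(keep, adj[[v]]))
        }
    }
    for (i in seq_along(nodes))
        grow(nodes[i], intersect(nodes[-seq_len(i)], adj[[nodes[i]]]))
    isMaximal <- vapply(cliques, function(cl) {
        ext <- Reduce(intersect, adj[cl])
        length(setdiff(ext, cl)) == 0L
    }, logical(1))
    out <- cliques[isMaximal & lengths(cliques) >= k]
    out[order(vapply(out, paste, character(1), collapse = "\r"),
              method = "radix")]
}

# Direct Newman-Girvan modularity of a given partition (list of node sets).
directModularity <- function(edges, partition) {
    m <- nrow(edges)
    if (m == 0L) return(0)
    memb <- rep(seq_along(partition), lengths(partition))
    names(memb) <- unlist(partition)
    deg <- table(c(edges$from, edges$to))
    q <- 0
    for (c in seq_along(partition)) {
        inC <- names(memb)[memb == c]
        ec <- sum(edges$from %in% inC & edges$to %in% inC)
        dc <- sum(deg[names(deg) %in% inC])
        q <- q + ec / m - (dc / (2 * m))^2
    }
    q
}

# Enumerate every set partition of 'nodes' (restricted-growth strings) and
# return the maximum directModularity over them. Feasible for n <= 10.
oracleMaxModularity <- function(edges, nodes) {
    n <- length(nodes)
    best <- -Inf
    bestPart <- NULL
    assign <- integer(n)
    recurse <- function(i, nBlocks) {
        if (i > n) {
            part <- split(nodes, assign[seq_len(n)])
            q <- directModularity(edges, part)
            if (q > best) {
                best <<- q
                bestPart <<- unname(part)
            }
            return(invisible())
        }
        for (b in seq_len(nBlocks + 1L)) {
            assign[i] <<- b
            recurse(i + 1L, max(nBlocks, b))
        }
    }
    recurse(1L, 0L)
    list(q = best, partition = bestPart)
}

# Canonical comparable form for a partition or clique list.
canonicalSets <- function(sets) {
    sets <- lapply(unname(sets), sort, method = "radix")
    sets[order(vapply(sets, paste, character(1), collapse = "\r"),
               method = "radix")]
}
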