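## Synthetic-network generation for benchmarking and testing: uniform
## G(n, m) random graphs (the benchmark design: node counts 500-5000, edge
## counts 2n-5n in categories, three replicates each), planted-partition
## graphs with known communities, and overlapping network families with a
## controlled shared-edge fraction. All randomness is driven by one explicit
## seed per call; the session RNG state is left untouched.

.nodeLabels <- function(n) sprintf("N%06d", seq_len(n))

#' Generate uniform G(n, m) random networks
#'
#' Samples simple undirected graphs with exactly \code{n} labelled nodes
#' ("N000001", ...) and exactly \code{m} distinct edges, uniformly over all
#' such graphs. Replicates share (n, m) but differ in wiring; the whole set
#' is reproducible from \code{seed}.
#'
#' @param n node count.
#' @param m edge count; must not exceed \code{n (n - 1) / 2}.
#' @param replicates number of graphs to generate (benchmark design: 3).
#' @param seed integer seed driving all randomness of the call.
#' @param labelPrefix prefix for the network labels
#'   (\code{"<prefix>1"}, ...).
#' @return list of \code{replicates} \linkS4class{Network} objects.
#' @examples
#' nets <- generateRandom(n = 50, m = 100, replicates = 2, seed = 1)
#' vapply(nets, numEdges, integer(1))  # both exactly 100
#' @export
generateRandom <- function(n, m, replicates = 1L, seed,
                           labelPrefix = "random") {
    n <- as.integer(n); m <- as.integer(m)
    if (m > n * (n - 1) / 2)
        stop(sprintf("m = %d exceeds simple-graph capacity %d for n = %d",
                     m, n * (n - 1) %/% 2, n))
    withr::with_seed(as.integer(seed), {
        lapply(seq_len(replicates), function(i) {
            g <- igraph::sample_gnm(n, m)
            igraph::V(g)$name <- .nodeLabels(n)
            ed <- igraph::as_data_frame(g, what = "edges")
            Network(ed, nodes = .nodeLabels(n),
                    label = paste0(labelPrefix, i))
        })
    })
}

#' Generate a planted-partition network with known communities
#'
#' Stochastic block model with within-block edge probability \code{pIn} and
#' between-block probability \code{pOut}; used to validate community
#' recovery (default geometry: two blocks of 20 nodes, pIn = 0.9,
#' pOut = 0.02).
#'
#' @param sizes integer vector of block sizes.
#' @param pIn,pOut within- and between-block edge probabilities.
#' @param seed integer seed.
#' @param label network label.
#' @return list with elements \code{network} (a \linkS4class{Network}) and
#'   \code{membership} (named integer vector of planted block ids).
#' @export
generatePlantedPartition <- function(sizes = c(20L, 20L), pIn = 0.9,
                                     pOut = 0.02, seed, label = "planted") {
    stopifnot(pIn >= 0, pIn <= 1, pOut >= 0, pOut <= 1)
    k <- length(sizes)
    pref <- matrix(pOut, k, k); diag(pref) <- pIn
    n <- sum(sizes)
    withr::with_seed(as.integer(seed), {
        g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = sizes)
    })
    igraph::V(g)$name <- .nodeLabels(n)
    ed <- igraph::as_data_frame(g, what = "edges")
    membership <- setNames(rep(seq_len(k), sizes), .nodeLabels(n))
    list(network = Network(ed, nodes = .nodeLabels(n), label = label),
         membership = membership)
}

#' Generate a family of overlapping networks
#'
#' Builds a base G(n, m) network and derives further networks that each
#' retain a given fraction of the base edges and rewire the remainder to
#' uniformly sampled node pairs absent from the base -- emulating network
#' rewiring between biological conditions while the node namespace stays
#' fixed. \code{overlap = 1} yields identical networks; \code{overlap = 0}
#' yields edge-disjoint ones.
#'
#' @param n,m base network node and edge counts.
#' @param networks number of networks in the family (2--8).
#' @param overlap fraction of base edges each derived network retains, in
#'   [0, 1].
#' @param seed integer seed.
#' @param labelPrefix network labels are \code{"<prefix>1"} (the base),
#'   \code{"<prefix>2"}, ...
#' @return a \linkS4class{NetworkCollection}.
#' @examples
#' fam <- generateFamily(n = 40, m = 80, networks = 3, overlap = 0.8,
#'                       seed = 7)
#' edgeJaccardMatrix(fam)
#' @export
generateFamily <- function(n, m, networks = 3L, overlap = 0.8, seed,
                           labelPrefix = "net") {
    if (overlap < 0 || overlap > 1)
        stop("overlap fraction must be in [0, 1]")
    if (networks < 2L || networks > 8L)
        stop("a family must contain between 2 and 8 networks")
    n <- as.integer(n); m <- as.integer(m)
    if (m > n * (n - 1) / 2)
        stop(sprintf("m = %d exceeds simple-graph capacity for n = %d", m, n))
    nodes <- .nodeLabels(n)
    withr::with_seed(as.integer(seed), {
        g <- igraph::sample_gnm(n, m)
        igraph::V(g)$name <- nodes
        baseEd <- igraph::as_data_frame(g, what = "edges")
        baseKeys <- edgeKey(baseEd$from, baseEd$to)
        capacity <- n * (n - 1) / 2
        keep <- round(overlap * m)
        if (capacity - m < m - keep)
            stop("rewiring pool too small; lower m or raise overlap")
        ## rejection-sample replacement pairs from the base's complement
        drawRewired <- function(count) {
            out <- character(0)
            while (length(out) < count) {
                u <- nodes[sample.int(n, 2L * count, replace = TRUE)]
                v <- nodes[sample.int(n, 2L * count, replace = TRUE)]
                ok <- u != v
                cand <- unique(edgeKey(u[ok], v[ok]))
                cand <- setdiff(cand, c(baseKeys, out))
                out <- c(out, cand)
            }
            out[seq_len(count)]
        }
        nets <- vector("list", networks)
        nets[[1L]] <- Network(baseEd, nodes = nodes,
                              label = paste0(labelPrefix, 1L))
        for (i in seq_len(networks - 1L)) {
            kept <- sample(baseKeys, keep)
            nRewire <- m - keep
            rewired <- if (nRewire > 0L) drawRewired(nRewire) else character(0)
            nets[[i + 1L]] <- Network(.splitEdgeKey(c(kept, rewired)),
                                      nodes = nodes,
                                      label = paste0(labelPrefix, i + 1L))
        }
    })
    loadCollection(nets)
}
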